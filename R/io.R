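#' Write a movie as a multi-page TIFF with a JSON sidecar
#'
#' Frames are linearly mapped to `[0, 1]` and stored as 32-bit float
#' grayscale pages; the affine scale, sampling interval, mask path, seed,
#' and optional ground-truth path are recorded in the sidecar so that
#' [read_movie()] restores the original values (to float precision).
#' The mask is written as a headerless 0/1 CSV grid; ground truth (when
#' given) as tidy CSV, one row per pixel.
#'
#' @param movie an [scn_movie()].
#' @param path output TIFF path.
#' @param sidecar sidecar JSON path (default `<path>.json`).
#' @param truth optional ground-truth list from [generate_scn_movie()].
#' @param seed optional integer recorded in the sidecar.
#' @return Invisibly, the sidecar path.
#' @export
write_movie <- function(movie, path, sidecar = paste0(path, ".json"),
                        truth = NULL, seed = NULL) {
  stopifnot(inherits(movie, "scn_movie"))
  d <- dim(movie$frames)
  lo <- min(movie$frames); hi <- max(movie$frames)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[3]),
                  function(k) (movie$frames[, , k] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32)

  mask_path <- paste0(sub("\\.tiff?$", "", path), "_mask.csv")
  utils::write.table(movie$mask * 1L, mask_path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  truth_path <- NULL
  if (!is.null(truth)) {
    truth_path <- paste0(sub("\\.tiff?$", "", path), "_truth.csv")
    idx <- which(movie$mask, arr.ind = TRUE)
    utils::write.csv(data.frame(
      row = idx[, 1] - 1L, col = idx[, 2] - 1L,
      true_period_h = truth$period_map[idx],
      true_acrophase_h = truth$acrophase_map[idx],
      rhythmic = truth$rhythmic_mask[idx] * 1L),
      truth_path, row.names = FALSE)
  }
  jsonlite::write_json(
    list(dt_h = movie$dt_h, height = d[1], width = d[2], frames = d[3],
         value_offset = lo, value_scale = scale,
         mask = basename(mask_path),
         truth = if (is.null(truth_path)) NULL else basename(truth_path),
         seed = seed),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sidecar)
}

#' Read a movie from a TIFF stack and its JSON sidecar
#'
#' @param path TIFF path.
#' @param sidecar sidecar JSON path (default `<path>.json`).
#' @return An [scn_movie()].
#' @export
read_movie <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$dt_h)) stop("sidecar is missing `dt_h`")
  if (is.null(meta$mask)) stop("sidecar is missing `mask`")
  mask_path <- file.path(dirname(sidecar), meta$mask)
  if (!file.exists(mask_path)) stop("mask file not found: ", mask_path)
  mask <- as.matrix(utils::read.table(mask_path, sep = ",")) > 0
  dimnames(mask) <- NULL
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    frames[, , k] <- pg
  }
  off <- if (is.null(meta$value_offset)) 0 else meta$value_offset
  sc <- if (is.null(meta$value_scale)) 1 else meta$value_scale
  frames <- frames * sc + off
  if (!identical(dim(mask), dim(frames)[1:2]))
    stop("mask shape does not match the frames")
  scn_movie(frames, meta$dt_h, mask)
}

#' Write / read a single trace as tidy CSV
#'
#' Columns `time_h`, `value`; times must be uniformly spaced.
#'
#' @param ts a [rhythm_ts()].
#' @param path CSV path.
#' @return `write_trace_csv`: invisibly, the path. `read_trace_csv`: a
#'   [rhythm_ts()].
#' @export
write_trace_csv <- function(ts, path) {
  stopifnot(inherits(ts, "rhythm_ts"))
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_h", "value") %in% names(df)))
    stop("trace CSV needs columns time_h, value")
  dts <- diff(df$time_h)
  if (length(dts) < 1L || any(abs(dts - dts[1]) > 1e-6 * dts[1]))
    stop("trace times must be uniformly spaced")
  rhythm_ts(df$value, dts[1], df$time_h[1])
}

#' Write / read an activity record (CSV + JSON sidecar)
#'
#' The CSV holds one row per bin (`day`, `bin_index`, `count`); bin width,
#' start clock time and the light schedule live in the sidecar.
#'
#' @param rec an [activity_record()].
#' @param path CSV path.
#' @param sidecar sidecar JSON path (default `<path>.json`).
#' @return `write_activity_record`: invisibly, the path.
#'   `read_activity_record`: an [activity_record()].
#' @export
write_activity_record <- function(rec, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(rec, "activity_record"))
  bins_per_day <- 1440 %/% rec$bin_min
  i <- seq_along(rec$counts) - 1L
  utils::write.csv(data.frame(day = i %/% bins_per_day + 1L,
                              bin_index = i %% bins_per_day,
                              count = rec$counts),
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(bin_min = rec$bin_min, start_clock_h = rec$start_clock_h,
         light_schedule = rec$light_schedule),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_activity_record
#' @export
read_activity_record <- function(path, sidecar = paste0(path, ".json")) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  sched <- meta$light_schedule
  if (!is.null(sched) && length(sched) == 0) sched <- NULL
  activity_record(df$count[order(df$day, df$bin_index)], meta$bin_min,
                  meta$start_clock_h %||% 0, sched)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a decay course as tidy CSV
#'
#' Columns `condition`, `replicate`, `time_h`, `level`.
#'
#' @param course a [decay_course()].
#' @param path CSV path.
#' @return `write_decay_course`: invisibly, the path.
#'   `read_decay_course`: a [decay_course()].
#' @export
write_decay_course <- function(course, path) {
  stopifnot(inherits(course, "decay_course"))
  utils::write.csv(as.data.frame(course), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decay_course
#' @export
read_decay_course <- function(path) {
  decay_course(utils::read.csv(path))
}

#' Export pixel maps as tidy CSV
#'
#' One row per in-region block: 0-based `row`/`col` block anchor,
#' `period_h` (NA where not oscillating), `rel_acrophase_h`, `rhythmic`.
#'
#' @param maps an [analyze_movie()] result.
#' @param path CSV path.
#' @return Invisibly, the path.
#' @export
write_pixel_maps <- function(maps, path) {
  stopifnot(inherits(maps, "pixel_maps"))
  idx <- which(maps$region_mask, arr.ind = TRUE)
  utils::write.csv(data.frame(
    row = (idx[, 1] - 1L) * maps$binning,
    col = (idx[, 2] - 1L) * maps$binning,
    period_h = maps$period_map[idx],
    rel_acrophase_h = maps$acrophase_map[idx],
    rhythmic = maps$rhythmic_mask[idx] * 1L),
    path, row.names = FALSE)
  invisible(path)
}

#' Summary list for a pixel-map analysis
#'
#' @param maps an [analyze_movie()] result.
#' @return List suitable for JSON serialization: pixel counts,
#'   oscillating fraction, period/acrophase summaries.
#' @export
movie_summary <- function(maps) {
  stopifnot(inherits(maps, "pixel_maps"))
  out <- list(n_region = sum(maps$region_mask),
              n_oscillating = sum(maps$rhythmic_mask),
              oscillating_fraction_pct = oscillating_fraction(maps),
              alpha = maps$alpha,
              slice_period_h = maps$slice_period_h,
              reference_acrophase_h = maps$reference_acrophase_h)
  if (sum(maps$rhythmic_mask) >= 2) {
    ds_p <- distribution_stats(maps, "period")
    ds_a <- distribution_stats(maps, "acrophase")
    out$period_mean_h <- ds_p$mean
    out$period_sd_h <- ds_p$sd
    out$acrophase_circ_mean_h <- ds_a$mean
    out$acrophase_circ_sd_h <- ds_a$sd
  }
  out
}
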