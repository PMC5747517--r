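#' Bioluminescence movie
#'
#' A frame stack (height x width x frames numeric array) with its sampling
#' interval and a binary region mask delimiting the tissue (e.g. the SCN).
#' Per-pixel access yields [rhythm_ts()] objects.
#'
#' @param frames numeric array `c(height, width, n_frames)`.
#' @param dt_h hours per frame (> 0). The recording cadence used throughout
#'   this package defaults to one 55-min exposure per frame, i.e.
#'   `dt_h = 55/60`.
#' @param mask logical (or 0/1) matrix of the same height/width as the
#'   frames; `TRUE` marks in-region pixels.
#' @return An object of class `scn_movie`.
#' @export
scn_movie <- function(frames, dt_h, mask) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array (height x width x frames)")
  if (!is.numeric(dt_h) || length(dt_h) != 1L || !is.finite(dt_h) || dt_h <= 0)
    stop("`dt_h` must be a single positive number")
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!identical(dim(mask), dim(frames)[1:2]))
    stop("mask shape must equal the frame shape")
  if (dim(frames)[3] < 2L)
    stop("a movie needs at least 2 frames")
  structure(list(frames = frames, dt_h = dt_h, mask = mask),
            class = "scn_movie")
}

#' @export
print.scn_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<scn_movie> %dx%d px, %d frames, dt = %.4g h (%.1f h), %d in-mask px\n",
              d[1], d[2], d[3], x$dt_h, d[3] * x$dt_h, sum(x$mask)))
  invisible(x)
}

#' Two-lobed elliptical SCN mask
#'
#' Builds the default recording geometry: a pair of touching ellipses
#' (left and right SCN lobe) centered on the frame, mimicking the bilateral
#' outline of a coronal SCN slice.
#'
#' @param height,width frame size in pixels (default 60 x 60).
#' @param lobe_rx,lobe_ry ellipse semi-axes in pixels.
#' @return Logical matrix `height x width`.
#' @export
scn_mask <- function(height = 60, width = 60, lobe_rx = 12, lobe_ry = 20) {
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  cy <- (height + 1) / 2
  cxl <- (width + 1) / 2 - lobe_rx
  cxr <- (width + 1) / 2 + lobe_rx
  inl <- ((cols - cxl) / lobe_rx)^2 + ((rows - cy) / lobe_ry)^2 <= 1
  inr <- ((cols - cxr) / lobe_rx)^2 + ((rows - cy) / lobe_ry)^2 <= 1
  inl | inr
}

#' Extract per-pixel time series from a movie
#'
#' For each in-mask pixel (or `binning x binning` superpixel block) the
#' luminescence time course is extracted as a [rhythm_ts()]. With
#' `binning = b > 1`, frames are partitioned into `b x b` blocks anchored at
#' the top-left corner; a block contributes one series (the mean over its
#' in-mask pixels) when it contains at least one in-mask pixel.
#'
#' @param movie an [scn_movie()].
#' @param binning block edge length in pixels (default 1 = no binning).
#' @return A list with elements `row`, `col` (0-based top-left pixel
#'   coordinates of each block) and `series` (list of `rhythm_ts`).
#' @export
extract_pixel_series <- function(movie, binning = 1) {
  stopifnot(inherits(movie, "scn_movie"))
  binning <- as.integer(binning)
  d <- dim(movie$frames)
  if (binning < 1L) stop("`binning` must be >= 1")
  if (binning > min(d[1], d[2])) stop("`binning` larger than the frame")
  n_frames <- d[3]
  block_rows <- seq(1L, d[1], by = binning)
  block_cols <- seq(1L, d[2], by = binning)
  rows <- integer(0); cols <- integer(0); series <- list()
  for (br in block_rows) {
    rr <- br:min(br + binning - 1L, d[1])
    for (bc in block_cols) {
      cc <- bc:min(bc + binning - 1L, d[2])
      sub_mask <- movie$mask[rr, cc, drop = FALSE]
      if (!any(sub_mask)) next
      block <- movie$frames[rr, cc, , drop = FALSE]
      vals <- apply(block, 3, function(fr) mean(fr[sub_mask]))
      rows <- c(rows, br - 1L)
      cols <- c(cols, bc - 1L)
      series[[length(series) + 1L]] <-
        rhythm_ts(vals, movie$dt_h, 0)
    }
  }
  list(row = rows, col = cols, series = series)
}

#' Luminescence profile along a line segment
#'
#' Samples the movie along the discrete segment between two pixels
#' (nearest-pixel interpolation), giving a position x time matrix. This is
#' the space-time display used to visualize whether oscillators along a
#' transect stay in phase or drift apart.
#'
#' @param movie an [scn_movie()].
#' @param start_px,end_px integer `c(row, col)` 0-based pixel coordinates.
#' @return Numeric matrix, one row per sampled pixel ordered from
#'   `start_px` to `end_px`, one column per frame. Attribute `coords`
#'   holds the 0-based (row, col) of each row.
#' @export
line_profile <- function(movie, start_px, end_px) {
  stopifnot(inherits(movie, "scn_movie"))
  d <- dim(movie$frames)
  px <- rbind(as.numeric(start_px), as.numeric(end_px))
  if (any(px < 0) || any(px[, 1] > d[1] - 1) || any(px[, 2] > d[2] - 1))
    stop("line endpoints must lie inside the frame")
  n <- max(abs(px[2, ] - px[1, ])) + 1
  s <- if (n == 1) 0 else seq(0, 1, length.out = n)
  rr <- round(px[1, 1] + s * (px[2, 1] - px[1, 1])) + 1L
  cc <- round(px[1, 2] + s * (px[2, 2] - px[1, 2])) + 1L
  out <- matrix(0, n, d[3])
  for (i in seq_len(n)) out[i, ] <- movie$frames[rr[i], cc[i], ]
  attr(out, "coords") <- cbind(row = rr - 1L, col = cc - 1L)
  out
}
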