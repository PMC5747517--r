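#' Analysis configuration for movie pipelines
#'
#' Bundles the tunable parameters of the per-pixel analysis. By default no
#' pre-smoothing is applied before the periodogram: the rhythm statistics
#' are computed on detrended data, and smoothing (used for display and
#' extrema detection) is left to [moving_average()]. Pre-smoothing
#' autocorrelates the noise and inflates the periodogram's false-positive
#' rate, so it is opt-in.
#'
#' @param smooth_window_h moving-average window in hours applied before
#'   detrending, or `NULL` (default) for none.
#' @param detrend_window_h baseline window for [detrend()] (default 24 h).
#' @param normalize_mode `"zscore"` (default), `"range"`, or `"none"`.
#' @param min_period_h,max_period_h,step_h periodogram search grid
#'   (defaults 20-28 h, 0.1 h).
#' @param alpha significance level for the oscillating-pixel call
#'   (default 0.10).
#' @param binning pixel binning passed to [extract_pixel_series()]
#'   (default 1).
#' @param refine_period refine each oscillating pixel's period by a
#'   least-squares sinusoid fit on the `step_h` grid within one frame
#'   interval of its best fold period (default TRUE). The periodogram
#'   folds at whole numbers of frames, so at a 55-min cadence its raw
#'   period resolution is ~0.9 h; the refinement restores sub-frame
#'   resolution for the period maps.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(smooth_window_h = NULL, detrend_window_h = 24,
                            normalize_mode = c("zscore", "range", "none"),
                            min_period_h = 20, max_period_h = 28,
                            step_h = 0.1, alpha = 0.10, binning = 1,
                            refine_period = TRUE) {
  normalize_mode <- match.arg(normalize_mode)
  if (!is.null(smooth_window_h) && smooth_window_h <= 0)
    stop("`smooth_window_h` must be positive or NULL")
  if (detrend_window_h <= 0) stop("`detrend_window_h` must be positive")
  if (min_period_h >= max_period_h) stop("`min_period_h` must be < `max_period_h`")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (binning < 1) stop("`binning` must be >= 1")
  structure(list(smooth_window_h = smooth_window_h,
                 detrend_window_h = detrend_window_h,
                 normalize_mode = normalize_mode,
                 min_period_h = min_period_h, max_period_h = max_period_h,
                 step_h = step_h, alpha = alpha, binning = binning,
                 refine_period = isTRUE(refine_period)),
            class = "analysis_config")
}

# preprocess one rhythm_ts according to a config
.preprocess_ts <- function(ts, config) {
  if (!is.null(config$smooth_window_h))
    ts <- moving_average(ts, config$smooth_window_h)
  ts <- detrend(ts, config$detrend_window_h)
  if (config$normalize_mode != "none" && stats::sd(ts$values) > 0)
    ts <- normalize(ts, config$normalize_mode)
  ts
}

# vectorized Sokolove-Bushell scan over the columns of V (n x npix)
.qp_matrix <- function(V, dt_h, Ps) {
  n <- nrow(V); npix <- ncol(V)
  m <- length(Ps)
  Qp <- p <- matrix(0, m, npix)
  for (j in seq_len(m)) {
    P <- Ps[j]; K <- n %/% P; nn <- K * P
    Vs <- V[seq_len(nn), , drop = FALSE]
    Mbar <- colMeans(Vs)
    folded <- array(Vs, dim = c(P, K, npix))
    Mh <- colMeans(aperm(folded, c(2, 1, 3)))          # P x npix
    ssb <- colSums((Mh - rep(Mbar, each = P))^2)
    sst <- colSums((Vs - rep(Mbar, each = nn))^2)
    q <- ifelse(sst > 0, nn * K * ssb / sst, 0)
    Qp[j, ] <- q
    p[j, ] <- stats::pchisq(q, df = P - 1, lower.tail = FALSE)
  }
  list(Qp = Qp, p = p, p_adj = pmin(m * p, 1))
}

# refine fold-quantized period estimates by least-squares sinusoid fit on a
# fine grid within +/- one frame interval of each pixel's best fold period
.refine_periods <- function(V, t, best_period, dt_h, lo, hi, step_h) {
  out <- best_period
  for (bp in unique(best_period[!is.na(best_period)])) {
    cols <- which(!is.na(best_period) & best_period == bp)
    cand <- seq(max(lo, bp - dt_h), min(hi, bp + dt_h), by = step_h)
    if (length(cand) < 2L) next
    rss <- vapply(cand, function(p) {
      w <- 2 * pi / p
      qx <- qr(cbind(1, cos(w * t), sin(w * t)))
      colSums(qr.resid(qx, V[, cols, drop = FALSE])^2)
    }, numeric(length(cols)))
    rss <- matrix(rss, nrow = length(cols))
    out[cols] <- cand[max.col(-rss, ties.method = "first")]
  }
  out
}

# cosinor at a common period for all columns of V; returns acrophase (h)
.cosinor_matrix <- function(V, t, period_h) {
  w <- 2 * pi / period_h
  X <- cbind(1, cos(w * t), sin(w * t))
  B <- qr.coef(qr(X), V)                                # 3 x npix
  (period_h / (2 * pi) * atan2(B[3, ], B[2, ])) %% period_h
}

#' Per-pixel rhythm analysis of a movie
#'
#' Runs the full pixel pipeline: series extraction, (optional) smoothing,
#' detrending, normalization, chi-squared periodogram with the
#' familywise-controlled oscillating-pixel call at `alpha`, and cosinor
#' acrophase estimation. Period maps carry each oscillating pixel's best
#' periodogram period. Acrophases are fitted at one common period (the
#' mean best period over oscillating pixels) for every pixel and for the
#' mask-averaged reference signal, because phase differences are only
#' defined on a shared cycle; the map stores each pixel's acrophase
#' relative to that of the mask-averaged signal.
#'
#' @param movie an [scn_movie()] spanning at least
#'   `2 * max_period_h` hours.
#' @param config an [analysis_config()].
#' @return An object of class `pixel_maps`: list with block-resolution
#'   matrices `period_map` (hours, NA where not oscillating),
#'   `acrophase_map` (relative hours, NA off-mask), logical
#'   `rhythmic_mask` and `region_mask`, `alpha`,
#'   `reference_acrophase_h`, `slice_period_h`, `binning`, `row`/`col`
#'   (0-based block anchors), and `config`.
#' @export
analyze_movie <- function(movie, config = analysis_config()) {
  stopifnot(inherits(movie, "scn_movie"), inherits(config, "analysis_config"))
  d <- dim(movie$frames)
  if (d[3] * movie$dt_h < 2 * config$max_period_h)
    stop("movie must span at least two cycles of `max_period_h`")

  px <- extract_pixel_series(movie, config$binning)
  npix <- length(px$series)
  if (npix == 0L) stop("region mask is empty")
  pre <- lapply(px$series, .preprocess_ts, config = config)
  V <- vapply(pre, function(s) s$values, numeric(length(pre[[1]]$values)))
  V <- matrix(V, ncol = npix)
  t <- ts_time(pre[[1]])

  Ps <- unique(as.integer(round(
    seq(config$min_period_h, config$max_period_h, by = config$step_h) /
      movie$dt_h)))
  Ps <- Ps[Ps >= 2L & Ps <= nrow(V) %/% 2L]
  scan <- .qp_matrix(V, movie$dt_h, Ps)
  rhythmic <- apply(scan$p_adj < config$alpha, 2, any)
  best_period <- rep(NA_real_, npix)
  for (i in which(rhythmic)) {
    sig <- scan$p_adj[, i] < config$alpha
    best_period[i] <- Ps[sig][which.max(scan$Qp[sig, i])] * movie$dt_h
  }
  if (config$refine_period && any(rhythmic))
    best_period <- .refine_periods(V, t, best_period, movie$dt_h,
                                   config$min_period_h, config$max_period_h,
                                   config$step_h)
  slice_period <- if (any(rhythmic)) mean(best_period[rhythmic])
                  else (config$min_period_h + config$max_period_h) / 2

  acro <- .cosinor_matrix(V, t, slice_period)
  ref_raw <- rhythm_ts(apply(movie$frames, 3, function(fr) mean(fr[movie$mask])),
                       movie$dt_h, 0)
  ref_pre <- .preprocess_ts(ref_raw, config)
  ref_fit <- cosinor_fit(ref_pre, slice_period)
  rel_acro <- .wrap_half(acro - ref_fit$acrophase_h, slice_period)

  b <- config$binning
  nbr <- length(seq(1L, d[1], by = b)); nbc <- length(seq(1L, d[2], by = b))
  period_map <- acro_map <- matrix(NA_real_, nbr, nbc)
  rhy_mask <- region <- matrix(FALSE, nbr, nbc)
  br <- px$row %/% b + 1L; bc <- px$col %/% b + 1L
  ij <- cbind(br, bc)
  region[ij] <- TRUE
  rhy_mask[ij] <- rhythmic
  period_map[ij] <- best_period
  acro_map[ij] <- rel_acro
  structure(list(period_map = period_map, acrophase_map = acro_map,
                 rhythmic_mask = rhy_mask, region_mask = region,
                 alpha = config$alpha,
                 reference_acrophase_h = ref_fit$acrophase_h,
                 slice_period_h = slice_period, binning = b,
                 row = px$row, col = px$col, config = config,
                 dt_h = movie$dt_h),
            class = "pixel_maps")
}

#' @export
print.pixel_maps <- function(x, ...) {
  cat(sprintf("<pixel_maps> %d in-mask blocks (binning %d), %.1f%% oscillating at alpha = %.2g\n",
              sum(x$region_mask), x$binning, oscillating_fraction(x), x$alpha))
  cat(sprintf("  common acrophase period %.3g h, reference acrophase %.3g h\n",
              x$slice_period_h, x$reference_acrophase_h))
  invisible(x)
}

#' Percentage of oscillating pixels in the region
#'
#' `100 * (oscillating blocks) / (in-region blocks)`, the headline summary
#' used to compare how many SCN pixels sustain a detectable circadian
#' rhythm between genotypes.
#'
#' @param maps a [analyze_movie()] result.
#' @return Percentage in `[0, 100]`.
#' @export
oscillating_fraction <- function(maps) {
  stopifnot(inherits(maps, "pixel_maps"))
  n_region <- sum(maps$region_mask)
  if (n_region == 0L) stop("region mask is empty")
  100 * sum(maps$rhythmic_mask) / n_region
}

#' Distribution summary of a pixel map
#'
#' Mean, spread, and histogram of per-pixel periods or relative acrophases
#' over the oscillating pixels. Acrophases are circular quantities, so
#' their mean and SD use circular statistics on the common analysis
#' period.
#'
#' @param maps a [analyze_movie()] result with at least 2 oscillating
#'   pixels.
#' @param which `"period"` or `"acrophase"`.
#' @param breaks histogram break specification (passed to
#'   [graphics::hist()]).
#' @return An object of class `distribution_summary`: `n`, `mean`, `sd`
#'   (circular for acrophase), `values`, histogram `breaks`/`counts`.
#' @export
distribution_stats <- function(maps, which = c("period", "acrophase"),
                               breaks = "Sturges") {
  stopifnot(inherits(maps, "pixel_maps"))
  which <- match.arg(which)
  sel <- maps$rhythmic_mask
  if (sum(sel) < 2L) stop("need at least 2 oscillating pixels")
  if (which == "period") {
    v <- maps$period_map[sel]
    mu <- mean(v); sdev <- stats::sd(v)
  } else {
    v <- maps$acrophase_map[sel]
    mu <- .wrap_half(circular_mean_h(v, maps$slice_period_h),
                     maps$slice_period_h)
    sdev <- circular_sd_h(v, maps$slice_period_h)
  }
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  structure(list(which = which, n = sum(sel), mean = mu, sd = sdev,
                 values = v, breaks = h$breaks, counts = h$counts),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("<distribution_summary> %s: n = %d, mean = %.4g h, %sSD = %.4g h\n",
              x$which, x$n, x$mean,
              if (x$which == "acrophase") "circular " else "", x$sd))
  invisible(x)
}

#' Time course of phase synchrony across the slice
#'
#' Slides a window along the movie and, in each window, fits a cosinor at
#' the slice period to every oscillating pixel, converts the acrophases to
#' angles, and computes the Kuramoto order parameter
#' `R = |mean(exp(i * theta))|`. `R` near 1 means the cellular oscillators
#' peak together; progressive desynchronization drives `R` down toward the
#' `1/sqrt(n)` noise floor of random phases.
#'
#' @param movie an [scn_movie()].
#' @param window_h window length in hours; at least one analysis period
#'   (default 24).
#' @param step_h spacing between window starts (default 6).
#' @param config an [analysis_config()].
#' @param maps optional precomputed [analyze_movie()] result for this
#'   movie (avoids recomputation).
#' @return A [rhythm_ts()] of `R` values; sample times are window centers.
#' @export
desynchrony_course <- function(movie, window_h = 24, step_h = 6,
                               config = analysis_config(), maps = NULL) {
  stopifnot(inherits(movie, "scn_movie"))
  if (is.null(maps)) maps <- analyze_movie(movie, config)
  if (!any(maps$rhythmic_mask)) stop("no oscillating pixels")
  period <- maps$slice_period_h
  if (window_h < period - movie$dt_h)  # one-frame slack on the cycle length
    stop("`window_h` must cover at least one analysis period")

  px <- extract_pixel_series(movie, config$binning)
  pre <- lapply(px$series, .preprocess_ts, config = config)
  V <- vapply(pre, function(s) s$values, numeric(length(pre[[1]]$values)))
  b <- config$binning
  keep <- maps$rhythmic_mask[cbind(px$row %/% b + 1L, px$col %/% b + 1L)]
  V <- V[, keep, drop = FALSE]
  t <- ts_time(pre[[1]])

  wlen <- as.integer(round(window_h / movie$dt_h))
  step <- max(1L, as.integer(round(step_h / movie$dt_h)))
  starts <- seq(1L, nrow(V) - wlen + 1L, by = step)
  R <- vapply(starts, function(s) {
    rows <- s:(s + wlen - 1L)
    acro <- .cosinor_matrix(V[rows, , drop = FALSE], t[rows], period)
    Mod(mean(exp(2i * pi * acro / period)))
  }, 0)
  rhythm_ts(R, dt_h = step * movie$dt_h,
            t0_h = t[starts[1]] + (wlen - 1) * movie$dt_h / 2)
}
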