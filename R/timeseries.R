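#' Uniformly sampled rhythm time series
#'
#' The basic container for a luminescence trace, a binned activity count
#' series, or any other uniformly sampled circadian signal: a numeric value
#' vector together with the sampling interval `dt_h` (hours per sample) and
#' the time of the first sample `t0_h` (hours).
#'
#' @param values numeric vector of at least two observations.
#' @param dt_h sampling interval in hours (> 0).
#' @param t0_h time of the first sample in hours (default 0).
#' @return An object of class `rhythm_ts`.
#' @examples
#' ts <- rhythm_ts(cos(2 * pi * (0:120) / 24), dt_h = 1)
#' ts_time(ts)[1:5]
#' @export
rhythm_ts <- function(values, dt_h, t0_h = 0) {
  values <- as.numeric(values)
  if (!is.numeric(dt_h) || length(dt_h) != 1L || !is.finite(dt_h) || dt_h <= 0)
    stop("`dt_h` must be a single positive number (hours per sample)")
  if (length(values) < 2L)
    stop("a rhythm_ts needs at least 2 samples")
  if (anyNA(values))
    stop("`values` must not contain NA")
  structure(list(values = values, dt_h = dt_h, t0_h = as.numeric(t0_h)),
            class = "rhythm_ts")
}

#' @export
print.rhythm_ts <- function(x, ...) {
  cat(sprintf("<rhythm_ts> %d samples, dt = %.4g h, span = %.4g h (t0 = %.4g h)\n",
              length(x$values), x$dt_h, ts_span(x), x$t0_h))
  invisible(x)
}

#' Sample times of a rhythm series
#'
#' @param ts a [rhythm_ts()].
#' @return Numeric vector of sample times in hours.
#' @export
ts_time <- function(ts) {
  stopifnot(inherits(ts, "rhythm_ts"))
  ts$t0_h + (seq_along(ts$values) - 1) * ts$dt_h
}

#' Span of a rhythm series in hours
#'
#' Defined as `n * dt_h`, the total duration covered by the samples.
#'
#' @param ts a [rhythm_ts()].
#' @return Span in hours.
#' @export
ts_span <- function(ts) {
  stopifnot(inherits(ts, "rhythm_ts"))
  length(ts$values) * ts$dt_h
}

#' @export
as.data.frame.rhythm_ts <- function(x, ...) {
  data.frame(time_h = ts_time(x), value = x$values)
}

# centered moving mean with shrinking windows at the edges; k odd
.runmean_shrink <- function(x, k) {
  n <- length(x)
  h <- k %/% 2L
  if (h == 0L) return(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# centered mean whose effective span is exactly `w` samples: for even
# round(w) the end samples get half weight (the 2 x m moving average used
# for seasonal baselines), which nulls a periodic component whose period
# equals the window; edges shrink symmetrically
.runmean_baseline <- function(x, w) {
  k <- as.integer(round(w))
  if (k < 2L) return(x)
  if (k %% 2L == 1L) return(.runmean_shrink(x, k))
  n <- length(x)
  h <- k %/% 2L
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    if (i - h >= 1L && i + h <= n) {
      out[i] <- ((cs[i + h] - cs[i - h + 1L]) +
                   0.5 * (x[i - h] + x[i + h])) / k
    } else {
      hh <- min(i - 1L, n - i)
      out[i] <- (cs[i + hh + 1L] - cs[i - hh]) / (2L * hh + 1L)
    }
  }
  out
}

# window in hours -> nearest odd sample count (>= 1)
.window_samples <- function(window_h, dt_h) {
  k <- window_h / dt_h
  k_odd <- 2L * as.integer(round((k - 1) / 2)) + 1L
  max(1L, k_odd)
}

#' Centered moving-average smoothing
#'
#' Smooths a series with a centered moving mean. The window is given in
#' hours and converted to the nearest odd number of samples; at the record
#' boundaries the window shrinks symmetrically rather than padding, so no
#' data are fabricated and the output length equals the input length.
#'
#' @param ts a [rhythm_ts()].
#' @param window_h window width in hours; must be at least `dt_h`.
#'   The default (3 samples' worth) suppresses frame noise without
#'   flattening circadian structure.
#' @return A smoothed `rhythm_ts`.
#' @export
moving_average <- function(ts, window_h = 3 * ts$dt_h) {
  stopifnot(inherits(ts, "rhythm_ts"))
  if (!is.finite(window_h) || window_h < ts$dt_h)
    stop("`window_h` must be >= dt_h")
  k <- .window_samples(window_h, ts$dt_h)
  rhythm_ts(.runmean_shrink(ts$values, k), ts$dt_h, ts$t0_h)
}

#' Remove the slow baseline from a series
#'
#' Subtracts a centered moving average whose window defaults to one
#' circadian cycle (24 h). A window of exactly one period passes none of
#' that periodic component, so the rhythm itself is preserved while the
#' baseline drift and damping envelope are removed; the interior of the
#' detrended series has (approximately) zero mean over any full window.
#' When the window corresponds to an even number of samples, the two end
#' samples of the window get half weight (the standard centered seasonal
#' baseline), keeping the effective span exactly at the window length.
#'
#' @param ts a [rhythm_ts()].
#' @param baseline_window_h baseline window in hours (default 24).
#' @return A detrended `rhythm_ts`.
#' @export
detrend <- function(ts, baseline_window_h = 24) {
  stopifnot(inherits(ts, "rhythm_ts"))
  if (!is.finite(baseline_window_h) || baseline_window_h <= 0)
    stop("`baseline_window_h` must be positive")
  if (ts_span(ts) < baseline_window_h)
    stop("series is shorter than the baseline window")
  base <- .runmean_baseline(ts$values, baseline_window_h / ts$dt_h)
  rhythm_ts(ts$values - base, ts$dt_h, ts$t0_h)
}

#' Normalize a series
#'
#' Mode `"zscore"` centers to mean 0 and scales to SD 1; mode `"range"`
#' maps the minimum to 0 and the maximum to 1.
#'
#' @param ts a [rhythm_ts()].
#' @param mode `"zscore"` (default) or `"range"`.
#' @return A normalized `rhythm_ts`.
#' @export
normalize <- function(ts, mode = c("zscore", "range")) {
  stopifnot(inherits(ts, "rhythm_ts"))
  mode <- match.arg(mode)
  v <- ts$values
  if (mode == "zscore") {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop("cannot z-score a series with zero variance")
    out <- (v - mean(v)) / s
  } else {
    r <- range(v)
    if (r[1] == r[2])
      stop("cannot range-normalize a constant series")
    out <- (v - r[1]) / (r[2] - r[1])
  }
  rhythm_ts(out, ts$dt_h, ts$t0_h)
}
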