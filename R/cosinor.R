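#' Cosinor fit at a fixed period
#'
#' Least-squares fit of `M + A cos(2 pi (t - phi) / period_h)` via the
#' linearization `y = M + b1 cos(wt) + b2 sin(wt)`, with
#' `A = sqrt(b1^2 + b2^2)` and acrophase
#' `phi = (period_h / 2 pi) atan2(b2, b1)` mapped into `[0, period_h)`.
#' The acrophase is the time (hours after the start of the record) at
#' which the fitted cosine peaks.
#'
#' @param ts a [rhythm_ts()] spanning at least one `period_h`.
#' @param period_h fixed period of the fitted cosine, hours.
#' @return An object of class `cosinor_fit`: `mesor`, `amplitude`,
#'   `acrophase_h`, `period_h`, `rss`, `n`.
#' @examples
#' ts <- rhythm_ts(2 + cos(2 * pi * (0:47) / 24), dt_h = 1)
#' cosinor_fit(ts, 24)
#' @export
cosinor_fit <- function(ts, period_h) {
  stopifnot(inherits(ts, "rhythm_ts"))
  if (!is.finite(period_h) || period_h <= 0) stop("`period_h` must be positive")
  n <- length(ts$values)
  if (n < 3L) stop("cosinor needs at least 3 samples")
  if (ts_span(ts) < period_h)
    stop("series must span at least one period")
  t <- ts_time(ts)
  w <- 2 * pi / period_h
  X <- cbind(1, cos(w * t), sin(w * t))
  fit <- stats::lm.fit(X, ts$values)
  b <- fit$coefficients
  A <- sqrt(b[2]^2 + b[3]^2)
  phi <- unname((period_h / (2 * pi)) * atan2(b[3], b[2])) %% period_h
  if (period_h - phi < 1e-9) phi <- 0
  structure(list(mesor = unname(b[1]), amplitude = unname(A),
                 acrophase_h = phi,
                 period_h = period_h,
                 rss = sum(fit$residuals^2), n = n),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf("<cosinor fit> period %.4g h: mesor %.4g, amplitude %.4g, acrophase %.4g h (rss %.4g)\n",
              x$period_h, x$mesor, x$amplitude, x$acrophase_h, x$rss))
  invisible(x)
}

#' Circular acrophase difference between two cosinor fits
#'
#' Difference `fit - reference` wrapped into
#' `(-period/2, +period/2]` hours; positive values mean the fit peaks
#' later than the reference. Both fits must share the same period, since
#' phase differences are only defined on a common cycle.
#'
#' @param fit,reference [cosinor_fit()] objects with equal `period_h`.
#' @return Signed phase difference in hours.
#' @export
relative_acrophase <- function(fit, reference) {
  stopifnot(inherits(fit, "cosinor_fit"), inherits(reference, "cosinor_fit"))
  if (abs(fit$period_h - reference$period_h) > 1e-8)
    stop("fits have different periods; relative acrophase is undefined")
  .wrap_half(fit$acrophase_h - reference$acrophase_h, fit$period_h)
}
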