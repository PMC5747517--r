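#' Circular mean of phases expressed in hours
#'
#' Phases on a cycle of length `period_h` wrap around, so ordinary means
#' are misleading (23 h and 1 h average to 0 h, not 12 h). The circular
#' mean maps hours to angles, averages the unit vectors, and maps back.
#'
#' @param x phases in hours.
#' @param period_h cycle length in hours (default 24).
#' @return Circular mean in `[0, period_h)` hours.
#' @export
circular_mean_h <- function(x, period_h = 24) {
  ang <- 2 * pi * x / period_h
  m <- Arg(mean(exp(1i * ang)))
  out <- (m * period_h / (2 * pi)) %% period_h
  if (period_h - out < 1e-9) out <- 0
  out
}

#' Circular standard deviation of phases in hours
#'
#' The angular SD `sqrt(-2 log R)` of the mean resultant length `R`,
#' converted back to hours. Approaches the ordinary SD for tightly
#' clustered phases and saturates for uniform phases.
#'
#' @inheritParams circular_mean_h
#' @return Circular SD in hours.
#' @export
circular_sd_h <- function(x, period_h = 24) {
  ang <- 2 * pi * x / period_h
  r <- Mod(mean(exp(1i * ang)))
  r <- min(max(r, 1e-12), 1)
  sqrt(-2 * log(r)) * period_h / (2 * pi)
}

# wrap an hour difference into (-period/2, +period/2]
.wrap_half <- function(d, period_h) {
  w <- (d + period_h / 2) %% period_h - period_h / 2
  w[w <= -period_h / 2] <- w[w <= -period_h / 2] + period_h
  w
}
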