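#' Normalize a decay course to its starting level
#'
#' Divides every replicate by its own level at `t = 0`, so all replicates
#' start exactly at 1 (the convention for cycloheximide-chase courses).
#' Idempotent.
#'
#' @param course a [decay_course()].
#' @return A normalized [decay_course()].
#' @export
normalize_to_t0 <- function(course) {
  stopifnot(inherits(course, "decay_course"))
  key <- interaction(course$condition, course$replicate, drop = TRUE)
  for (k in levels(key)) {
    rows <- key == k
    l0 <- course$level[rows & course$time_h == 0]
    if (length(l0) != 1L || l0 <= 0)
      stop("each replicate needs exactly one positive t = 0 level")
    course$level[rows] <- course$level[rows] / l0
  }
  course
}

#' Fit first-order decay kinetics
#'
#' Log-linear least squares `log(level) ~ time`: with only a few chase
#' timepoints (typically 0/3/6 h) a nonlinear exponential fit is fragile,
#' while the log-linear fit is exact for clean first-order decay. The
#' course is normalized to `t = 0` first, which makes the fitted rate
#' invariant to per-replicate rescaling.
#'
#' @param course a [decay_course()] with at least 3 distinct timepoints
#'   and positive levels.
#' @return An object of class `decay_fit`: `rate_per_h` (may be <= 0 for
#'   a stable protein), `half_life_h` (`Inf` when `rate_per_h <= 0`),
#'   `se_rate`, `r_squared`, `n`.
#' @export
fit_decay <- function(course) {
  stopifnot(inherits(course, "decay_course"))
  if (length(unique(course$time_h)) < 3L)
    stop("need at least 3 timepoints to fit a decay rate")
  if (any(course$level <= 0)) stop("levels must be positive")
  course <- normalize_to_t0(course)
  fit <- stats::lm(log(level) ~ time_h, data = course)
  sm <- summary(fit)
  rate <- -unname(stats::coef(fit)["time_h"])
  structure(list(rate_per_h = rate,
                 half_life_h = if (rate > 0) log(2) / rate else Inf,
                 se_rate = sm$coefficients["time_h", "Std. Error"],
                 r_squared = sm$r.squared,
                 n = nrow(course)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay fit> rate %.4g /h (SE %.3g), half-life %s h, R^2 %.3f (n = %d)\n",
              x$rate_per_h, x$se_rate,
              if (is.finite(x$half_life_h)) sprintf("%.4g", x$half_life_h) else "Inf",
              x$r_squared, x$n))
  invisible(x)
}

#' Per-timepoint comparison of two decay courses
#'
#' After normalizing each course to `t = 0`, performs a Student's
#' two-sample two-sided t-test at every shared post-zero timepoint
#' (t = 0 is identically 1 in both courses and carries no information).
#'
#' @param a,b [decay_course()] objects measured at the same timepoints,
#'   each with at least 2 replicates.
#' @return Data frame with `time_h`, `mean_a`, `mean_b`, `statistic`,
#'   `p_value`.
#' @export
compare_courses <- function(a, b) {
  stopifnot(inherits(a, "decay_course"), inherits(b, "decay_course"))
  ta <- sort(unique(a$time_h)); tb <- sort(unique(b$time_h))
  if (!identical(ta, tb)) stop("courses have mismatched timepoints")
  if (length(unique(a$replicate)) < 2L || length(unique(b$replicate)) < 2L)
    stop("each course needs at least 2 replicates")
  a <- normalize_to_t0(a); b <- normalize_to_t0(b)
  tp <- ta[ta > 0]
  rows <- lapply(tp, function(tt) {
    va <- a$level[a$time_h == tt]; vb <- b$level[b$time_h == tt]
    if (stats::sd(c(va, vb)) == 0) {
      st <- 0; pv <- 1
    } else {
      tt_res <- stats::t.test(va, vb, var.equal = TRUE)
      st <- unname(tt_res$statistic); pv <- tt_res$p.value
    }
    data.frame(time_h = tt, mean_a = mean(va), mean_b = mean(vb),
               statistic = st, p_value = pv)
  })
  do.call(rbind, rows)
}
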