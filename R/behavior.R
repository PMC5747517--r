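#' Convert an activity record to a rhythm time series
#'
#' @param rec an [activity_record()].
#' @return A [rhythm_ts()] of counts with `dt_h = bin_min / 60`.
#' @export
as_rhythm_ts <- function(rec) {
  stopifnot(inherits(rec, "activity_record"))
  rhythm_ts(rec$counts, rec$bin_min / 60, 0)
}

#' Free-running period of an actogram
#'
#' Chi-squared periodogram estimate of the locomotor period over a range
#' of days recorded in constant darkness. The search grid is fine
#' (default 0.01 h) but the achievable resolution is set by the bin width,
#' since the statistic folds the record at whole numbers of bins.
#'
#' @param rec an [activity_record()].
#' @param day_range `c(first_day, last_day)` (1-based, inclusive) or
#'   `NULL` for the whole record; at least 7 days.
#' @param min_period_h,max_period_h,step_h periodogram search grid
#'   (defaults 20-28 h, 0.01 h).
#' @param alpha significance level (default 0.10).
#' @return Best significant period in hours, or `NA` when no period
#'   reaches significance; the full [chi_squared_periodogram()] result is
#'   attached as attribute `"periodogram"`.
#' @export
free_running_period <- function(rec, day_range = NULL, min_period_h = 20,
                                max_period_h = 28, step_h = 0.01,
                                alpha = 0.10) {
  stopifnot(inherits(rec, "activity_record"))
  bins_per_day <- 1440 %/% rec$bin_min
  n_days_total <- length(rec$counts) %/% bins_per_day
  if (is.null(day_range)) day_range <- c(1L, n_days_total)
  d0 <- day_range[1]; d1 <- day_range[2]
  if (d1 - d0 + 1 < 7) stop("need at least 7 days of record")
  if (d1 > n_days_total) stop("`day_range` exceeds the record")
  if (!is.null(rec$light_schedule)) {
    lit <- rec$light_schedule
    if (any(lit$day >= d0 & lit$day <= d1))
      warning("selected days include a light schedule; free-running period assumes DD")
  }
  idx <- ((d0 - 1L) * bins_per_day + 1L):(d1 * bins_per_day)
  ts <- rhythm_ts(rec$counts[idx], rec$bin_min / 60, 0)
  if (stats::sd(ts$values) == 0) {
    out <- NA_real_
    attr(out, "periodogram") <- NULL
    return(out)
  }
  pg <- chi_squared_periodogram(ts, min_period_h, max_period_h, step_h, alpha)
  out <- pg$best_period_h
  attr(out, "periodogram") <- pg
  out
}

#' Per-day acrophase of an activity record
#'
#' For each complete 24-h day, the cosinor acrophase of that day's counts
#' at a fixed 24-h period, reported in clock hours (hours after midnight
#' for LD records via `start_clock_h`; hours after record start when the
#' record starts at clock 0).
#'
#' @param rec an [activity_record()] with at least 1 complete day.
#' @return Numeric vector, one acrophase per day (`NA` for all-zero or
#'   constant days).
#' @export
daily_acrophase <- function(rec) {
  stopifnot(inherits(rec, "activity_record"))
  bins_per_day <- 1440 %/% rec$bin_min
  n_days <- length(rec$counts) %/% bins_per_day
  if (n_days < 1) stop("need at least one complete day")
  dt <- rec$bin_min / 60
  vapply(seq_len(n_days), function(d) {
    v <- rec$counts[((d - 1L) * bins_per_day + 1L):(d * bins_per_day)]
    if (all(v == 0) || stats::sd(v) == 0) return(NA_real_)
    fit <- cosinor_fit(rhythm_ts(v, dt, 0), 24)
    (fit$acrophase_h + rec$start_clock_h) %% 24
  }, 0)
}

#' Mean daily activity profile
#'
#' Folds the record modulo 24 h and averages the first `n_days` days
#' bin-by-bin, the standard averaged activity plot. The profile conserves
#' counts: its sum equals total counts over those days divided by
#' `n_days`.
#'
#' @param rec an [activity_record()] spanning at least `n_days`.
#' @param n_days number of days to average (default 16).
#' @return Data frame with `clock_h` (start of each bin) and `mean_count`.
#' @export
mean_daily_profile <- function(rec, n_days = 16) {
  stopifnot(inherits(rec, "activity_record"))
  bins_per_day <- 1440 %/% rec$bin_min
  if (length(rec$counts) < n_days * bins_per_day)
    stop("record shorter than `n_days`")
  m <- matrix(rec$counts[seq_len(n_days * bins_per_day)], nrow = bins_per_day)
  data.frame(clock_h = (seq_len(bins_per_day) - 1) * rec$bin_min / 60,
             mean_count = rowMeans(m))
}

#' Phase delay between two physiological rhythms
#'
#' Circularly wrapped cosinor acrophase difference `b - a` at a fixed
#' 24-h period; positive values mean `b` peaks later (is phase-delayed).
#' Both series must cover at least two days. Each series is checked for
#' rhythmicity with a chi-squared periodogram (search range capped at
#' half the span); if either fails, the estimate is still returned with a
#' warning.
#'
#' @param a,b [rhythm_ts()] objects spanning >= 48 h.
#' @return Delay in hours in `(-12, 12]`, with logical attribute
#'   `rhythmic` (one flag per series).
#' @export
metabolic_phase_delay <- function(a, b) {
  stopifnot(inherits(a, "rhythm_ts"), inherits(b, "rhythm_ts"))
  if (ts_span(a) < 48 || ts_span(b) < 48)
    stop("both series must cover at least 48 h")
  rhythmic <- vapply(list(a, b), function(ts) {
    maxp <- min(28, ts_span(ts) / 2)
    pg <- tryCatch(
      chi_squared_periodogram(ts, min_period_h = 20, max_period_h = maxp),
      error = function(e) NULL)
    !is.null(pg) && pg$rhythmic
  }, TRUE)
  if (!all(rhythmic))
    warning("series not significantly rhythmic; phase delay is a best-effort estimate")
  delay <- .wrap_half(cosinor_fit(b, 24)$acrophase_h -
                        cosinor_fit(a, 24)$acrophase_h, 24)
  attr(delay, "rhythmic") <- rhythmic
  delay
}
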