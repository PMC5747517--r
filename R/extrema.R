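#' Detect alternating peaks and troughs
#'
#' Finds local maxima and minima of a (preferably smoothed) trace, then
#' enforces strict peak/trough alternation (runs of same-kind extrema
#' collapse to the most extreme member; ties go to the earliest time) and
#' a minimum spacing (peak-trough pairs closer than `min_separation_h` are
#' treated as noise wiggles and removed). Extremum times are refined by
#' 3-point parabolic interpolation, so they need not fall on the sampling
#' grid. Plateau extrema are dated at their earliest sample.
#'
#' @param ts a [rhythm_ts()].
#' @param min_separation_h minimum time between retained extrema, hours
#'   (default 6, half of a circadian half-period).
#' @return An object of class `extrema`: data frame with columns
#'   `time_h`, `kind` (`"peak"`/`"trough"`), `value`, strictly increasing
#'   in time and strictly alternating in kind. May have zero rows.
#' @export
detect_extrema <- function(ts, min_separation_h = 6) {
  stopifnot(inherits(ts, "rhythm_ts"))
  if (min_separation_h <= 0) stop("`min_separation_h` must be positive")
  v <- ts$values
  t <- ts_time(ts)
  n <- length(v)
  s <- sign(diff(v))
  # plateaus: carry the next non-zero slope backwards so the earliest
  # plateau sample is the extremum
  nz <- which(s != 0)
  if (length(nz) == 0L)
    return(.extrema_df(numeric(0), character(0), numeric(0)))
  for (i in rev(seq_len(length(s)))) if (s[i] == 0) {
    s[i] <- if (i < length(s)) s[i + 1] else 0
  }
  idx <- integer(0); kind <- character(0)
  for (i in seq_len(n - 2L)) {
    if (s[i] > 0 && s[i + 1] < 0) { idx <- c(idx, i + 1L); kind <- c(kind, "peak") }
    if (s[i] < 0 && s[i + 1] > 0) { idx <- c(idx, i + 1L); kind <- c(kind, "trough") }
  }
  if (length(idx) == 0L)
    return(.extrema_df(numeric(0), character(0), numeric(0)))

  keep <- .alternate(idx, kind, v)
  # prune peak-trough pairs closer than the minimum separation
  repeat {
    if (length(keep$idx) < 2L) break
    gaps <- diff(t[keep$idx])
    bad <- which(gaps < min_separation_h)
    if (length(bad) == 0L) break
    drop <- c(bad[1], bad[1] + 1L)
    keep <- .alternate(keep$idx[-drop], keep$kind[-drop], v)
  }
  if (length(keep$idx) == 0L)
    return(.extrema_df(numeric(0), character(0), numeric(0)))

  # parabolic refinement of time and value
  time_h <- t[keep$idx]; value <- v[keep$idx]
  for (j in seq_along(keep$idx)) {
    i <- keep$idx[j]
    if (i <= 1L || i >= n) next
    denom <- v[i - 1] - 2 * v[i] + v[i + 1]
    if (abs(denom) < .Machine$double.eps) next
    delta <- 0.5 * (v[i - 1] - v[i + 1]) / denom
    delta <- max(-0.5, min(0.5, delta))
    time_h[j] <- t[i] + delta * ts$dt_h
    value[j] <- v[i] - 0.25 * (v[i - 1] - v[i + 1]) * delta
  }
  .extrema_df(time_h, keep$kind, value)
}

.extrema_df <- function(time_h, kind, value) {
  structure(data.frame(time_h = time_h, kind = kind, value = value,
                       stringsAsFactors = FALSE),
            class = c("extrema", "data.frame"))
}

# collapse same-kind runs to their most extreme member (earliest on ties)
.alternate <- function(idx, kind, v) {
  while (length(idx) >= 2L) {
    same <- which(kind[-1] == kind[-length(kind)])
    if (length(same) == 0L) break
    i <- same[1]
    a <- idx[i]; b <- idx[i + 1]
    better_b <- if (kind[i] == "peak") v[b] > v[a] else v[b] < v[a]
    drop <- if (better_b) i else i + 1L
    idx <- idx[-drop]; kind <- kind[-drop]
  }
  list(idx = idx, kind = kind)
}

#' Successive half-periods from an extrema sequence
#'
#' Time differences between consecutive extrema, starting at the first
#' extremum of `start_kind`: trough-to-peak, peak-to-trough, and so on.
#' In an undistorted oscillation both half-periods equal half the period;
#' waveform distortion shows up as unequal alternating values (e.g. a
#' longer trough-to-peak rise than peak-to-trough fall).
#'
#' @param ex an `extrema` object from [detect_extrema()].
#' @param start_kind `"trough"` (default) or `"peak"`.
#' @param n number of half-periods requested (default 5).
#' @return Numeric vector of half-periods in hours, named by their kind
#'   (`"trough_to_peak"` / `"peak_to_trough"`). If fewer than `n` are
#'   available, the shorter list is returned with attribute
#'   `truncated = TRUE` and a warning.
#' @export
half_periods <- function(ex, start_kind = c("trough", "peak"), n = 5) {
  stopifnot(inherits(ex, "extrema"))
  start_kind <- match.arg(start_kind)
  first <- which(ex$kind == start_kind)
  if (length(first) == 0L) {
    warning("no extremum of the requested start kind")
    out <- numeric(0); attr(out, "truncated") <- TRUE
    return(out)
  }
  times <- ex$time_h[first[1]:nrow(ex)]
  kinds <- ex$kind[first[1]:nrow(ex)]
  hp <- diff(times)
  labels <- paste0(kinds[-length(kinds)], "_to_", kinds[-1])
  truncated <- length(hp) < n
  if (truncated)
    warning(sprintf("only %d of %d half-periods available", length(hp), n))
  else { hp <- hp[seq_len(n)]; labels <- labels[seq_len(n)] }
  names(hp) <- labels
  attr(hp, "truncated") <- truncated
  hp
}
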