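# Shared fixtures and independent oracles used across the suite.

# plain cosine trace peaking at `acrophase_h`
cosine_ts <- function(period_h = 24, acrophase_h = 0, mesor = 0,
                      amplitude = 1, dt_h = 1, duration_h = 120,
                      noise_sd = 0, seed = NULL) {
  n <- round(duration_h / dt_h)
  t <- (seq_len(n) - 1) * dt_h
  v <- mesor + amplitude * cos(2 * pi * (t - acrophase_h) / period_h)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + rnorm(n, 0, noise_sd)
  }
  rhythm_ts(v, dt_h)
}

# piecewise-linear periodic wave: rises for `rise_h`, falls for `fall_h`;
# troughs at multiples of (rise_h + fall_h), first trough at t = 0
sawtooth_ts <- function(rise_h = 16, fall_h = 8, dt_h = 0.25,
                        duration_h = 120) {
  period <- rise_h + fall_h
  n <- round(duration_h / dt_h)
  t <- (seq_len(n) - 1) * dt_h
  ph <- t %% period
  v <- ifelse(ph <= rise_h, ph / rise_h, 1 - (ph - rise_h) / fall_h)
  rhythm_ts(v, dt_h)
}

# oracle: exhaustive least-squares sinusoid fit over a period grid
# (independent of the folding-based periodogram code path)
ls_best_period <- function(ts, periods_h) {
  t <- ts_time(ts)
  rss <- vapply(periods_h, function(p) {
    w <- 2 * pi / p
    X <- cbind(1, cos(w * t), sin(w * t))
    sum(qr.resid(qr(X), ts$values)^2)
  }, 0)
  periods_h[which.min(rss)]
}

# oracle: dense 1-D grid search over acrophase, amplitude/mesor profiled
# out by regression on the shifted cosine
grid_acrophase <- function(ts, period_h, step_h = 0.02) {
  t <- ts_time(ts)
  phis <- seq(0, period_h - step_h, by = step_h)
  sse <- vapply(phis, function(phi) {
    X <- cbind(1, cos(2 * pi * (t - phi) / period_h))
    qx <- qr(X)
    if (qr.coef(qx, ts$values)[2] < 0) return(Inf)  # amplitude must be >= 0
    sum(qr.resid(qx, ts$values)^2)
  }, 0)
  phis[which.min(sse)]
}

# small movie geometry used by imaging tests (keeps runtimes short)
small_movie_params <- function(duration_h = 96, ...) {
  movie_params(height = 30, width = 30, mask = scn_mask(30, 30, 6, 10),
               duration_h = duration_h, ...)
}
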