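# run code under a temporary RNG state so generators are reproducible
# without clobbering the caller's stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single integer or NULL")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Parameters of a single synthetic cellular oscillator
#'
#' Describes one damped, noisy, phase-diffusing circadian oscillator of the
#' kind seen in single-pixel PER2::LUC luminescence traces:
#' `baseline + trend_slope*t + amplitude*exp(-damping_rate*t) *
#'  cos(2*pi*(t - phase_h + D(t)) / period_h) + noise`,
#' where `D(t)` is a Gaussian random walk (one step per sample) that makes
#' initially synchronous oscillators drift apart.
#'
#' @param period_h intrinsic period in hours (> 0; default 24).
#' @param phase_h acrophase offset in hours: time of the first peak when
#'   there is no diffusion (default 0).
#' @param amplitude oscillation amplitude in luminescence units (>= 0).
#' @param damping_rate exponential amplitude damping per hour (>= 0).
#' @param baseline additive baseline in luminescence units.
#' @param trend_slope linear baseline drift, units per hour.
#' @param noise_sd SD of additive Gaussian noise in luminescence units.
#' @param phase_diffusion_sd SD (hours) of the per-sample phase random
#'   walk step.
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(period_h = 24, phase_h = 0, amplitude = 1,
                        damping_rate = 0, baseline = 0, trend_slope = 0,
                        noise_sd = 0, phase_diffusion_sd = 0) {
  if (period_h <= 0) stop("`period_h` must be positive")
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  if (damping_rate < 0) stop("`damping_rate` must be >= 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (phase_diffusion_sd < 0) stop("`phase_diffusion_sd` must be >= 0")
  structure(list(period_h = period_h, phase_h = phase_h,
                 amplitude = amplitude, damping_rate = damping_rate,
                 baseline = baseline, trend_slope = trend_slope,
                 noise_sd = noise_sd, phase_diffusion_sd = phase_diffusion_sd),
            class = "cell_params")
}

#' Simulate one cellular luminescence trace
#'
#' @param params a [cell_params()].
#' @param dt_h sampling interval in hours (> 0).
#' @param duration_h recording length in hours (> 0); the number of frames
#'   is `round(duration_h / dt_h)`.
#' @param seed integer seed or NULL.
#' @return A [rhythm_ts()]. Attribute `phase_walk_h` stores the accumulated
#'   phase-diffusion trajectory in hours.
#' @export
generate_cell_trace <- function(params, dt_h, duration_h, seed = NULL) {
  stopifnot(inherits(params, "cell_params"))
  if (!is.finite(dt_h) || dt_h <= 0) stop("`dt_h` must be positive")
  if (!is.finite(duration_h) || duration_h <= 0)
    stop("`duration_h` must be positive")
  n <- max(2L, as.integer(round(duration_h / dt_h)))
  .with_seed(seed, {
    t <- (seq_len(n) - 1) * dt_h
    walk <- if (params$phase_diffusion_sd > 0)
      cumsum(c(0, stats::rnorm(n - 1L, 0, params$phase_diffusion_sd)))
    else rep(0, n)
    v <- params$baseline + params$trend_slope * t +
      params$amplitude * exp(-params$damping_rate * t) *
      cos(2 * pi * (t - params$phase_h + walk) / params$period_h)
    if (params$noise_sd > 0) v <- v + stats::rnorm(n, 0, params$noise_sd)
    out <- rhythm_ts(v, dt_h, 0)
    attr(out, "phase_walk_h") <- walk
    out
  })
}

#' Parameters of a synthetic SCN movie
#'
#' Geometry, population heterogeneity, and noise structure of a simulated
#' single-cell bioluminescence recording. Defaults reproduce the recording
#' conditions modeled throughout the package: a 60 x 60 frame with a
#' two-lobed elliptical SCN mask, one 55-min exposure per frame for five
#' days (131 frames), and a wild-type-like oscillator population (period
#' 24 +/- 0.2 h, phase SD 0.5 h, 4.1% arrhythmic pixels, high
#' signal-to-noise).
#'
#' @param height,width frame size in pixels.
#' @param mask logical region mask (default [scn_mask()]).
#' @param dt_h hours per frame (default 55/60).
#' @param duration_h recording span in hours (default 120, i.e. 5 days);
#'   must be at least `2 * period_mean_h`.
#' @param period_mean_h,period_sd_h per-pixel period draw N(mean, sd), hours.
#' @param phase_sd_h SD of the initial acrophase draw N(0, sd), hours.
#' @param arrhythmic_fraction fraction of in-mask pixels rendered with
#'   amplitude 0 (rounded to a whole pixel count), in `[0, 1]`.
#' @param coupling_strength mean-field coupling toward the population
#'   circular-mean phase, per hour; 0 leaves oscillators independent so
#'   phase diffusion desynchronizes them.
#' @param phase_diffusion_sd per-frame phase random-walk SD in hours.
#' @param amplitude,baseline,trend_slope,damping_rate,noise_sd cellular
#'   signal parameters shared by all rhythmic pixels (see [cell_params()]).
#' @param background,background_noise_sd mean and noise SD of out-of-mask
#'   pixels.
#' @param seed integer seed or NULL.
#' @return An object of class `movie_params`.
#' @export
movie_params <- function(height = 60, width = 60,
                         mask = scn_mask(height, width),
                         dt_h = 55 / 60, duration_h = 120,
                         period_mean_h = 24, period_sd_h = 0.2,
                         phase_sd_h = 0.5, arrhythmic_fraction = 0.041,
                         coupling_strength = 0, phase_diffusion_sd = 0.05,
                         amplitude = 100, baseline = 200, trend_slope = -0.2,
                         damping_rate = 0.005, noise_sd = 5,
                         background = 20, background_noise_sd = 2,
                         seed = NULL) {
  if (dt_h <= 0) stop("`dt_h` must be positive")
  if (duration_h < 2 * period_mean_h)
    stop("`duration_h` must cover at least two mean periods")
  if (arrhythmic_fraction < 0 || arrhythmic_fraction > 1)
    stop("`arrhythmic_fraction` must lie in [0, 1]")
  mask <- as.matrix(mask); storage.mode(mask) <- "logical"
  if (!identical(dim(mask), c(as.integer(height), as.integer(width))))
    stop("mask shape must be height x width")
  if (!any(mask)) stop("region mask is empty")
  structure(list(height = height, width = width, mask = mask, dt_h = dt_h,
                 duration_h = duration_h, period_mean_h = period_mean_h,
                 period_sd_h = period_sd_h, phase_sd_h = phase_sd_h,
                 arrhythmic_fraction = arrhythmic_fraction,
                 coupling_strength = coupling_strength,
                 phase_diffusion_sd = phase_diffusion_sd,
                 amplitude = amplitude, baseline = baseline,
                 trend_slope = trend_slope, damping_rate = damping_rate,
                 noise_sd = noise_sd, background = background,
                 background_noise_sd = background_noise_sd, seed = seed),
            class = "movie_params")
}

#' Simulate an SCN bioluminescence movie with known ground truth
#'
#' In-mask pixels are independent (or mean-field coupled) damped
#' oscillators; a fixed fraction is arrhythmic (amplitude 0); out-of-mask
#' pixels carry background noise only. Phase trajectories evolve as
#' `theta[t+1] = theta[t] + omega*dt + omega*eps + K*dt*sin(theta_bar - theta)`
#' with `eps ~ N(0, phase_diffusion_sd)` in hours and `theta_bar` the
#' circular-mean phase of the rhythmic population.
#'
#' @param params a [movie_params()].
#' @return A list with `movie` (an [scn_movie()]) and `truth`, a list with
#'   per-pixel `period_map` and `acrophase_map` (hours, NA off-mask and for
#'   arrhythmic pixels), logical `rhythmic_mask`, `phase_traj` (radians,
#'   rhythmic pixels x frames), and `rhythmic_index` (their 1-based matrix
#'   indices).
#' @export
generate_scn_movie <- function(params) {
  stopifnot(inherits(params, "movie_params"))
  p <- params
  n_frames <- max(2L, as.integer(round(p$duration_h / p$dt_h)))
  idx_mask <- which(p$mask)
  n_mask <- length(idx_mask)
  n_arr <- as.integer(round(p$arrhythmic_fraction * n_mask))
  .with_seed(p$seed, {
    arr_idx <- if (n_arr > 0) sample(idx_mask, n_arr) else integer(0)
    rhy_idx <- setdiff(idx_mask, arr_idx)
    n_rhy <- length(rhy_idx)
    t <- (seq_len(n_frames) - 1) * p$dt_h

    period <- acro <- rep(NA_real_, 0)
    theta <- NULL
    if (n_rhy > 0) {
      period <- stats::rnorm(n_rhy, p$period_mean_h, p$period_sd_h)
      period <- pmax(period, 1e-3)
      acro <- stats::rnorm(n_rhy, 0, p$phase_sd_h)
      omega <- 2 * pi / period
      theta <- matrix(0, n_rhy, n_frames)
      theta[, 1] <- -omega * acro
      for (k in seq_len(n_frames - 1L)) {
        eps <- if (p$phase_diffusion_sd > 0)
          stats::rnorm(n_rhy, 0, p$phase_diffusion_sd) else 0
        step <- omega * p$dt_h + omega * eps
        if (p$coupling_strength > 0) {
          z <- mean(exp(1i * theta[, k]))
          step <- step + p$coupling_strength * p$dt_h *
            sin(Arg(z) - theta[, k])
        }
        theta[, k + 1L] <- theta[, k] + step
      }
    }

    frames <- array(0, dim = c(p$height, p$width, n_frames))
    n_px <- p$height * p$width
    for (k in seq_len(n_frames)) {
      fr <- matrix(p$background, p$height, p$width)
      if (p$background_noise_sd > 0)
        fr <- fr + matrix(stats::rnorm(n_px, 0, p$background_noise_sd),
                          p$height, p$width)
      cell_base <- p$baseline + p$trend_slope * t[k] +
        if (p$noise_sd > 0) stats::rnorm(n_mask, 0, p$noise_sd) else 0
      fr[idx_mask] <- cell_base
      if (n_rhy > 0)
        fr[rhy_idx] <- fr[rhy_idx] + p$amplitude *
          exp(-p$damping_rate * t[k]) * cos(theta[, k])
      frames[, , k] <- fr
    }

    period_map <- acro_map <- matrix(NA_real_, p$height, p$width)
    rhythmic <- matrix(FALSE, p$height, p$width)
    if (n_rhy > 0) {
      period_map[rhy_idx] <- period
      acro_map[rhy_idx] <- acro %% period
      rhythmic[rhy_idx] <- TRUE
    }
    list(movie = scn_movie(frames, p$dt_h, p$mask),
         truth = list(period_map = period_map, acrophase_map = acro_map,
                      rhythmic_mask = rhythmic, phase_traj = theta,
                      rhythmic_index = rhy_idx, params = p))
  })
}

#' Locomotor activity record
#'
#' Binned event counts from an area sensor plus the light schedule under
#' which they were recorded.
#'
#' @param counts non-negative integer vector of binned activity counts.
#' @param bin_min bin width in minutes; must divide 1440.
#' @param start_clock_h clock time (hours after midnight) of the first bin.
#' @param light_schedule `NULL` for constant darkness (DD), otherwise a
#'   data frame with columns `day`, `lights_on_h`, `lights_off_h`.
#' @return An object of class `activity_record`.
#' @export
activity_record <- function(counts, bin_min, start_clock_h = 0,
                            light_schedule = NULL) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || anyNA(counts)) stop("`counts` must be >= 0")
  if (1440 %% bin_min != 0) stop("`bin_min` must divide 1440")
  if (!is.null(light_schedule) &&
      !all(c("day", "lights_on_h", "lights_off_h") %in% names(light_schedule)))
    stop("`light_schedule` needs columns day, lights_on_h, lights_off_h")
  structure(list(counts = counts, bin_min = bin_min,
                 start_clock_h = start_clock_h,
                 light_schedule = light_schedule),
            class = "activity_record")
}

#' @export
print.activity_record <- function(x, ...) {
  cat(sprintf("<activity_record> %d bins of %d min (%.1f days), %s\n",
              length(x$counts), x$bin_min,
              length(x$counts) * x$bin_min / 1440,
              if (is.null(x$light_schedule)) "DD" else "LD schedule"))
  invisible(x)
}

#' Simulate a nocturnal actogram
#'
#' Poisson activity counts whose rate is high during the subjective night
#' (half cycle) of an internal clock advancing with period `tau_h`, and low
#' (rate divided by `night_day_ratio`) otherwise. Under a light schedule
#' with `masking = TRUE`, activity during lights-on is suppressed to zero
#' rate (negative masking).
#'
#' @param tau_h free-running period in hours, in `[20, 28]`.
#' @param n_days record length in days (default 14).
#' @param bin_min bin width in minutes; must divide 1440 (default 10).
#' @param light_schedule `NULL` (DD, default) or a data frame as in
#'   [activity_record()].
#' @param activity_level expected counts per bin during the active phase
#'   (default 20).
#' @param night_day_ratio active:rest rate ratio (default 5).
#' @param onset_h time (hours after record start) of the first activity
#'   onset (default 12).
#' @param masking suppress activity during lights-on (default TRUE).
#' @param seed integer seed or NULL.
#' @return A list with `record` (an [activity_record()]) and `truth`
#'   (list: `tau_h`, `onset_h`, per-day `acrophase_h` = subjective-night
#'   midpoints in hours after record start).
#' @export
generate_actogram <- function(tau_h, n_days = 14, bin_min = 10,
                              light_schedule = NULL, activity_level = 20,
                              night_day_ratio = 5, onset_h = 12,
                              masking = TRUE, seed = NULL) {
  if (tau_h < 20 || tau_h > 28) stop("`tau_h` must lie in [20, 28]")
  if (1440 %% bin_min != 0) stop("`bin_min` must divide 1440")
  if (activity_level < 0) stop("`activity_level` must be >= 0")
  dt <- bin_min / 60
  n <- as.integer(round(n_days * 24 / dt))
  t <- (seq_len(n) - 1) * dt
  phase <- ((t - onset_h) / tau_h) %% 1
  rate <- ifelse(phase < 0.5, activity_level, activity_level / night_day_ratio)
  if (!is.null(light_schedule) && masking) {
    clock <- t %% 24
    day <- floor(t / 24) + 1
    sched <- light_schedule[match(day, light_schedule$day), ]
    lit <- !is.na(sched$lights_on_h) &
      ((clock >= sched$lights_on_h) & (clock < sched$lights_off_h))
    rate[lit] <- 0
  }
  counts <- .with_seed(seed, stats::rpois(n, rate))
  n_cycles <- floor((max(t) - onset_h) / tau_h) + 1
  acros <- onset_h + (seq_len(max(0, n_cycles)) - 1) * tau_h + tau_h / 4
  list(record = activity_record(counts, bin_min, 0, light_schedule),
       truth = list(tau_h = tau_h, onset_h = onset_h,
                    acrophase_h = acros[acros <= max(t)]))
}

#' Simulate a pair of phase-shifted metabolic rhythms
#'
#' Two 24-h cosine rhythms (e.g. oxygen consumption in two genotypes)
#' sampled at `dt_h`, the second phase-delayed by `delay_h`.
#'
#' @param delay_h acrophase delay of the second series, hours.
#' @param dt_h sampling interval in hours (default 1, hourly averaging).
#' @param duration_h record length (default 48 h, two days).
#' @param noise_sd additive Gaussian noise SD in signal units.
#' @param seed integer seed or NULL.
#' @param mesor,amplitude cosine midline and amplitude (defaults 100, 20).
#' @param acrophase_a_h acrophase of the first series, hours (default 18,
#'   a nocturnal metabolic peak).
#' @return List with `a`, `b` ([rhythm_ts()]) and `truth`
#'   (acrophases and delay).
#' @export
generate_metabolic_pair <- function(delay_h, dt_h = 1, duration_h = 48,
                                    noise_sd = 0, seed = NULL,
                                    mesor = 100, amplitude = 20,
                                    acrophase_a_h = 18) {
  if (dt_h <= 0) stop("`dt_h` must be positive")
  n <- max(2L, as.integer(round(duration_h / dt_h)))
  t <- (seq_len(n) - 1) * dt_h
  .with_seed(seed, {
    mk <- function(acro) {
      v <- mesor + amplitude * cos(2 * pi * (t - acro) / 24)
      if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)
      rhythm_ts(v, dt_h, 0)
    }
    list(a = mk(acrophase_a_h), b = mk(acrophase_a_h + delay_h),
         truth = list(acrophase_a_h = acrophase_a_h,
                      acrophase_b_h = acrophase_a_h + delay_h,
                      delay_h = delay_h))
  })
}

#' Cycloheximide-chase decay course
#'
#' Tidy container for relative protein levels measured at fixed times after
#' translation blockade, with replicate structure.
#'
#' @param df data frame with columns `condition`, `replicate`, `time_h`,
#'   `level`. Each replicate must include `time_h == 0` with a positive
#'   level.
#' @return The data frame with class `decay_course`.
#' @export
decay_course <- function(df) {
  need <- c("condition", "replicate", "time_h", "level")
  if (!all(need %in% names(df))) stop("need columns ", paste(need, collapse = ", "))
  sp <- split(df, df$replicate)
  for (r in sp) {
    tt <- sort(unique(r$time_h))
    if (tt[1] != 0) stop("each replicate must include a t = 0 measurement")
    lv0 <- r$level[r$time_h == 0]
    if (any(lv0 <= 0)) stop("t = 0 level must be positive")
  }
  class(df) <- c("decay_course", class(df))
  df
}

#' Simulate a protein decay course
#'
#' Relative level `exp(-rate_per_h * t) * (1 + eps)` with
#' `eps ~ N(0, noise_sd)`, replicated; levels are floored at a tiny
#' positive value so log-linear fitting stays defined (keep `noise_sd`
#' well below 1).
#'
#' @param rate_per_h first-order decay rate per hour (>= 0).
#' @param times_h sampling times in hours, must include 0
#'   (default `c(0, 3, 6)`).
#' @param noise_sd relative noise SD (default 0).
#' @param n_reps number of replicates (default 3).
#' @param seed integer seed or NULL.
#' @param condition condition label (default "control").
#' @return A [decay_course()].
#' @export
generate_decay_course <- function(rate_per_h, times_h = c(0, 3, 6),
                                  noise_sd = 0, n_reps = 3, seed = NULL,
                                  condition = "control") {
  if (rate_per_h < 0) stop("`rate_per_h` must be >= 0")
  if (!0 %in% times_h) stop("`times_h` must include 0")
  times_h <- sort(unique(times_h))
  .with_seed(seed, {
    df <- expand.grid(replicate = seq_len(n_reps), time_h = times_h)
    mu <- exp(-rate_per_h * df$time_h)
    eps <- if (noise_sd > 0) stats::rnorm(nrow(df), 0, noise_sd) else 0
    df$level <- pmax(mu * (1 + eps), 1e-8)
    df$condition <- condition
    decay_course(df[, c("condition", "replicate", "time_h", "level")])
  })
}
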