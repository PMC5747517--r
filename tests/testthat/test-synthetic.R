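test_that("noiseless cell traces follow the closed-form waveform", {
  # exact cosine peaking at t = 0 and t = 24
  tr <- generate_cell_trace(cell_params(), dt_h = 1, duration_h = 48)
  t <- ts_time(tr)
  expect_equal(tr$values, cos(2 * pi * t / 24), tolerance = 1e-12)
  expect_equal(tr$values[t == 0], 1)
  expect_equal(tr$values[t == 24], 1)

  # flat baseline when amplitude is zero
  flat <- generate_cell_trace(cell_params(amplitude = 0, baseline = 5),
                              dt_h = 1, duration_h = 48)
  expect_true(all(flat$values == 5))

  # damping envelope hits amplitude * exp(-1) at t = 1/rate
  dmp <- generate_cell_trace(cell_params(damping_rate = 0.01, phase_h = 0),
                             dt_h = 0.5, duration_h = 120)
  v100 <- dmp$values[abs(ts_time(dmp) - 100) < 1e-9]
  expect_equal(v100, exp(-1) * cos(2 * pi * 100 / 24), tolerance = 1e-9)

  expect_error(generate_cell_trace(cell_params(), dt_h = 0, duration_h = 48),
               "positive")
  expect_error(generate_cell_trace(cell_params(), dt_h = 1, duration_h = -1),
               "positive")
})

test_that("generators are seed-reproducible and seeds differ", {
  a <- generate_cell_trace(cell_params(noise_sd = 1), 1, 48, seed = 3)
  b <- generate_cell_trace(cell_params(noise_sd = 1), 1, 48, seed = 3)
  c <- generate_cell_trace(cell_params(noise_sd = 1), 1, 48, seed = 4)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))

  m1 <- generate_scn_movie(small_movie_params(seed = 5))
  m2 <- generate_scn_movie(small_movie_params(seed = 5))
  expect_identical(m1$movie$frames, m2$movie$frames)
  expect_identical(m1$truth$period_map, m2$truth$period_map)

  r1 <- generate_actogram(24, seed = 9)
  r2 <- generate_actogram(24, seed = 9)
  expect_identical(r1$record$counts, r2$record$counts)
})

test_that("movie ground truth matches its stated arrhythmic fraction", {
  mk <- function(f) generate_scn_movie(small_movie_params(
    arrhythmic_fraction = f, seed = 1))
  n_mask <- sum(scn_mask(30, 30, 6, 10))

  all_off <- mk(1)
  expect_equal(sum(all_off$truth$rhythmic_mask), 0)
  # arrhythmic in-mask pixels are flat apart from noise and trend
  px <- extract_pixel_series(all_off$movie)
  amp <- vapply(px$series, function(s) diff(range(detrend(s)$values)), 0)
  expect_lt(max(amp), 8 * 5)  # well below the rhythmic amplitude of 100

  all_on <- mk(0)
  expect_equal(sum(all_on$truth$rhythmic_mask), n_mask)

  part <- mk(0.167)
  expect_equal(sum(part$truth$rhythmic_mask),
               n_mask - round(0.167 * n_mask))
  expect_true(all(part$truth$rhythmic_mask[part$movie$mask] %in% c(TRUE, FALSE)))
  expect_false(any(part$truth$rhythmic_mask & !part$movie$mask))
})

test_that("homogeneous movies share one period and phase; diffusion desynchronizes", {
  hom <- generate_scn_movie(small_movie_params(
    period_sd_h = 0, phase_sd_h = 0, phase_diffusion_sd = 0,
    arrhythmic_fraction = 0, noise_sd = 0, seed = 2))
  expect_equal(diff(range(hom$truth$period_map[hom$movie$mask])), 0)
  expect_equal(diff(range(hom$truth$acrophase_map[hom$movie$mask])), 0)

  # uncoupled phase diffusion: circular SD of tracked phases grows
  dif <- generate_scn_movie(small_movie_params(
    phase_diffusion_sd = 0.3, coupling_strength = 0,
    arrhythmic_fraction = 0, seed = 2))
  theta <- dif$truth$phase_traj
  frame_sd <- apply(theta, 2, function(a) {
    r <- Mod(mean(exp(1i * a))); sqrt(-2 * log(max(r, 1e-12)))
  })
  n_day <- round(24 / (55 / 60))
  expect_gt(mean(frame_sd[(ncol(theta) - n_day + 1):ncol(theta)]),
            mean(frame_sd[1:n_day]))
})

test_that("noiseless generated traces re-derive their ground truth exactly", {
  p <- cell_params(period_h = 23.4, phase_h = 5.2, amplitude = 2,
                   baseline = 10)
  tr <- generate_cell_trace(p, dt_h = 0.5, duration_h = 117)
  fit <- cosinor_fit(tr, 23.4)
  expect_equal(fit$acrophase_h, 5.2, tolerance = 1e-6)
  expect_equal(fit$amplitude, 2, tolerance = 1e-6)
  expect_equal(fit$mesor, 10, tolerance = 1e-6)
})

test_that("actogram generator obeys its truth and schedule", {
  # zero activity level gives an all-zero record
  z <- generate_actogram(24, activity_level = 0, seed = 1)
  expect_true(all(z$record$counts == 0))

  # tau = 25 in DD: truth acrophase drifts 1 h per cycle
  d <- generate_actogram(25, n_days = 10, seed = 1)
  expect_equal(unique(round(diff(d$truth$acrophase_h), 9)), 25)

  # entrained tau = 24 under LD with negligible noise: each day's
  # acrophase identical
  sched <- data.frame(day = 1:14, lights_on_h = 0, lights_off_h = 12)
  e <- generate_actogram(24, light_schedule = sched, activity_level = 2000,
                         seed = 1)
  acro <- daily_acrophase(e$record)
  expect_lt(max(abs(diff(acro))), 0.05)

  expect_error(generate_actogram(19), "20")
  expect_error(generate_actogram(24, bin_min = 7), "1440")
})

test_that("metabolic pair generator produces the requested phase offset", {
  same <- generate_metabolic_pair(0)
  expect_identical(same$a$values, same$b$values)

  off <- generate_metabolic_pair(6)
  cc <- ccf(off$b$values, off$a$values, lag.max = 12, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 6)
})

test_that("decay generator matches closed forms and recovers its rate", {
  stable <- generate_decay_course(0)
  expect_true(all(stable$level == 1))

  halving <- generate_decay_course(log(2) / 3, n_reps = 1)
  expect_equal(halving$level, c(1, 0.5, 0.25), tolerance = 1e-12)

  expect_error(generate_decay_course(0.1, times_h = c(3, 6)), "include 0")

  fits <- vapply(1:50, function(s) {
    f <- fit_decay(generate_decay_course(log(2) / 3, noise_sd = 0.05,
                                         seed = s))
    abs(f$rate_per_h - log(2) / 3) <= 2 * f$se_rate
  }, TRUE)
  expect_gte(sum(fits), 42)  # ~2 SE covers roughly 92-95% at these df
})
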