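test_that("moving average preserves constants, length, and identity windows", {
  const <- rhythm_ts(rep(3, 50), 1)
  expect_equal(moving_average(const, 5)$values, rep(3, 50))

  ts <- cosine_ts(noise_sd = 0.2, seed = 1, duration_h = 48)
  expect_identical(moving_average(ts, ts$dt_h)$values, ts$values)
  expect_length(moving_average(ts, 5)$values, length(ts$values))

  tri <- rhythm_ts(c(0, 3, 6), 1)
  expect_equal(moving_average(tri, 3)$values[2], 3)

  expect_error(moving_average(ts, 0.5), "dt_h")
})

test_that("moving average and normalize commute with time shift", {
  v <- cos(2 * pi * (0:99) / 24) + 0.3 * sin(2 * pi * (0:99) / 7)
  a <- rhythm_ts(v, 1, t0_h = 0)
  b <- rhythm_ts(v, 1, t0_h = 13)
  expect_equal(moving_average(a, 5)$values, moving_average(b, 5)$values)
  expect_equal(normalize(a)$values, normalize(b)$values)
})

test_that("detrending removes baseline and trend but keeps the rhythm", {
  # interior of a pure cosine survives a one-period baseline window
  ts <- cosine_ts(duration_h = 120)
  d <- detrend(ts)
  interior <- 25:95
  expect_equal(d$values[interior], ts$values[interior], tolerance = 0.02)

  # cosine + linear trend: interior residual matches the pure cosine
  t <- 0:119
  trended <- rhythm_ts(cos(2 * pi * t / 24) + 0.5 * t + 7, 1)
  dt <- detrend(trended)
  rms <- sqrt(mean((dt$values[interior] - cos(2 * pi * t / 24)[interior])^2))
  expect_lt(rms, 0.01 * sqrt(mean(cos(2 * pi * t / 24)[interior]^2)))

  # constant series detrends to zero
  expect_equal(detrend(rhythm_ts(rep(4, 48), 1))$values[13:36], rep(0, 24))

  expect_error(detrend(rhythm_ts(1:10, 1), 24), "shorter")
})

test_that("detrend of constant + rhythm equals detrend of the rhythm", {
  ts <- cosine_ts(duration_h = 96)
  shifted <- rhythm_ts(ts$values + 11, 1)
  expect_equal(detrend(shifted)$values, detrend(ts)$values, tolerance = 1e-12)
})

test_that("normalization modes behave as documented", {
  ts <- cosine_ts(noise_sd = 0.5, seed = 2, duration_h = 72)
  z <- normalize(ts, "zscore")
  expect_equal(mean(z$values), 0, tolerance = 1e-12)
  expect_equal(sd(z$values), 1, tolerance = 1e-12)

  # affine invariance of the z-score
  aff <- rhythm_ts(3 * ts$values - 17, 1)
  expect_equal(normalize(aff)$values, z$values, tolerance = 1e-10)

  r <- normalize(rhythm_ts(c(0, 10, 5), 1), "range")
  expect_equal(r$values, c(0, 1, 0.5))

  expect_error(normalize(rhythm_ts(rep(2, 10), 1)), "zero variance")
})

test_that("pixel series extraction honors mask, count, and binning", {
  fr <- array(seq_len(2 * 2 * 5), dim = c(2, 2, 5))
  mv <- scn_movie(fr, 1, matrix(TRUE, 2, 2))
  px <- extract_pixel_series(mv)
  expect_length(px$series, 4)

  # checkerboard mask: one series per TRUE pixel
  mask <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  px2 <- extract_pixel_series(scn_movie(fr, 1, mask))
  expect_length(px2$series, sum(mask))

  # binning spanning the whole mask: single series of masked frame means
  px3 <- extract_pixel_series(scn_movie(fr, 1, mask), binning = 2)
  expect_length(px3$series, 1)
  means <- apply(fr, 3, function(f) mean(f[mask]))
  expect_equal(px3$series[[1]]$values, means)
  expect_equal(px3$row, 0L)

  expect_error(extract_pixel_series(mv, binning = 3), "larger")
})

test_that("line profiles sample the nearest pixels from start to end", {
  fr <- array(5, dim = c(8, 8, 4))
  mv <- scn_movie(fr, 1, matrix(TRUE, 8, 8))
  lp <- line_profile(mv, c(3, 0), c(3, 7))
  expect_equal(dim(lp), c(8, 4))
  expect_true(all(lp == 5))

  # single-pixel line equals that pixel's series
  fr2 <- array(rnorm(8 * 8 * 4), dim = c(8, 8, 4))
  mv2 <- scn_movie(fr2, 1, matrix(TRUE, 8, 8))
  lp2 <- line_profile(mv2, c(2, 5), c(2, 5))
  expect_equal(as.numeric(lp2[1, ]), fr2[3, 6, ])

  expect_error(line_profile(mv, c(0, 0), c(8, 0)), "inside")
})

test_that("profile rows stay in phase on synchronized movies and diverge under diffusion", {
  sync <- generate_scn_movie(small_movie_params(
    phase_sd_h = 0, period_sd_h = 0, phase_diffusion_sd = 0,
    arrhythmic_fraction = 0, noise_sd = 1, seed = 3))
  desy <- generate_scn_movie(small_movie_params(
    phase_sd_h = 0, period_sd_h = 0, phase_diffusion_sd = 0.4,
    arrhythmic_fraction = 0, noise_sd = 1, seed = 3))

  spread_late <- function(sim) {
    lp <- line_profile(sim$movie, c(14, 6), c(14, 23))
    co <- attr(lp, "coords")
    keep <- sim$movie$mask[cbind(co[, "row"] + 1, co[, "col"] + 1)]
    lp <- lp[keep, , drop = FALSE]
    half <- ncol(lp) %/% 2
    late <- (half + 1):ncol(lp)
    acr <- apply(lp[, late], 1, function(v) {
      ts <- detrend(rhythm_ts(v, sim$movie$dt_h))
      cosinor_fit(ts, 24)$acrophase_h
    })
    circular_sd_h(acr, 24)
  }
  expect_gt(spread_late(desy), spread_late(sync) + 0.5)
})
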