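test_that("synchronized noiseless movies give uniform maps near zero relative phase", {
  sim <- generate_scn_movie(small_movie_params(
    period_sd_h = 0, phase_sd_h = 0, phase_diffusion_sd = 0,
    arrhythmic_fraction = 0, noise_sd = 0, background_noise_sd = 0,
    seed = 1))
  maps <- analyze_movie(sim$movie)
  expect_equal(oscillating_fraction(maps), 100)
  p <- maps$period_map[maps$region_mask]
  expect_lt(diff(range(p)), 0.11)
  expect_equal(mean(p), 24, tolerance = 0.15)
  expect_lt(max(abs(maps$acrophase_map[maps$region_mask])), 0.1)
})

test_that("fully arrhythmic movies yield an (almost) empty rhythmic mask", {
  # noiseless arrhythmic pixels are exactly flat: no pixel can be called
  flat <- generate_scn_movie(small_movie_params(
    arrhythmic_fraction = 1, noise_sd = 0, background_noise_sd = 0,
    seed = 2))
  maps0 <- analyze_movie(flat$movie)
  expect_equal(sum(maps0$rhythmic_mask), 0)
  expect_equal(oscillating_fraction(maps0), 0)
  expect_error(distribution_stats(maps0, "period"), "2 oscillating")

  # with photon noise the call rate stays below the alpha = 10% ceiling
  noisy <- generate_scn_movie(small_movie_params(arrhythmic_fraction = 1,
                                                 seed = 2))
  expect_lt(oscillating_fraction(analyze_movie(noisy$movie)), 10)
})

test_that("per-pixel period estimates track ground truth on heterogeneous movies", {
  sim <- generate_scn_movie(small_movie_params(
    arrhythmic_fraction = 0, period_sd_h = 0.4, phase_sd_h = 0.5,
    phase_diffusion_sd = 0, noise_sd = 20, duration_h = 120, seed = 11))
  maps <- analyze_movie(sim$movie)
  sel <- maps$rhythmic_mask & sim$truth$rhythmic_mask
  expect_gt(sum(sel), 100)
  expect_gt(cor(maps$period_map[sel], sim$truth$period_map[sel]), 0.9)
})

test_that("estimated period spread grows with generator period SD", {
  sds <- c(0.1, 0.3, 0.6)
  est <- vapply(sds, function(s) {
    sim <- generate_scn_movie(small_movie_params(
      arrhythmic_fraction = 0, period_sd_h = s, phase_diffusion_sd = 0,
      seed = 21))
    maps <- analyze_movie(sim$movie)
    distribution_stats(maps, "period")$sd
  }, 0)
  expect_identical(order(est), 1:3)
})

test_that("oscillating fraction is monotone non-increasing in alpha", {
  sim <- generate_scn_movie(small_movie_params(arrhythmic_fraction = 0.3,
                                               seed = 4))
  f_strict <- oscillating_fraction(
    analyze_movie(sim$movie, analysis_config(alpha = 0.01)))
  f_loose <- oscillating_fraction(
    analyze_movie(sim$movie, analysis_config(alpha = 0.10)))
  expect_lte(f_strict, f_loose)
  expect_gte(f_strict, 0); expect_lte(f_loose, 100)
})

test_that("analysis is deterministic given movie and config", {
  sim <- generate_scn_movie(small_movie_params(seed = 6))
  m1 <- analyze_movie(sim$movie)
  m2 <- analyze_movie(sim$movie)
  expect_identical(m1$period_map, m2$period_map)
  expect_identical(m1$acrophase_map, m2$acrophase_map)
})

test_that("phase-spread genotype contrast is detected by the variance F-test", {
  ps <- vapply(1:20, function(s) {
    wt <- analyze_movie(generate_scn_movie(small_movie_params(
      phase_sd_h = 0.5, arrhythmic_fraction = 0, seed = 900 + s))$movie)
    ko <- analyze_movie(generate_scn_movie(small_movie_params(
      phase_sd_h = 2, arrhythmic_fraction = 0, seed = 950 + s))$movie)
    variance_f_test(ko$acrophase_map[ko$rhythmic_mask],
                    wt$acrophase_map[wt$rhythmic_mask])$p_value
  }, 0)
  expect_gte(sum(ps < 1e-4), 19)
})

test_that("desynchrony order parameter tracks truth and declines under diffusion", {
  sim <- generate_scn_movie(small_movie_params(
    phase_diffusion_sd = 0.3, coupling_strength = 0,
    arrhythmic_fraction = 0, phase_sd_h = 0.3, seed = 31))
  maps <- analyze_movie(sim$movie)
  R <- desynchrony_course(sim$movie, maps = maps)
  expect_true(all(R$values >= 0 & R$values <= 1))
  n <- length(R$values)
  expect_gt(mean(R$values[1:3]), mean(R$values[(n - 2):n]))

  # against the order parameter of the generator's own phase trajectories
  theta <- sim$truth$phase_traj
  R_truth <- apply(theta, 2, function(a) Mod(mean(exp(1i * a))))
  t_frames <- (seq_len(ncol(theta)) - 1) * sim$movie$dt_h
  R_truth_at <- vapply(ts_time(R), function(tc) {
    mean(R_truth[abs(t_frames - tc) <= 12])
  }, 0)
  expect_lt(mean(abs(R$values - R_truth_at)), 0.15)

  # synchronized control stays near 1
  syn <- generate_scn_movie(small_movie_params(
    phase_diffusion_sd = 0, phase_sd_h = 0.2, period_sd_h = 0,
    arrhythmic_fraction = 0, seed = 32))
  Rs <- desynchrony_course(syn$movie)
  expect_gt(min(Rs$values), 0.9)
})

test_that("summary export reflects the analysis", {
  sim <- generate_scn_movie(small_movie_params(seed = 8))
  maps <- analyze_movie(sim$movie)
  sm <- movie_summary(maps)
  expect_equal(sm$n_region, sum(maps$region_mask))
  expect_equal(sm$oscillating_fraction_pct, oscillating_fraction(maps))
  expect_true(sm$period_sd_h >= 0)
})
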