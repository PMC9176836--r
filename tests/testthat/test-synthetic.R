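test_that("stimulus generator produces the specified ramp and oscillation", {
  stim <- gen_stimulus(18, 21, osc_amp_C = 0, duration_s = 300)
  expect_length(stim$temperature_C, 300)
  expect_equal(stim$temperature_C[1], 18)
  expect_equal(stim$temperature_C[300], 21)
  expect_equal(diff(stim$temperature_C), rep(3 / 299, 299))

  withosc <- gen_stimulus(18, 21, osc_amp_C = 0.5, duration_s = 300)
  expect_equal(withosc$temperature_C[1], 18)  # sine is 0 at t = 0
  expect_equal(withosc$temperature_C - stim$temperature_C,
               0.5 * sin(2 * pi * 0.033 * stim$time_s))

  expect_error(gen_stimulus(18, 21, duration_s = 0), "positive")
  expect_error(gen_stimulus(18, 21, duration_s = 300, frame_rate_Hz = -1),
               "positive")
})

test_that("oscillation dominates the detrended stimulus spectrum at 0.033 Hz", {
  stim <- gen_stimulus(15, 24, osc_freq_Hz = 0.033, osc_amp_C = 0.5,
                       duration_s = 400)
  resid <- stats::residuals(stats::lm(stim$temperature_C ~ stim$time_s))
  n <- length(resid)
  p <- Mod(stats::fft(resid))^2
  f <- (seq_len(n) - 1) / n
  half <- f > 0 & f <= 0.5
  f_peak <- f[half][which.max(p[half])]
  expect_lt(abs(f_peak - 0.033), 1 / n + 1e-12)
})

test_that("AFD trace follows the threshold-gated first-order model", {
  # gate never opens: stimulus entirely below threshold
  stim <- gen_stimulus(15, 18, osc_amp_C = 0, duration_s = 100)
  cfg <- simulation_config(afd_threshold_C = 19, noise_sd = 0, drift_amp = 0)
  expect_equal(gen_afd_trace(stim, cfg), rep(cfg$baseline_F, 100))

  # temperature step above threshold: exact first-order rise
  step_stim <- gen_stimulus(18, 18, osc_amp_C = 0, duration_s = 200)
  step_stim$temperature_C[101:200] <- 21
  act <- afd_activity(step_stim, cfg)
  expect_equal(act[1:100], rep(0, 100))
  j <- seq_len(100)
  analytic <- cfg$afd_gain * 2 * (1 - exp(-j / cfg$kinetic_tau_s))
  expect_equal(act[100 + j], analytic, tolerance = 1e-12)
  expect_equal(act[200], cfg$afd_gain * 2, tolerance = 1e-8)
})

test_that("seed changes noise realizations but not the noiseless component", {
  stim <- sync_stimulus()
  cfg1 <- simulation_config(seed = 1, noise_sd = 2)
  cfg2 <- simulation_config(seed = 2, noise_sd = 2)
  f1 <- gen_afd_trace(stim, cfg1)
  f2 <- gen_afd_trace(stim, cfg2)
  expect_false(identical(f1, f2))
  cfg1q <- simulation_config(seed = 1, noise_sd = 0)
  cfg2q <- simulation_config(seed = 2, noise_sd = 0)
  expect_identical(gen_afd_trace(stim, cfg1q), gen_afd_trace(stim, cfg2q))
  # same seed, same config: bit-identical
  expect_identical(f1, gen_afd_trace(stim, cfg1))
})

test_that("AIY coupling controls its dependence on AFD", {
  stim <- sync_stimulus()
  act <- afd_activity(stim, simulation_config())

  # coupling 1, zero lag: identical activity
  cfg1 <- simulation_config(coupling = 1, coupling_lag_s = 0)
  expect_identical(aiy_activity(act, cfg1), act)

  # coupling 0: activity correlation with AFD is ~0 over seeds
  r <- vapply(1:100, function(s) {
    cfg0 <- simulation_config(seed = s, coupling = 0)
    stats::cor(act, aiy_activity(act, cfg0))
  }, numeric(1))
  expect_lt(abs(mean(r)), 0.05)
  expect_lt(mean(abs(r)), 0.15)

  # lag too long errors
  cfgl <- simulation_config(coupling_lag_s = 400)
  expect_error(aiy_activity(act, cfgl), "trace length")
})

test_that("the lag sign convention puts a delayed AIY at positive lags", {
  set.seed(42)
  broadband <- abs(stats::rnorm(300))  # rough activity, sharp autocorrelation
  cfg <- simulation_config(coupling = 1, coupling_lag_s = 3)
  aiy <- aiy_activity(broadband, cfg)
  a <- broadband - mean(broadband)
  b <- aiy - mean(aiy)
  bf <- brute_xcorr(a, b)
  # near-full lags are single-product noise; search within |m| <= 50
  expect_equal(brute_argmax_lag(bf, 50), 3)
  sm <- synchrony_metrics(cross_correlation(a, b), max_lag_s = 50)
  expect_equal(sm$lag_at_max_s, 3)
})

test_that("cohorts are labelled, sized and seed-deterministic", {
  cfg_wf <- simulation_config(seed = 7, coupling = 0.9, duration_s = 150)
  cfg_st <- simulation_config(seed = 8, coupling = 0.1, duration_s = 150)
  stim <- sync_stimulus(150)
  coh <- gen_cohort(cfg_wf, cfg_st, n_per_group = 5, stimulus = stim)
  expect_length(coh, 10)
  expect_equal(sum(vapply(coh, `[[`, "", "feeding_state") == "well_fed"), 5)
  expect_true(all(vapply(coh, function(r) !is.null(r$truth), logical(1))))
  coh2 <- gen_cohort(cfg_wf, cfg_st, n_per_group = 5, stimulus = stim)
  expect_identical(coh, coh2)
  expect_error(gen_cohort(cfg_wf, cfg_st, n_per_group = 0, stimulus = stim),
               ">= 1")
})

test_that("growing a cohort does not reshuffle earlier animals", {
  cfg <- simulation_config(seed = 3, duration_s = 150)
  stim <- sync_stimulus(150)
  small <- gen_cohort(cfg, cfg, n_per_group = 2, stimulus = stim)
  large <- gen_cohort(cfg, cfg, n_per_group = 4, stimulus = stim)
  expect_identical(small[[1]]$F_afd, large[[1]]$F_afd)
  expect_identical(small[[2]]$F_aiy, large[[2]]$F_aiy)
})

test_that("drift is separable from the stimulus band by the trend filter", {
  t <- 0:399
  d <- thermosync:::drift_profile(t, 0.1)
  expect_lt(power_above(d, 0.03), 0.01)
})

test_that("mean downstream C(0) is non-decreasing in coupling", {
  stim <- sync_stimulus()
  filt <- design_trend_filter(filter_spec())
  mean_c0 <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(cp) {
    c0 <- vapply(1:50, function(s) {
      cfg <- simulation_config(seed = s, coupling = cp)
      rec <- dual_recording(stim, gen_afd_trace(stim, cfg),
                            gen_aiy_trace(afd_activity(stim, cfg), stim, cfg),
                            feeding_state = "well_fed")
      pair <- preprocess_recording(rec, filt = filt)
      synchrony_metrics(cross_correlation(pair))$c0
    }, numeric(1))
    mean(c0)
  }, numeric(1))
  expect_true(all(diff(mean_c0) >= 0))
})

test_that("plate counts follow the relaxing mixture and always sum to n", {
  p0 <- gen_plate_counts(30, t_hours = 0, tc_section = 8, seed = 1)
  expect_equal(p0$counts, c(0, 0, 0, 0, 0, 0, 0, 30))

  # uniform limit: expected index 4.5
  idx_inf <- vapply(1:200, function(s)
    ttx_score(gen_plate_counts(100, t_hours = 1000, tc_section = 8,
                               relax_tau_hours = 4, seed = s))$index,
    numeric(1))
  expect_lt(abs(mean(idx_inf) - 4.5), 0.05)

  # half-life: expected index midway between 8 and 4.5
  idx_half <- vapply(1:200, function(s)
    ttx_score(gen_plate_counts(100, t_hours = 4 * log(2), tc_section = 8,
                               relax_tau_hours = 4, seed = s))$index,
    numeric(1))
  expect_lt(abs(mean(idx_half) - 6.25), 0.1)

  for (s in 1:20) {
    p <- gen_plate_counts(57, t_hours = s / 3, tc_section = 5, seed = s)
    expect_equal(sum(p$counts), 57)
    expect_equal(sum(ttx_score(p)$fractions), 1, tolerance = 1e-12)
  }
  expect_error(gen_plate_counts(30, 1, tc_section = 9), "1..8")
  expect_error(gen_plate_counts(0, 1, tc_section = 8), ">= 1")
})
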