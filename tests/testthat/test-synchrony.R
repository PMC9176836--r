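test_that("cross-correlation reproduces hand-computed cases exactly", {
  cc <- cross_correlation(c(1, -1, 1, -1), c(1, -1, 1, -1))
  expect_equal(cc$values[cc$lags_s == 0], 1)
  expect_equal(cc$values[cc$lags_s == 1], -1)
  expect_equal(cc$values[cc$lags_s == -1], -1)

  cc2 <- cross_correlation(c(1, 0, 0, 0), c(0, 0, 1, 0))
  expect_equal(cc2$unnormalized[cc2$lags_s == 2], 1)
  expect_equal(cc2$values[cc2$lags_s == 2], 0.5)
  expect_equal(cc2$values[cc2$lags_s %in% c(0, 1, 3)], c(0, 0, 0))

  expect_error(cross_correlation(1:4, 1:5), "equal length")
  expect_error(cross_correlation(1, 1), "2 samples")
})

test_that("implementation matches the naive double-loop oracle", {
  set.seed(21)
  for (i in 1:30) {
    n <- sample(2:64, 1)
    x <- stats::rnorm(n)
    y <- stats::rnorm(n)
    cc <- cross_correlation(x, y)
    bf <- brute_xcorr(x, y)
    expect_equal(cc$lags_s, bf$lags)
    expect_equal(cc$values, bf$values, tolerance = 1e-12)
    expect_equal(cc$unnormalized, bf$unnormalized, tolerance = 1e-12)
    # normalization invariant
    expect_equal(cc$values, cc$unnormalized / (n - abs(cc$lags_s)))
  }
})

test_that("exchange symmetry C_AB(m) = C_BA(-m) holds on random inputs", {
  set.seed(5)
  for (i in 1:10) {
    x <- stats::rnorm(40)
    y <- stats::rnorm(40)
    ab <- cross_correlation(x, y)
    ba <- cross_correlation(y, x)
    expect_equal(ab$values, rev(ba$values), tolerance = 1e-12)
  }
})

test_that("cross-correlation agrees with an independent covariance routine", {
  set.seed(31)
  x <- stats::rnorm(128)
  y <- stats::rnorm(128)
  x <- x - mean(x)
  y <- y - mean(y)
  cc <- cross_correlation(x, y)
  # ccf() demeans and scales by 1/N at every lag; on centred inputs its
  # covariance at lag -m equals the unnormalized sum / N
  cv <- stats::ccf(x, y, lag.max = 20, plot = FALSE, type = "covariance")
  for (m in -20:20) {
    expect_equal(cc$unnormalized[cc$lags_s == m] / 128,
                 cv$acf[cv$lag == -m], tolerance = 1e-10)
  }
})

test_that("synchrony metrics extract C(0) and the argmax lag with tie-breaks", {
  mk <- function(vals) {
    n <- (length(vals) + 1) / 2
    structure(list(lags_s = seq(-(n - 1), n - 1), values = vals,
                   unnormalized = vals, n_samples = n, window = NULL,
                   labels = list()),
              class = "correlogram")
  }
  sm <- synchrony_metrics(mk(c(0, 1, 0.5, 1, 0)))   # tie at -1 and +1
  expect_equal(sm$lag_at_max_s, -1)
  sm2 <- synchrony_metrics(mk(c(1, 0.5, 1, 0.5, 1)))  # tie at -2, 0, +2
  expect_equal(sm2$lag_at_max_s, 0)
  expect_equal(sm2$c_max, 1)
  expect_gte(sm2$c_max, sm2$c0)

  zero <- cross_correlation(stats::rnorm(10), rep(0, 10))
  smz <- synchrony_metrics(zero)
  expect_equal(smz$c0, 0)
  expect_equal(smz$c_max, 0)
})

test_that("identical white-noise signals peak at zero lag", {
  # restricted to |m| <= N/2: the near-full lags average over a handful of
  # products and their argmax is pure noise for any signal
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    x <- stats::rnorm(100)
    synchrony_metrics(cross_correlation(x, x), max_lag_s = 50)$lag_at_max_s == 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("argmax agrees with brute force on generated coupled pairs", {
  stim <- sync_stimulus()
  cfg <- simulation_config(seed = 5, coupling = 1, coupling_lag_s = 3,
                           noise_sd = 0, drift_amp = 0)
  act <- afd_activity(stim, cfg)
  aiy <- aiy_activity(act, cfg)
  a <- act[101:400] - mean(act[101:400])
  b <- aiy[101:400] - mean(aiy[101:400])
  sm <- synchrony_metrics(cross_correlation(a, b))
  expect_equal(sm$lag_at_max_s, brute_argmax_lag(brute_xcorr(a, b)))
})

test_that("group means of C(0) increase strictly with coupling", {
  stim <- sync_stimulus()
  filt <- design_trend_filter(filter_spec())
  group_c0 <- vapply(c(0.1, 0.5, 0.9), function(cp) {
    cfg <- simulation_config(seed = 17, coupling = cp)
    mean(vapply(1:20, function(k) {
      rec <- dual_recording(
        stim, gen_afd_trace(stim, cfg, animal = k),
        gen_aiy_trace(afd_activity(stim, cfg), stim, cfg, animal = k),
        feeding_state = "well_fed")
      synchrony_metrics(cross_correlation(preprocess_recording(rec, filt = filt)))$c0
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(group_c0) > 0))
})

test_that("cohort summaries aggregate per group with SEM conventions", {
  one <- data.frame(feeding_state = "well_fed", c0 = 0.4, lag_at_max_s = 0)
  s1 <- cohort_summary(one)
  expect_equal(s1$mean_c0, 0.4)
  expect_true(is.na(s1$sem_c0))

  two <- data.frame(feeding_state = rep(c("well_fed", "starved"), each = 3),
                    c0 = rep(c(0.5, 0.1), each = 3),
                    lag_at_max_s = rep(0, 6))
  s2 <- cohort_summary(two)
  expect_equal(s2$mean_c0[s2$feeding_state == "well_fed"], 0.5)
  expect_equal(s2$mean_c0[s2$feeding_state == "starved"], 0.1)
  expect_equal(s2$sem_c0, c(0, 0))
  expect_equal(s2$n, c(3, 3))

  expect_error(cohort_summary(two, "nonexistent_label"), "unknown label")
})

test_that("mean correlograms average per-animal curves", {
  c1 <- cross_correlation(c(1, 0, 0), c(1, 0, 0))
  c2 <- cross_correlation(c(0, 1, 0), c(0, 1, 0))
  mc <- mean_correlogram(list(c1, c2))
  expect_equal(mc$values, (c1$values + c2$values) / 2)
  expect_equal(mc$values, mc$unnormalized / (3 - abs(mc$lags_s)))
})
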