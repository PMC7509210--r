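test_that("xcorr_normalized matches brute force and its symmetries", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(40:64, 1)
    L <- sample(5:16, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    fast <- xcorr_normalized(x, y, L)
    expect_equal(unname(fast), xcorr_oracle(x, y, L), tolerance = 1e-12)
    rev_ <- xcorr_normalized(y, x, L)
    expect_equal(unname(fast), rev(unname(rev_)), tolerance = 1e-12)
    expect_true(all(abs(fast) <= 1 + 1e-12))
  }
  x <- rnorm(64)
  self <- xcorr_normalized(x, x, 10)
  expect_equal(unname(self["0"]), 1, tolerance = 1e-12)
  expect_equal(which.max(self), 11L, ignore_attr = TRUE)
  expect_error(xcorr_normalized(rep(1, 50), rnorm(50), 5), "degeneracy")
  expect_error(xcorr_normalized(rnorm(10), rnorm(9), 2), "equal length")
})

test_that("estimate_delay follows the lead/lag sign convention", {
  fs <- 100
  set.seed(12)
  base <- abs(fft_smooth_noise(6000)) + 0.1
  # torque magnitude is a delayed copy of the envelope: muscle leads
  d <- 30L  # 300 ms
  env <- base
  torque <- c(rep(0, d), base[1:(length(base) - d)])
  res <- estimate_delay(env, torque, fs, max_lag_ms = 1000)
  expect_equal(res$tau_ms, -300, tolerance = 1000 / fs)
  expect_false(res$boundary)

  # envelope is a delayed copy of the torque: muscle lags (co-contraction)
  d2 <- 10L
  env2 <- c(rep(0, d2), base[1:(length(base) - d2)])
  res2 <- estimate_delay(env2, base, fs, max_lag_ms = 1000)
  expect_equal(res2$tau_ms, +100, tolerance = 1000 / fs)

  # swapping the inputs negates the delay
  res3 <- estimate_delay(torque, env, fs, max_lag_ms = 1000)
  expect_equal(res3$tau_ms, -res$tau_ms, tolerance = 1000 / fs)
})

test_that("estimate_delay is invariant to positive affine transforms", {
  fs <- 100
  set.seed(14)
  base <- abs(fft_smooth_noise(4000)) + 0.2
  torque <- c(rep(0, 15), base[1:3985])
  r0 <- estimate_delay(base, torque, fs, max_lag_ms = 500)
  r1 <- estimate_delay(4 * base + 1, torque, fs, max_lag_ms = 500)
  expect_equal(r1$tau_ms, r0$tau_ms)
  expect_equal(r1$rho_at_tau, r0$rho_at_tau, tolerance = 1e-9)
})

test_that("zero-lag optimum and boundary flag behave", {
  set.seed(15)
  x <- abs(fft_smooth_noise(2000)) + 0.1
  res <- estimate_delay(x, x, 100, max_lag_ms = 200)
  expect_equal(res$tau_ms, 0)
  expect_equal(res$rho_at_tau, 1, tolerance = 1e-12)

  # a shift beyond the window parks the optimum at the edge (the smooth
  # autocorrelation ramps toward the true lag)
  y <- c(rep(0, 60), x[1:1940])
  res2 <- estimate_delay(x, y, 100, max_lag_ms = 300)
  expect_true(res2$boundary)
})

test_that("delays are recovered on noisy synthetic channels", {
  cfg <- sim_config(n_subjects = 1, duration_s = 60, fs = 1000, seed = 33,
                    subject_variability = 0)
  tor <- generate_torque(cfg)
  specs <- replicate(10, muscle_spec(0.4, 0.4, 0), simplify = FALSE)
  specs[[2]] <- muscle_spec(0.4, 0.4, d_ms = 300)
  sim <- generate_emg(cfg, tor$torque, specs = specs, seed = 44)
  env <- emg_envelope(sim$emg[2, ], 1000)
  env_d <- decimate_signal(env, 1000, 100)
  tq_d <- decimate_signal(tor$torque, 1000, 100)
  res <- estimate_delay(env_d$x, tq_d$x, 100, max_lag_ms = 1000)
  expect_equal(res$tau_ms, -300, tolerance = 20)
  # noiseless ground-truth envelope recovers the injected lead exactly
  gt_env <- decimate_signal(sim$envelopes[2, ], 1000, 100)
  res_gt <- estimate_delay(gt_env$x, tq_d$x, 100, max_lag_ms = 1000)
  expect_equal(res_gt$tau_ms, -300, tolerance = 1000 / 100)
})
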