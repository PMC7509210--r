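test_that("direction_correlation is exact on self-correlated input", {
  fs <- 100
  t <- (0:(60 * fs - 1)) / fs
  torque <- 2 * sin(2 * pi * t / 10)
  segs <- segment_directions(torque, fs, segmentation_params(theta = 0.1))
  env <- abs(torque)
  for (dir in c("cw", "ccw")) {
    expect_equal(direction_correlation(env, torque, segs, dir, fs), 1,
                 tolerance = 1e-9)
  }
})

test_that("correlation maximum is shift-invariant within the window", {
  fs <- 100
  set.seed(2)
  y <- abs(fft_smooth_noise(3000))
  shift <- 20L  # 200 ms at 100 Hz
  x <- c(y[(shift + 1):length(y)], y[1:shift])  # circular shift keeps support
  segs <- whole_span_segs(length(y), "cw", fs)
  r <- direction_correlation(x, y, segs, "cw", fs,
                             correlation_params(max_lag_ms = 500))
  expect_equal(r, 1, tolerance = 1e-6)
})

test_that("independent series yield small correlations (Monte-Carlo null)", {
  fs <- 100
  n <- 60 * fs
  set.seed(99)
  worst <- 0
  for (i in 1:50) {
    env <- abs(rnorm(n))
    torque <- rnorm(n)
    segs <- whole_span_segs(n, "cw", fs)
    r <- direction_correlation(env, torque, segs, "cw", fs)
    worst <- max(worst, r)
  }
  expect_lt(worst, 0.2)
})

test_that("direction_correlation is invariant to positive affine scaling", {
  fs <- 100
  set.seed(8)
  torque <- fft_smooth_noise(4000)
  env <- abs(torque) + 0.1 * abs(rnorm(4000))
  segs <- segment_directions(torque, fs, segmentation_params(theta = 0.05))
  r0 <- direction_correlation(env, torque, segs, "cw", fs)
  r1 <- direction_correlation(3 * env + 2, torque, segs, "cw", fs)
  r2 <- direction_correlation(env, 5 * torque, segs, "cw", fs)
  expect_equal(r1, r0, tolerance = 1e-9)
  expect_equal(r2, r0, tolerance = 1e-9)
})

test_that("coverage precondition names the missing direction", {
  fs <- 100
  torque <- rep(1, 500)  # never negative: no ccw segments
  segs <- segment_directions(torque, fs, segmentation_params(theta = 0.1))
  expect_error(direction_correlation(abs(torque) + rnorm(500), torque, segs,
                                     "ccw", fs),
               "coverage error.*ccw")
})

test_that("strength classification uses a strict 0.75 threshold", {
  expect_identical(classify_strength(0.76), "strong")
  expect_identical(classify_strength(0.75), "not_strong")
  expect_identical(classify_strength(0.20), "not_strong")
  expect_error(classify_strength(1.2), "domain error")
  expect_error(classify_strength(-0.1), "domain error")
})

test_that("amplitude statistic averages the envelope per direction", {
  segs <- segment_directions(c(rep(1, 100), rep(-1, 100)), fs = 100,
                             segmentation_params(theta = 0.1, min_dur_s = 0.5))
  env_const <- rep(0.5, 200)
  expect_equal(amplitude_statistic(env_const, segs, "cw"), 0.5)
  env_split <- c(rep(0, 100), rep(1, 100))
  expect_equal(amplitude_statistic(env_split, segs, "cw"), 0)
  expect_equal(amplitude_statistic(env_split, segs, "ccw"), 1)
  no_ccw <- segs[segs$direction == "cw", ]
  expect_error(amplitude_statistic(env_const, no_ccw, "ccw"), "coverage")
})

test_that("contribution ratios normalize the r*a products", {
  expect_equal(contribution_ratios(rep(0.8, 10), rep(0.3, 10)), rep(0.1, 10))
  expect_equal(contribution_ratios(c(0.8, 0.4), c(0.5, 0.25)), c(0.8, 0.2))
  set.seed(3)
  for (i in 1:20) {
    cs <- contribution_ratios(runif(10), runif(10, 0, 2))
    expect_equal(sum(cs), 1, tolerance = 1e-9)
    expect_true(all(cs >= 0))
  }
  expect_error(contribution_ratios(numeric(10), runif(10)), "degenerate")
  expect_error(contribution_ratios(runif(3), runif(4)), "aligned")
})

test_that("sign-flip permutation test matches its contract", {
  r <- runif(8, 0.5, 0.9)
  expect_equal(direction_dependence_test(r, r), 1)
  set.seed(10)
  cw <- rnorm(20, 0.8, 0.05)
  ccw <- rnorm(20, 0.3, 0.05)
  expect_lt(direction_dependence_test(cw, ccw, seed = 1), 0.001)
  expect_error(direction_dependence_test(0.5, 0.6), "sample-size")
  expect_error(direction_dependence_test(runif(5), runif(4)), "pairing")
})

test_that("exhaustive branch agrees with a Monte-Carlo estimate", {
  set.seed(6)
  cw <- rnorm(10, 0.6, 0.1)
  ccw <- cw + rnorm(10, 0.08, 0.05)
  p_exact <- direction_dependence_test(cw, ccw)
  # independent oracle: plain Monte-Carlo sign flips
  d <- ccw - cw
  obs <- abs(mean(d))
  set.seed(123)
  hits <- sum(replicate(40000, abs(mean(d * sample(c(-1, 1), 10, TRUE)))) >=
                obs - 1e-12)
  p_mc <- hits / 40000
  expect_equal(p_exact, p_mc, tolerance = 0.02)
})
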