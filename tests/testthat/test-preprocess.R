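test_that("envelope of a pure tone matches the rectified-sine mean", {
  fs <- 1000
  t <- (0:(30 * fs - 1)) / fs
  x <- sin(2 * pi * 100 * t)
  env <- emg_envelope(x, fs)
  expect_true(all(env >= 0))
  expect_length(env, length(x))
  core <- env[(2 * fs):(28 * fs)]  # steady state away from edges
  # 5% slack covers the discrete sampling of |sin| at 10 samples/cycle
  expect_equal(mean(core), 2 / pi, tolerance = 0.05)
})

test_that("envelope is positively homogeneous and zero on zero input", {
  fs <- 1000
  set.seed(1)
  x <- rnorm(4000)
  e1 <- emg_envelope(x, fs)
  e3 <- emg_envelope(3 * x, fs)
  expect_equal(e3, 3 * e1, tolerance = 1e-9)
  expect_equal(emg_envelope(numeric(4000), fs), numeric(4000))
  # bounded by max |raw| after transients
  expect_lte(max(e1[500:3500]), max(abs(x)))
})

test_that("envelope rejects bad sampling rates and short inputs", {
  expect_error(emg_envelope(rnorm(4000), fs = 800), "parameter error")
  expect_error(emg_envelope(rnorm(100), fs = 1000), "short")
  expect_error(preprocess_params(bp_low = 0), "parameter error")
  expect_error(preprocess_params(env_cutoff = 30), "parameter error")
})

test_that("normalization methods behave per contract", {
  env <- c(0.1, 0.25, 0.5, 0.4)
  n1 <- normalize_envelope(env, "trial_max")
  expect_equal(max(n1), 1)
  expect_equal(normalize_envelope(5 * env, "trial_max"), n1)  # scale invariant
  expect_equal(normalize_envelope(env, "reference_value", ref = 2), env / 2)
  expect_error(normalize_envelope(numeric(10), "trial_max"), "degenerate")
  expect_error(normalize_envelope(env, "reference_value"), "ref")
})

test_that("segmentation labels runs by sign with dead band and min duration", {
  segs <- segment_directions(c(1, 1, 1, -1, -1, -1), fs = 1,
                             segmentation_params(theta = 0.1, min_dur_s = 2))
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$start, c(1L, 4L))
  expect_equal(segs$end, c(4L, 7L))
  expect_equal(segs$direction, c("cw", "ccw"))

  # short blips are discarded
  x <- c(rep(1, 10), -1, rep(1, 10))
  s2 <- segment_directions(x, fs = 1, segmentation_params(theta = 0.1,
                                                          min_dur_s = 3))
  expect_equal(s2$direction, c("cw", "cw"))

  expect_warning(s0 <- segment_directions(numeric(100), fs = 100),
                 "no steering episodes")
  expect_equal(nrow(s0), 0L)
})

test_that("cw/ccw durations are balanced for a sinusoidal torque", {
  fs <- 100
  t <- (0:(60 * fs - 1)) / fs
  x <- sin(2 * pi * t / 10)
  segs <- segment_directions(x, fs, segmentation_params(theta = 0.05))
  dur <- tapply(segs$end - segs$start, segs$direction, sum)
  expect_lt(abs(dur[["cw"]] - dur[["ccw"]]) / sum(dur), 0.02)
  # default dead band keeps most samples labeled
  segs_d <- segment_directions(x, fs)
  expect_gte(sum(segs_d$end - segs_d$start) / length(x), 0.8)
})

test_that("segmentation is label-antisymmetric", {
  set.seed(4)
  for (rep in 1:5) {
    x <- fft_smooth_noise(2000)
    a <- segment_directions(x, 100, segmentation_params(theta = 0.1))
    b <- segment_directions(-x, 100, segmentation_params(theta = 0.1))
    expect_equal(a$start, b$start)
    expect_equal(a$end, b$end)
    expect_equal(a$direction, ifelse(b$direction == "cw", "ccw", "cw"))
  }
})
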