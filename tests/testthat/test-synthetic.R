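test_that("active torque is bounded, sign-balanced and deterministic", {
  cfg <- sim_config(n_subjects = 1, duration_s = 60, fs = 1000,
                    torque_amplitude = 2, torque_period_s = 10, seed = 11)
  a <- generate_torque(cfg)
  b <- generate_torque(cfg)
  expect_identical(a$torque, b$torque)
  expect_lte(max(abs(a$torque)), 2 * (1 + 1))
  expect_equal(mean(a$torque), 0, tolerance = 1e-10)
  n_cw <- sum(a$torque > 0)
  n_ccw <- sum(a$torque < 0)
  expect_lt(abs(n_cw - n_ccw) / length(a$torque), 0.02)
})

test_that("passive torque is band-limited noise at the requested scale", {
  cfg <- sim_config(n_subjects = 1, duration_s = 60, fs = 1000,
                    task = "passive", torque_amplitude = 2,
                    disturbance_bandwidth_Hz = 0.5, seed = 5)
  a <- generate_torque(cfg)
  expect_equal(stats::sd(a$torque), 1, tolerance = 1e-9)  # amplitude / 2
  # energy above the corner should be negligible
  sp <- Mod(stats::fft(a$torque))^2
  f <- (seq_along(sp) - 1) / length(sp) * 1000
  hi <- f > 1 & f < 500
  expect_lt(sum(sp[hi]) / sum(sp[f < 500 & f > 0]), 0.01)
})

test_that("invalid configs are rejected", {
  expect_error(sim_config(torque_amplitude = 0), "config error")
  expect_error(sim_config(n_subjects = 0), "config error")
  expect_error(sim_config(duration_s = 0.5), "config error")
  expect_error(sim_config(hand_position = "0130", arm_mode = "both"),
               "config error")
  cfg <- sim_config(n_subjects = 1, duration_s = 2, fs = 2000, seed = 1)
  expect_silent(generate_emg(cfg, generate_torque(cfg)$torque))
  cfg500 <- tryCatch(sim_config(duration_s = 10, fs = 500), error = identity)
  if (!inherits(cfg500, "error")) {
    expect_error(generate_emg(cfg500, numeric(5000)), "fs")
  }
  specs0 <- replicate(10, muscle_spec(0, 0, 0, b = 0), simplify = FALSE)
  cfg0 <- sim_config(n_subjects = 1, duration_s = 2, muscle_specs = specs0,
                     seed = 1)
  expect_error(generate_emg(cfg0, generate_torque(cfg0)$torque),
               "no active muscle")
})

test_that("ground-truth envelope respects direction-dependent gains", {
  specs <- replicate(10, muscle_spec(0.3, 0.3, 0), simplify = FALSE)
  specs[[1]] <- muscle_spec(g_cw = 0, g_ccw = 0.6, d_ms = 0)
  cfg <- sim_config(n_subjects = 1, duration_s = 20, fs = 1000,
                    muscle_specs = specs, seed = 9)
  tor <- generate_torque(cfg)
  sim <- generate_emg(cfg, tor$torque)
  cw <- tor$torque > 0.1
  ccw <- tor$torque < -0.1
  expect_gt(mean(sim$envelopes[1, ccw]), mean(sim$envelopes[1, cw]))
})

test_that("rectified raw EMG tracks the ground-truth envelope", {
  cfg <- sim_config(n_subjects = 1, duration_s = 60, fs = 1000, seed = 21)
  tor <- generate_torque(cfg)
  sim <- generate_emg(cfg, tor$torque)
  # mean of |envelope * carrier| = envelope * E|carrier|, E|N(0,1)| = sqrt(2/pi)
  for (i in c(1L, 6L)) {
    slope <- mean(abs(sim$emg[i, ])) / mean(sim$envelopes[i, ])
    expect_equal(slope, sqrt(2 / pi), tolerance = 0.05)
  }
  # raw EMG is zero-mean where the envelope is flat (baseline-only muscle)
  specs <- replicate(10, muscle_spec(0, 0, 0, b = 0.02), simplify = FALSE)
  cfgb <- sim_config(n_subjects = 1, duration_s = 20, muscle_specs = specs,
                     seed = 3)
  simb <- generate_emg(cfgb, generate_torque(cfgb)$torque)
  expect_lt(abs(mean(simb$emg[1, ])), 3 * 0.02 / sqrt(20000 / 430))
})

test_that("cohorts are reproducible and variability behaves", {
  cfg <- sim_config(n_subjects = 4, duration_s = 2, fs = 1000, seed = 7)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$trials[[3]]$emg, c2$trials[[3]]$emg)
  expect_identical(c1$ground_truth, c2$ground_truth)

  cfg0 <- sim_config(n_subjects = 3, duration_s = 2, subject_variability = 0,
                     seed = 7)
  c0 <- generate_cohort(cfg0)
  gt <- c0$ground_truth
  expect_equal(stats::sd(gt$d_ms[gt$muscle == "MB1"]), 0)
  expect_equal(stats::sd(gt$g_ccw[gt$muscle == "MB2"]), 0)

  cfgv <- sim_config(n_subjects = 8, duration_s = 2, subject_variability = 0.1,
                     seed = 7)
  cv <- generate_cohort(cfgv)
  gtv <- cv$ground_truth
  expect_gt(stats::sd(gtv$d_ms[gtv$muscle == "MB1"]), 0)
  expect_gt(stats::sd(gtv$g_cw[gtv$muscle == "MB6"]), 0)
})

test_that("written cohort directory round-trips through read_trial", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_subjects = 2, duration_s = 2, fs = 1000, seed = 13)
  co <- generate_cohort(cfg)
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  back <- read_trial(file.path(dir, "S002.csv"))
  expect_equal(back$torque, co$trials[[2]]$torque, tolerance = 1e-12)
  expect_equal(back$emg, co$trials[[2]]$emg, tolerance = 1e-12)
})
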