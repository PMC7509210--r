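#' Per-muscle generative specification
#'
#' The synthetic EMG model couples each muscle's activation envelope to
#' the steering torque with direction-dependent gains: the true envelope
#' is
#' \deqn{e(t) = b + g_{cw} \max(T(t + d), 0) + g_{ccw} \max(-T(t + d), 0)}
#' where the advance by the lead time `d` (in ms) makes the envelope
#' precede the torque when `d > 0`, the generative counterpart of a
#' negative measured EMG-to-torque delay. The raw EMG is the envelope
#' multiplied by a unit-variance band-limited (20-450 Hz) Gaussian
#' carrier scaled by `sigma`.
#'
#' @param g_cw,g_ccw dimensionless gains (>= 0) coupling clockwise /
#'   counterclockwise torque magnitude to the envelope.
#' @param d_ms lead time in ms (envelope precedes torque when positive).
#' @param b baseline envelope in mV (>= 0).
#' @param sigma carrier scale (> 0).
#' @return list of class `muscle_spec`.
#' @export
muscle_spec <- function(g_cw, g_ccw, d_ms = 0, b = 0.02, sigma = 1) {
  vals <- c(g_cw = g_cw, g_ccw = g_ccw, d_ms = d_ms, b = b, sigma = sigma)
  if (any(!is.finite(vals))) stop("muscle_spec fields must be finite", call. = FALSE)
  if (g_cw < 0 || g_ccw < 0 || b < 0) {
    stop("gains and baseline must be >= 0", call. = FALSE)
  }
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  structure(as.list(vals), class = "muscle_spec")
}

#' Default 10-muscle generative table
#'
#' Emulates the activation structure seen in upper-limb steering: for
#' the both-arm montage, the right pectoralis major (clavicular) and
#' deltoid anterior (channels 1-2) are counterclockwise agonists while
#' their left-arm counterparts (channels 6-7) are clockwise agonists;
#' the remaining muscles couple weakly. For the single-arm montage the
#' first three channels are strong and the rest weak, with a
#' counterclockwise bias. Lead times of the key muscles sit in the
#' 300-420 ms range; weak muscles near zero.
#'
#' @param arm_mode `"both"` or `"single"`.
#' @return list of 10 [muscle_spec]s.
#' @export
default_muscle_specs <- function(arm_mode = "both") {
  mk <- function(gcw, gccw, d) muscle_spec(g_cw = gcw, g_ccw = gccw, d_ms = d)
  if (arm_mode == "both") {
    list(mk(0.25, 0.80, 330), mk(0.20, 0.70, 400),  # MB1 MB2: right, ccw agonists
         mk(0.15, 0.30, 150), mk(0.20, 0.20, 100),  # MB3 MB4
         mk(0.10, 0.10, 0),                         # MB5
         mk(0.80, 0.25, 330), mk(0.70, 0.20, 400),  # MB6 MB7: left, cw agonists
         mk(0.15, 0.15, 50), mk(0.10, 0.20, 0), mk(0.10, 0.10, 0))
  } else {
    list(mk(0.45, 0.85, 350), mk(0.40, 0.75, 450),  # MS1 MS2
         mk(0.40, 0.60, 200), mk(0.15, 0.15, 100),
         mk(0.30, 0.30, 100), mk(0.10, 0.10, 0),
         mk(0.25, 0.30, 150), mk(0.10, 0.15, 0),
         mk(0.20, 0.25, 100), mk(0.25, 0.30, 50))
  }
}

#' Simulation configuration for a synthetic cohort
#'
#' Defaults mirror the study design being emulated: 60-s trials at
#' 1 kHz, a +/-2 N·m steering effort, 10-s steering period for the
#' active target-following task or a 0.5-Hz band-limited disturbance for
#' the passive task, and 10% between-subject variability on gains and
#' lead times.
#'
#' @param n_subjects number of subjects (cohort size).
#' @param duration_s trial duration in seconds.
#' @param fs sampling rate in Hz (>= 1000 so the 20-450 Hz carrier band
#'   is representable).
#' @param task `"active"` or `"passive"`.
#' @param arm_mode `"both"` or `"single"`.
#' @param hand_position grip code valid for `arm_mode`.
#' @param muscle_specs list of 10 [muscle_spec]s.
#' @param torque_amplitude peak effort scale in N·m (> 0).
#' @param torque_period_s steering period for the active task, seconds.
#' @param disturbance_bandwidth_Hz low-pass corner of the passive
#'   disturbance torque.
#' @param subject_variability relative jitter applied per subject:
#'   log-normal (sd on the log scale) on gains, additive Gaussian with
#'   sd `subject_variability * 100` ms on lead times.
#' @param seed integer seed; a fixed seed makes the cohort byte-identical.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 22, duration_s = 60, fs = 1000,
                       task = "active", arm_mode = "both",
                       hand_position = "0300",
                       muscle_specs = default_muscle_specs(arm_mode),
                       torque_amplitude = 2, torque_period_s = 10,
                       disturbance_bandwidth_Hz = 0.5,
                       subject_variability = 0.1, seed = 1L) {
  if (n_subjects < 1) stop("config error: n_subjects must be >= 1", call. = FALSE)
  if (torque_amplitude <= 0) {
    stop("config error: torque_amplitude must be > 0", call. = FALSE)
  }
  if (duration_s * fs < 1000) {
    stop("config error: duration_s * fs must be >= 1000 samples", call. = FALSE)
  }
  if (!task %in% c("active", "passive")) stop("config error: bad task", call. = FALSE)
  if (!hand_position %in% hand_positions_for(arm_mode)) {
    stop("config error: hand_position invalid for arm_mode", call. = FALSE)
  }
  if (length(muscle_specs) != 10L ||
      !all(vapply(muscle_specs, inherits, logical(1), "muscle_spec"))) {
    stop("config error: muscle_specs must be 10 muscle_spec objects", call. = FALSE)
  }
  if (torque_period_s <= 0 || disturbance_bandwidth_Hz <= 0) {
    stop("config error: torque_period_s and disturbance_bandwidth_Hz must be > 0",
         call. = FALSE)
  }
  if (subject_variability < 0) {
    stop("config error: subject_variability must be >= 0", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), duration_s = duration_s,
                 fs = fs, task = task, arm_mode = arm_mode,
                 hand_position = hand_position, muscle_specs = muscle_specs,
                 torque_amplitude = torque_amplitude,
                 torque_period_s = torque_period_s,
                 disturbance_bandwidth_Hz = disturbance_bandwidth_Hz,
                 subject_variability = subject_variability,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a steering torque and angle trace
#'
#' Active task: a zero-mean, sign-balanced sum of two odd harmonics,
#' `A (sin wt + 0.5 sin 3wt)` with `w = 2*pi / torque_period_s`, giving
#' alternating clockwise/counterclockwise episodes (positive torque =
#' clockwise). Passive task: Gaussian disturbance torque low-passed at
#' `disturbance_bandwidth_Hz`, rescaled to SD `torque_amplitude / 2`.
#' The angle is a scaled leaky integral of the torque (carried for
#' interchange; unused by the analysis stages, which segment on torque).
#'
#' @param config a [sim_config].
#' @param seed optional seed overriding `config$seed`.
#' @return list with `torque`, `angle`, `time`, `fs`.
#' @export
generate_torque <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(round(config$duration_s * config$fs))
  t <- (seq_len(n) - 1L) / config$fs
  torque <- with_seed(seed, {
    if (config$task == "active") {
      w <- 2 * pi / config$torque_period_s
      config$torque_amplitude * (sin(w * t) + 0.5 * sin(3 * w * t))
    } else {
      z <- stats::rnorm(n)
      zf <- fft_filter(z, config$fs, low = NULL,
                       high = config$disturbance_bandwidth_Hz)
      zf / stats::sd(zf) * (config$torque_amplitude / 2)
    }
  })
  # leaky integrator: ~5 s time constant, 30 deg per N.m.s
  lam <- exp(-1 / (5 * config$fs))
  angle <- 30 * stats::filter(torque / config$fs, lam, method = "recursive")
  list(torque = torque, angle = as.numeric(angle), time = t, fs = config$fs)
}

shift_advance <- function(x, k) {
  # y[t] = x[t + k] (advance when k > 0), zero-padded at the edges
  n <- length(x)
  if (k == 0L) return(x)
  if (abs(k) >= n) return(numeric(n))
  if (k > 0L) c(x[(k + 1L):n], numeric(k)) else c(numeric(-k), x[1:(n + k)])
}

#' Generate the EMG matrix for one subject
#'
#' Implements the envelope model of [muscle_spec]: per muscle, the true
#' envelope is baseline plus direction-gated, gain-scaled torque
#' magnitude advanced by the lead time; the raw channel is that envelope
#' multiplied by a fresh unit-variance 20-450 Hz Gaussian carrier scaled
#' by `sigma`. Ground truth (envelopes, realized specs) is returned
#' alongside for recovery tests.
#'
#' @param config a [sim_config] (uses its `muscle_specs` unless `specs`
#'   is given, e.g. subject-jittered ones).
#' @param torque torque series from [generate_torque].
#' @param specs optional list of 10 realized [muscle_spec]s.
#' @param seed seed for the carriers.
#' @return list with `emg` (10 x N), `envelopes` (10 x N ground truth),
#'   `specs`.
#' @export
generate_emg <- function(config, torque, specs = config$muscle_specs,
                         seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (config$fs < 1000) {
    stop("config error: fs must be >= 1000 Hz (20-450 Hz carrier band)",
         call. = FALSE)
  }
  active <- vapply(specs, function(s) s$g_cw + s$g_ccw + s$b, numeric(1))
  if (all(active <= 0)) {
    stop("config error: no active muscle (all gains and baselines zero)",
         call. = FALSE)
  }
  n <- length(torque)
  env <- matrix(0, nrow = 10L, ncol = n)
  emg <- matrix(0, nrow = 10L, ncol = n)
  with_seed(seed, {
    for (i in 1:10) {
      s <- specs[[i]]
      k <- as.integer(round(s$d_ms / 1000 * config$fs))
      ts <- shift_advance(torque, k)
      env[i, ] <- s$b + s$g_cw * pmax(ts, 0) + s$g_ccw * pmax(-ts, 0)
      w <- fft_filter(stats::rnorm(n), config$fs, low = 20, high = 450)
      w <- w / stats::sd(w)
      emg[i, ] <- env[i, ] * (s$sigma * w)
    }
  })
  list(emg = emg, envelopes = env, specs = specs)
}

jitter_specs <- function(specs, variability, seed) {
  with_seed(seed, lapply(specs, function(s) {
    muscle_spec(
      g_cw  = s$g_cw * exp(stats::rnorm(1, 0, variability)),
      g_ccw = s$g_ccw * exp(stats::rnorm(1, 0, variability)),
      d_ms  = s$d_ms + stats::rnorm(1, 0, variability * 100),
      b = s$b, sigma = s$sigma)
  }))
}

#' Generate a synthetic cohort of trials with ground truth
#'
#' Each subject gets independently jittered muscle parameters
#' (multiplicative log-normal on gains, additive Gaussian on lead times,
#' controlled by `subject_variability`) drawn from seed-derived
#' substreams, then a fresh torque trace and EMG. The ground-truth table
#' records every realized parameter so downstream recovery tests can
#' compare estimates against what was injected.
#'
#' @param config a [sim_config].
#' @return list with `trials` (list of [steer_trial]) and `ground_truth`
#'   (data.frame: subject_id, muscle, g_cw, g_ccw, d_ms, b, sigma).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  labels <- default_channel_labels(config$arm_mode)
  trials <- vector("list", config$n_subjects)
  gt <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%03d", s)
    specs <- jitter_specs(config$muscle_specs, config$subject_variability,
                          derive_seed(config$seed, 3L * s))
    tor <- generate_torque(config, seed = derive_seed(config$seed, 3L * s + 1L))
    sim <- generate_emg(config, tor$torque, specs = specs,
                        seed = derive_seed(config$seed, 3L * s + 2L))
    trials[[s]] <- steer_trial(
      subject_id = sid, arm_mode = config$arm_mode,
      hand_position = config$hand_position, task = config$task,
      fs = config$fs, time = tor$time, torque = tor$torque,
      angle = tor$angle, emg = sim$emg, channel_labels = labels)
    gt[[s]] <- data.frame(
      subject_id = sid, muscle = labels,
      g_cw = vapply(specs, `[[`, numeric(1), "g_cw"),
      g_ccw = vapply(specs, `[[`, numeric(1), "g_ccw"),
      d_ms = vapply(specs, `[[`, numeric(1), "d_ms"),
      b = vapply(specs, `[[`, numeric(1), "b"),
      sigma = vapply(specs, `[[`, numeric(1), "sigma"),
      stringsAsFactors = FALSE)
  }
  list(trials = trials, ground_truth = do.call(rbind, gt))
}

#' Write a cohort to a directory (trial CSV + meta JSON per subject)
#'
#' Also writes `ground_truth.csv` with the realized per-subject
#' parameters.
#'
#' @param cohort result of [generate_cohort].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in cohort$trials) {
    write_trial(tr, file.path(dir, paste0(tr$subject_id, ".csv")))
  }
  write_numeric_csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}
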