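#' EMG conditioning parameters
#'
#' Defaults follow standard surface-EMG practice: 20-450 Hz band-pass to
#' isolate the myoelectric band, full-wave rectification, 6-Hz low-pass
#' for the linear envelope, and trial-maximum normalization (used when
#' no maximal-voluntary-contraction reference is available;
#' `reference_value` is retained for users with calibration data).
#'
#' @param bp_low,bp_high band-pass corners in Hz.
#' @param env_cutoff envelope low-pass corner in Hz.
#' @param norm_method `"trial_max"` or `"reference_value"`.
#' @return list of class `preprocess_params`.
#' @export
preprocess_params <- function(bp_low = 20, bp_high = 450, env_cutoff = 6,
                              norm_method = c("trial_max", "reference_value")) {
  norm_method <- match.arg(norm_method)
  if (!(bp_low > 0 && bp_low < bp_high)) {
    stop("parameter error: need 0 < bp_low < bp_high", call. = FALSE)
  }
  if (!(env_cutoff > 0 && env_cutoff < bp_low)) {
    stop("parameter error: need 0 < env_cutoff < bp_low", call. = FALSE)
  }
  structure(list(bp_low = bp_low, bp_high = bp_high, env_cutoff = env_cutoff,
                 norm_method = norm_method), class = "preprocess_params")
}

#' Extract the activation envelope of one raw EMG channel
#'
#' Zero-phase band-pass, full-wave rectification, zero-phase low-pass,
#' clipped at zero. All filtering is forward-backward-equivalent
#' (real-masked FFT), so the envelope is lag-neutral: it adds no delay
#' that would bias EMG-to-torque lag estimates.
#'
#' @param raw numeric vector, one EMG channel in mV.
#' @param fs sampling rate in Hz; must exceed `2 * bp_high`.
#' @param params a [preprocess_params].
#' @return non-negative envelope, same length as `raw`.
#' @export
emg_envelope <- function(raw, fs, params = preprocess_params()) {
  stopifnot(inherits(params, "preprocess_params"))
  if (fs <= 2 * params$bp_high) {
    stop("parameter error: fs must exceed 2 * bp_high (", 2 * params$bp_high,
         " Hz)", call. = FALSE)
  }
  if (length(raw) < 10 * fs / params$bp_low) {
    stop("input too short: need at least ", ceiling(10 * fs / params$bp_low),
         " samples", call. = FALSE)
  }
  band <- fft_filter(raw, fs, low = params$bp_low, high = params$bp_high)
  env <- fft_filter(abs(band), fs, low = NULL, high = params$env_cutoff)
  pmax(env, 0)
}

#' Normalize an envelope to a comparable scale
#'
#' @param env envelope series.
#' @param method `"trial_max"` (divide by the trial maximum, so the
#'   peak is 1) or `"reference_value"` (divide by `ref`).
#' @param ref positive reference scale, required for
#'   `"reference_value"`.
#' @return normalized envelope.
#' @export
normalize_envelope <- function(env, method = c("trial_max", "reference_value"),
                               ref = NULL) {
  method <- match.arg(method)
  if (method == "trial_max") {
    m <- max(env)
    if (!(m > 0)) {
      stop("degenerate input: all-zero envelope cannot be trial-max normalized",
           call. = FALSE)
    }
    env / m
  } else {
    if (is.null(ref) || !(ref > 0)) {
      stop("reference_value normalization needs ref > 0", call. = FALSE)
    }
    env / ref
  }
}

#' Direction segmentation parameters
#'
#' @param theta torque dead-band in N·m; `NULL` (default) resolves to 5%
#'   of the trial's maximum absolute torque at segmentation time.
#' @param min_dur_s minimum episode duration in seconds.
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(theta = NULL, min_dur_s = 0.5) {
  if (!is.null(theta) && theta < 0) stop("theta must be >= 0", call. = FALSE)
  if (min_dur_s <= 0) stop("min_dur_s must be > 0", call. = FALSE)
  structure(list(theta = theta, min_dur_s = min_dur_s),
            class = "segmentation_params")
}

#' Segment a torque trace into clockwise / counterclockwise episodes
#'
#' Samples with torque above `+theta` are clockwise, below `-theta`
#' counterclockwise, and the dead band in between is unlabeled; maximal
#' runs shorter than `min_dur_s` are discarded. The dead band plus
#' minimum duration act as hysteresis against sign chatter near zero.
#'
#' @param torque torque series in N·m (positive = clockwise).
#' @param fs sampling rate in Hz.
#' @param params a [segmentation_params].
#' @return data.frame of class `direction_segments` with columns
#'   `start`, `end` (half-open sample indices, 1-based) and `direction`
#'   (`"cw"`/`"ccw"`), sorted and non-overlapping. Empty (with a
#'   warning) when the dead band swallows the whole trace.
#' @export
segment_directions <- function(torque, fs, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  if (any(!is.finite(torque))) stop("torque must be finite", call. = FALSE)
  theta <- if (is.null(params$theta)) 0.05 * max(abs(torque)) else params$theta
  lab <- integer(length(torque))
  lab[torque > theta] <- 1L
  lab[torque < -theta] <- -1L
  min_len <- max(1L, as.integer(ceiling(params$min_dur_s * fs)))
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0L & runs$lengths >= min_len
  segs <- data.frame(start = starts[keep], end = ends[keep] + 1L,
                     direction = c("ccw", "", "cw")[runs$values[keep] + 2L],
                     stringsAsFactors = FALSE)
  if (!nrow(segs)) {
    warning("no steering episodes found (dead band theta = ",
            signif(theta, 4), " N.m covers the whole trace)", call. = FALSE)
  }
  class(segs) <- c("direction_segments", "data.frame")
  attr(segs, "theta") <- theta
  attr(segs, "fs") <- fs
  segs
}

# concatenate the samples of one direction's segments, per-segment
# mean-removed when demean = TRUE; returns NULL when no segments match
collect_segments <- function(x, segs, direction = NULL, demean = TRUE) {
  if (!is.null(direction)) segs <- segs[segs$direction == direction, , drop = FALSE]
  if (!nrow(segs)) return(NULL)
  pieces <- lapply(seq_len(nrow(segs)), function(i) {
    v <- x[segs$start[i]:(segs$end[i] - 1L)]
    if (demean) v - mean(v) else v
  })
  unlist(pieces, use.names = FALSE)
}
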