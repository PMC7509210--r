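# Independent brute-force oracles used to cross-check the fast kernels.

# normalized cross-correlation: double loop, stats::cor on each overlap
xcorr_oracle <- function(x, y, max_lag) {
  n <- length(x)
  vapply(-max_lag:max_lag, function(tau) {
    t <- if (tau < 0) (1 - tau):n else 1:(n - tau)
    xv <- x[t]
    yv <- y[t + tau]
    if (stats::var(xv) == 0 || stats::var(yv) == 0) return(0)
    stats::cor(xv, yv)
  }, numeric(1))
}

# Pincus approximate entropy: direct template counting, self-matches in
apen_oracle <- function(x, m = 2L, r_frac = 0.2) {
  r <- r_frac * stats::sd(x)
  phi <- function(mm) {
    nt <- length(x) - mm + 1L
    cols <- lapply(seq_len(mm), function(k) x[k:(k + nt - 1L)])
    cnt <- vapply(seq_len(nt), function(i) {
      dmax <- Reduce(pmax, lapply(seq_len(mm), function(k) {
        abs(cols[[k]] - cols[[k]][i])
      }))
      sum(dmax <= r)
    }, numeric(1))
    mean(log(cnt / nt))
  }
  phi(m) - phi(m + 1L)
}

# smooth random series with long sign runs (centered random walk)
fft_smooth_noise <- function(n) {
  x <- cumsum(stats::rnorm(n))
  x - mean(x)
}

# convenience: build a small valid trial around given torque
make_trial <- function(torque, fs = 1000, emg = NULL,
                       arm_mode = "both", hand_position = "0300",
                       task = "active", subject_id = "T01") {
  n <- length(torque)
  time <- (seq_len(n) - 1L) / fs
  if (is.null(emg)) {
    emg <- matrix(stats::rnorm(10L * n, sd = 0.05), nrow = 10L)
  }
  steer_trial(subject_id = subject_id, arm_mode = arm_mode,
              hand_position = hand_position, task = task, fs = fs,
              time = time, torque = torque, angle = numeric(n), emg = emg)
}

# single-direction-segments table covering the whole series
whole_span_segs <- function(n, direction = "cw", fs = 100) {
  segs <- data.frame(start = 1L, end = n + 1L, direction = direction,
                     stringsAsFactors = FALSE)
  class(segs) <- c("direction_segments", "data.frame")
  attr(segs, "fs") <- fs
  segs
}
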