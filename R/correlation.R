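#' Correlation analysis parameters
#'
#' @param max_lag_ms half-width of the lag search window for the
#'   correlation maximum, in ms.
#' @param strong_threshold correlation above which (strictly) a muscle
#'   counts as strongly coupled to the steering task; default 0.75.
#' @return list of class `correlation_params`.
#' @export
correlation_params <- function(max_lag_ms = 1000, strong_threshold = 0.75) {
  if (max_lag_ms <= 0) stop("max_lag_ms must be > 0", call. = FALSE)
  if (!(strong_threshold > 0 && strong_threshold < 1)) {
    stop("strong_threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(list(max_lag_ms = max_lag_ms, strong_threshold = strong_threshold),
            class = "correlation_params")
}

#' Direction-resolved EMG-torque correlation
#'
#' Restricts the envelope and the torque magnitude to one direction's
#' episodes (concatenated, each segment mean-removed) and takes the
#' maximum of the normalized cross-correlation over lags within
#' `max_lag_ms`. Within a direction the torque magnitude `|torque|` is
#' the correlate (sign is already conditioned on by the split), and the
#' same max-over-lags correlation function underlies the delay estimate,
#' so correlation and delay are two readouts of one quantity.
#' Anticorrelation is clipped to 0 for reporting.
#'
#' @param env normalized envelope series.
#' @param torque torque series (same sampling as `env`).
#' @param segs [segment_directions] output.
#' @param direction `"cw"` or `"ccw"`.
#' @param fs sampling rate in Hz of `env`/`torque`.
#' @param params a [correlation_params].
#' @return correlation `r` in `[0, 1]`.
#' @export
direction_correlation <- function(env, torque, segs, direction, fs,
                                  params = correlation_params()) {
  stopifnot(inherits(params, "correlation_params"),
            direction %in% c("cw", "ccw"))
  x <- collect_segments(env, segs, direction)
  y <- collect_segments(abs(torque), segs, direction)
  max_lag <- max(1L, as.integer(round(params$max_lag_ms / 1000 * fs)))
  need <- 2L * max_lag
  if (is.null(x) || length(x) < need) {
    stop("coverage error: direction '", direction, "' has ",
         if (is.null(x)) 0L else length(x), " labeled samples, need >= ",
         need, call. = FALSE)
  }
  rho <- xcorr_normalized(x, y, max_lag)
  max(0, max(rho))
}

#' Classify a correlation as strong or not
#'
#' Strong means strictly larger than the threshold (default 0.75).
#'
#' @param r correlation in `[0, 1]`.
#' @param params a [correlation_params].
#' @return `"strong"` or `"not_strong"`.
#' @export
classify_strength <- function(r, params = correlation_params()) {
  if (any(!is.finite(r)) || any(r < 0) || any(r > 1)) {
    stop("domain error: r must lie in [0, 1]", call. = FALSE)
  }
  ifelse(r > params$strong_threshold, "strong", "not_strong")
}

#' Direction-resolved amplitude statistic
#'
#' Mean of the normalized envelope over all samples belonging to one
#' direction's episodes.
#'
#' @param env normalized envelope.
#' @param segs [segment_directions] output.
#' @param direction `"cw"` or `"ccw"`.
#' @return amplitude `a >= 0`.
#' @export
amplitude_statistic <- function(env, segs, direction) {
  x <- collect_segments(env, segs, direction, demean = FALSE)
  if (is.null(x)) {
    stop("coverage error: no '", direction, "' segments", call. = FALSE)
  }
  mean(x)
}

#' Muscle contribution ratios for one direction
#'
#' Integrates correlation and amplitude into a single importance score:
#' `c_i = r_i * a_i / sum_j r_j * a_j`, non-negative and summing to 1
#' across the muscles of a direction.
#'
#' @param rs correlations, one per muscle.
#' @param as amplitudes, aligned with `rs`.
#' @return numeric vector of contributions (named like `rs` if named).
#' @export
contribution_ratios <- function(rs, as) {
  if (length(rs) != length(as)) {
    stop("rs and as must be aligned by muscle", call. = FALSE)
  }
  if (any(rs < 0) || any(as < 0)) {
    stop("correlations and amplitudes must be >= 0", call. = FALSE)
  }
  p <- rs * as
  s <- sum(p)
  if (!(s > 0)) {
    stop("degenerate input: all correlation x amplitude products are zero",
         call. = FALSE)
  }
  p / s
}

#' Paired sign-flip permutation test for direction dependence
#'
#' Two-sided exact (or Monte-Carlo for larger n) permutation test on the
#' mean of paired differences `r_ccw - r_cw` across subjects, flipping
#' the sign of each subject's difference. Assumption-light and exact at
#' the small cohort sizes typical here; preferred over a paired t-test
#' whose normality assumption is unverifiable at n ~ 20.
#'
#' @param r_cw,r_ccw per-subject correlations, paired by subject.
#' @param n_perm Monte-Carlo draws when exhaustive enumeration (used for
#'   n <= 14) is too large.
#' @param seed seed for the Monte-Carlo branch (ignored when
#'   exhaustive).
#' @return p-value in (0, 1].
#' @export
direction_dependence_test <- function(r_cw, r_ccw, n_perm = 10000, seed = 1L) {
  if (length(r_cw) != length(r_ccw)) {
    stop("pairing error: r_cw and r_ccw must have equal length", call. = FALSE)
  }
  n <- length(r_cw)
  if (n < 2L) stop("sample-size error: need n >= 2 pairs", call. = FALSE)
  d <- r_ccw - r_cw
  obs <- abs(mean(d))
  tol <- 1e-12 * max(1, obs)
  if (n <= 14L) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stat <- abs(signs %*% d) / n
    sum(stat >= obs - tol) / nrow(signs)
  } else {
    hits <- with_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                      nrow = n_perm)
      stat <- abs(signs %*% d) / n
      sum(stat >= obs - tol)
    })
    (hits + 1) / (n_perm + 1)  # include the observed labeling
  }
}
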