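#' Approximate entropy (ApEn) of a series
#'
#' Pincus' regularity statistic with self-matches included:
#' `C_i^m` is the fraction of length-`m` templates within max-norm
#' tolerance `r_tol` of template `i`, `Phi^m` the mean log of those
#' fractions, and `ApEn = Phi^m - Phi^(m+1) >= 0`. Lower values mean a
#' more regular (smoother) signal. The tolerance is SD-relative
#' (`r_tol = r_frac * sd(x)`), which makes ApEn invariant under affine
#' transforms of the input; the canonical parameterization `m = 2`,
#' `r_frac = 0.2` is the default. A constant series (zero SD) returns 0
#' with `degenerate = TRUE`.
#'
#' @param x numeric series, length `> m + 1`.
#' @param m embedding dimension.
#' @param r_frac tolerance as a fraction of `sd(x)`.
#' @return list of class `apen_result`: `apen`, `phi_m`, `phi_m1`,
#'   `counts_m` (per-template match counts at length `m`), `r_tol`,
#'   `m`, `degenerate`.
#' @export
approximate_entropy <- function(x, m = 2L, r_frac = 0.2) {
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  if (r_frac <= 0) stop("r_frac must be > 0", call. = FALSE)
  n <- length(x)
  if (n <= m + 1L) {
    stop("length error: need length > m + 1 (got ", n, ")", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) {
    return(structure(list(apen = 0, phi_m = 0, phi_m1 = 0,
                          counts_m = NULL, r_tol = 0, m = m,
                          degenerate = TRUE), class = "apen_result"))
  }
  r_tol <- r_frac * s
  a <- .apen_phi_cpp(as.numeric(x), as.integer(m), r_tol)
  b <- .apen_phi_cpp(as.numeric(x), as.integer(m) + 1L, r_tol)
  structure(list(apen = a$phi - b$phi, phi_m = a$phi, phi_m1 = b$phi,
                 counts_m = a$counts, r_tol = r_tol, m = m,
                 degenerate = FALSE), class = "apen_result")
}

#' Sliding standard deviation (SSD) of a series
#'
#' Mean over window positions of the sample SD (n-1 denominator) within
#' each window; positions advance by `step` samples. Lower values mean a
#' smoother signal; exactly 0 on constant input and positively
#' homogeneous (`ssd(c x) = c ssd(x)` for `c > 0`).
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (window must hold >= 2
#'   samples).
#' @param step stride between window starts, in samples.
#' @return the SSD scalar.
#' @export
sliding_sd <- function(x, fs, window_s = 0.5, step = 1L) {
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  w <- as.integer(round(window_s * fs))
  if (w < 2L) stop("window must hold at least 2 samples", call. = FALSE)
  n <- length(x)
  if (n < w) {
    stop("length error: window (", w, ") longer than series (", n, ")",
         call. = FALSE)
  }
  c1 <- c(0, cumsum(x))
  c2 <- c(0, cumsum(x * x))
  starts <- seq(1L, n - w + 1L, by = as.integer(step))
  ends <- starts + w - 1L
  s1 <- c1[ends + 1L] - c1[starts]
  s2 <- c2[ends + 1L] - c2[starts]
  v <- pmax(0, (s2 - s1 * s1 / w) / (w - 1))
  mean(sqrt(v))
}

#' Steering-smoothness report for one trial
#'
#' Computes both smoothness metrics on the torque channel only: ApEn on
#' the torque decimated to `apen_fs` (at raw kHz rates successive
#' samples are trivially similar and ApEn collapses toward 0; 100 Hz
#' retains the steering dynamics), and SSD on the raw torque. Lower
#' values of either metric mean smoother steering.
#'
#' @param trial a [steer_trial].
#' @param m,r_frac ApEn parameters (see [approximate_entropy]).
#' @param apen_fs decimation target for the ApEn input, Hz.
#' @param window_s,step SSD parameters (see [sliding_sd]).
#' @return list of class `smoothness_result`: `apen`, `ssd`,
#'   `degenerate`, plus the parameters used.
#' @export
smoothness_report <- function(trial, m = 2L, r_frac = 0.2, apen_fs = 100,
                              window_s = 0.5, step = 1L) {
  validate_trial(trial)
  dec <- decimate_signal(trial$torque, trial$fs, apen_fs)
  if (stats::sd(trial$torque) == 0) {
    # constant torque: both metrics are defined as exactly 0
    return(structure(list(apen = 0, ssd = 0, degenerate = TRUE,
                          m = m, r_frac = r_frac, apen_fs = apen_fs,
                          window_s = window_s, step = step),
                     class = "smoothness_result"))
  }
  ae <- approximate_entropy(dec$x, m = m, r_frac = r_frac)
  ssd <- sliding_sd(trial$torque, trial$fs, window_s = window_s, step = step)
  structure(list(apen = ae$apen, ssd = ssd, degenerate = ae$degenerate,
                 m = m, r_frac = r_frac, apen_fs = apen_fs,
                 window_s = window_s, step = step),
            class = "smoothness_result")
}
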