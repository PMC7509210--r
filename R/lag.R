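#' Normalized cross-correlation over integer lags
#'
#' `rho[tau]` is the Pearson correlation between `x(t)` and `y(t + tau)`
#' over the overlapping range, with each window mean-removed, for
#' `tau = -max_lag, ..., +max_lag`. Satisfies `|rho| <= 1` everywhere
#' and the symmetry `xcorr(x, y)(tau) = xcorr(y, x)(-tau)`.
#'
#' @param x,y numeric series of equal length (`>= 2 * max_lag`), each
#'   with positive variance.
#' @param max_lag half-width of the lag window in samples.
#' @return numeric vector of length `2 * max_lag + 1`, named by lag.
#' @export
xcorr_normalized <- function(x, y, max_lag) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L || n < 2L * max_lag || n < max_lag + 2L) {
    stop("series too short for max_lag = ", max_lag, " (length ", n, ")",
         call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("degeneracy error: zero-variance input", call. = FALSE)
  }
  rho <- .xcorr_norm_cpp(as.numeric(x), as.numeric(y), max_lag)
  names(rho) <- as.character(-max_lag:max_lag)
  rho
}

#' Estimate the EMG-to-torque time delay of one muscle
#'
#' The delay is the lag of maximum absolute normalized cross-correlation
#' between the activation envelope and the torque magnitude, with the
#' sign convention that `tau_ms < 0` means the muscle activity leads
#' (precedes) the torque and `tau_ms > 0` means it lags behind the
#' torque (the signature of co-contraction). Ties are broken toward the
#' smallest `|tau|` (the most conservative causal claim). By default the
#' whole labeled span (both directions pooled, per-segment mean-removed)
#' is analyzed, matching one-delay-per-muscle reporting; pass
#' `segs = NULL` to use the full trial.
#'
#' @param env envelope series.
#' @param torque torque series at the same sampling rate.
#' @param fs sampling rate in Hz.
#' @param segs optional [segment_directions] output restricting the
#'   analysis span; `NULL` uses the whole trial.
#' @param max_lag_ms search half-window, ms (default 1000, comfortably
#'   containing physiological leads of a few hundred ms).
#' @param muscle optional muscle code carried into the result.
#' @return list of class `delay_result`: `muscle`, `tau_ms`,
#'   `rho_at_tau`, `max_lag_ms`, and `boundary` (TRUE when the optimum
#'   sits on the window edge, i.e. the window is likely too small).
#' @export
estimate_delay <- function(env, torque, fs, segs = NULL, max_lag_ms = 1000,
                           muscle = NA_character_) {
  if (!is.null(segs) && nrow(segs)) {
    x <- collect_segments(env, segs)
    y <- collect_segments(abs(torque), segs)
  } else {
    x <- env - mean(env)
    y <- abs(torque)
    y <- y - mean(y)
  }
  max_lag <- max(1L, as.integer(round(max_lag_ms / 1000 * fs)))
  rho <- xcorr_normalized(x, y, max_lag)
  taus <- -max_lag:max_lag
  m <- max(abs(rho))
  cand <- which(abs(rho) >= m - 1e-15)
  best <- cand[which.min(abs(taus[cand]))]
  tau_star <- taus[best]
  structure(list(muscle = muscle,
                 # rho is indexed by the shift applied to the torque, so a
                 # positive optimum means the envelope came first: flip the
                 # sign to report lead as negative
                 tau_ms = -tau_star * 1000 / fs,
                 rho_at_tau = unname(rho[best]),
                 max_lag_ms = max_lag * 1000 / fs,
                 boundary = abs(tau_star) == max_lag),
            class = "delay_result")
}

#' @export
print.delay_result <- function(x, ...) {
  cat(sprintf("<delay_result> %s: tau = %.1f ms (rho = %.3f)%s\n",
              x$muscle, x$tau_ms, x$rho_at_tau,
              if (x$boundary) " [optimum at window edge]" else ""))
  invisible(x)
}
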