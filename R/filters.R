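#' Zero-phase FFT band-pass / low-pass filtering
#'
#' Filtering is done by masking the discrete Fourier transform of the
#' (reflect-padded) signal with a real, raised-cosine-edged frequency
#' response and inverting. Because the mask is real and symmetric the
#' filter has exactly zero phase, so envelopes derived from it add no
#' lag that could contaminate downstream time-delay estimates.
#'
#' @param x numeric vector, the signal.
#' @param fs sampling rate in Hz.
#' @param low lower corner in Hz, or `NULL` for a pure low-pass.
#' @param high upper corner in Hz, or `NULL` for a pure high-pass.
#' @param trans_frac relative half-width of the raised-cosine transition
#'   band around each corner (fraction of the corner frequency).
#' @return filtered signal, same length as `x`.
#' @keywords internal
fft_filter <- function(x, fs, low = NULL, high = NULL, trans_frac = 0.15) {
  stopifnot(is.numeric(x), fs > 0)
  n <- length(x)
  if (n < 4L) stop("signal too short to filter (length ", n, ")", call. = FALSE)
  nyq <- fs / 2
  if (!is.null(high) && high >= nyq) {
    stop("upper corner (", high, " Hz) must lie below Nyquist (", nyq, " Hz)",
         call. = FALSE)
  }
  if (!is.null(low) && !is.null(high) && low >= high) {
    stop("band-pass corners must satisfy low < high", call. = FALSE)
  }

  # reflect-pad to suppress circular wrap-around at the edges
  p <- min(n - 1L, as.integer(ceiling(fs)))
  xp <- c(rev(x[seq_len(p) + 1L]), x, rev(x[(n - p):(n - 1L)]))
  m <- length(xp)

  f <- (seq_len(m) - 1L) / m * fs
  f <- pmin(f, fs - f)  # fold onto [0, fs/2]: keeps the mask Hermitian

  mask <- rep(1, m)
  if (!is.null(low)) {
    t <- trans_frac * low
    mask <- mask * ramp_up(f, low - t, low + t)
  }
  if (!is.null(high)) {
    t <- min(trans_frac * high, nyq - high)
    mask <- mask * (1 - ramp_up(f, high - t, high + t))
  }

  y <- Re(stats::fft(stats::fft(xp) * mask, inverse = TRUE)) / m
  y[(p + 1L):(p + n)]
}

# half-cosine ramp from 0 (f <= f0) to 1 (f >= f1)
ramp_up <- function(f, f0, f1) {
  if (f1 <= f0) return(as.numeric(f >= f0))
  u <- pmin(pmax((f - f0) / (f1 - f0), 0), 1)
  0.5 - 0.5 * cos(pi * u)
}

#' Decimate a signal to a lower sampling rate
#'
#' Applies a zero-phase anti-aliasing low-pass at `0.4 * target_fs`
#' before subsampling. The decimation factor `fs / target_fs` must be a
#' whole number.
#'
#' @param x numeric vector.
#' @param fs original sampling rate in Hz.
#' @param target_fs requested sampling rate in Hz (must divide `fs`).
#' @return list with `x` (decimated signal) and `fs` (the new rate).
#' @export
decimate_signal <- function(x, fs, target_fs) {
  if (target_fs > fs) stop("target_fs must not exceed fs", call. = FALSE)
  q <- fs / target_fs
  if (abs(q - round(q)) > 1e-9) {
    stop("fs / target_fs must be an integer (got ", q, ")", call. = FALSE)
  }
  q <- as.integer(round(q))
  if (q == 1L) return(list(x = x, fs = fs))
  xf <- fft_filter(x, fs, low = NULL, high = 0.4 * target_fs)
  list(x = xf[seq(1L, length(x), by = q)], fs = target_fs)
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards. Keeps generators deterministic without
# clobbering the session seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a reproducible 31-bit sub-seed from a master seed and an index.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 7919 + 12345) %% 2147483647)
}
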