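# Shared signal-processing kernels: FIR design, zero-phase filtering of
# multichannel matrices, analytic signal, and Welch cross-spectra.

#' Design a zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) band-pass design. The order follows the classic
#' 3.3 * fs / transition-width rule of thumb and is forced even so the filter
#' is type I (symmetric, odd tap count).
#'
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz.
#' @param transition Transition width in Hz; default `max(2, 0.25 * low)`.
#' @return Numeric vector of filter taps.
#' @keywords internal
fir_bandpass <- function(fs, low, high, transition = NULL) {
  if (high >= fs / 2) {
    abort(sprintf("band edge %g Hz infeasible at fs = %g Hz", high, fs))
  }
  if (low <= 0 || low >= high) abort("band edges must satisfy 0 < low < high")
  if (is.null(transition)) transition <- max(2, 0.25 * low)
  ord <- ceiling(3.3 * fs / transition)
  if (ord %% 2 == 1) ord <- ord + 1
  as.numeric(signal::fir1(ord, c(low, high) / (fs / 2), type = "pass"))
}

# Forward-backward (zero-phase) application of FIR taps to every row of a
# channels x samples matrix; length preserved. Implemented in the frequency
# domain (squared magnitude response, zero net delay for any taps) with odd
# reflection padding of 3 filter lengths at both edges, vectorised across
# rows. Agrees with per-row signal::filtfilt away from the padded edges.
filtfilt_rows <- function(taps, x) {
  stopifnot(is.matrix(x))
  k <- length(taps)
  n <- ncol(x)
  if (n < 3 * k) {
    abort(sprintf(
      "signal too short (%d samples) for zero-phase filtering with %d taps",
      n, k
    ))
  }
  pad <- 3 * k
  left <- 2 * x[, 1] - x[, (pad + 1):2, drop = FALSE]
  right <- 2 * x[, n] - x[, (n - 1):(n - pad), drop = FALSE]
  xp <- cbind(left, x, right)
  np <- ncol(xp)
  N <- stats::nextn(np + 2 * k, c(2, 3, 5))
  H2 <- Mod(fft(c(taps, rep(0, N - k))))^2
  X <- stats::mvfft(t(cbind(xp, matrix(0, nrow(x), N - np))))
  y <- Re(t(stats::mvfft(X * H2, inverse = TRUE))) / N
  out <- y[, (pad + 1):(pad + n), drop = FALSE]
  dimnames(out) <- dimnames(x)
  out
}

# Analytic signal of every row via the frequency-domain Hilbert method.
analytic_rows <- function(x) {
  stopifnot(is.matrix(x))
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  xf <- t(stats::mvfft(t(x)))
  xa <- t(stats::mvfft(t(xf * rep(h, each = nrow(x))), inverse = TRUE)) / n
  dimnames(xa) <- dimnames(x)
  xa
}

# Wrap angles into (-pi, pi].
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Welch auto- and cross-spectra of a multichannel window
#'
#' Splits each channel row into Hanning-tapered segments with the given
#' overlap, and averages the per-segment cross-spectral matrices.
#'
#' @param x Channels x samples matrix.
#' @param fs Sampling rate (Hz).
#' @param seg_len Segment length in samples.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @param freq_sel Optional indices into the one-sided frequency grid; only
#'   those cross-spectral matrices are accumulated.
#' @return List with `freq` (one-sided grid, Hz; restricted when `freq_sel`
#'   is given), `S` (array `n_freq x C x C` of complex cross-spectra;
#'   diagonal real), and `n_segments`.
#' @keywords internal
welch_cross_spectra <- function(x, fs, seg_len = 125L, overlap = 0.5,
                                freq_sel = NULL) {
  stopifnot(is.matrix(x))
  n <- ncol(x)
  C <- nrow(x)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  if (length(starts) < 2L) {
    abort(sprintf(
      "window of %d samples too short for >= 2 Welch segments of %d",
      n, seg_len
    ))
  }
  win <- as.numeric(signal::hanning(seg_len))
  nf <- floor(seg_len / 2) + 1L
  freq <- (seq_len(nf) - 1L) * fs / seg_len
  sel <- if (is.null(freq_sel)) seq_len(nf) else freq_sel
  S <- array(0 + 0i, dim = c(length(sel), C, C))
  for (s0 in starts) {
    seg <- x[, s0:(s0 + seg_len - 1L), drop = FALSE] *
      rep(win, each = C)
    Xf <- stats::mvfft(t(seg))[sel, , drop = FALSE]
    for (k in seq_along(sel)) {
      v <- Xf[k, ]
      S[k, , ] <- S[k, , ] + outer(v, Conj(v))
    }
  }
  S <- S / length(starts)
  list(freq = freq[sel], S = S, n_segments = length(starts))
}

# Deterministic derivation of sub-seeds from a master seed; kept below 2^31.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 104729 + as.numeric(index) * 7919) %%
    2147483629)
}
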