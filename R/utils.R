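# Internal numerical helpers shared across modules.

#' @keywords internal
next_pow2 <- function(n) 2L^as.integer(ceiling(log2(max(n, 1L))))

# Derive a reproducible child seed from a base seed and an index.
# Kept below 2^31 so it is always a valid R integer seed.
#' @keywords internal
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483587)
}

# Linear convolution of a real/complex signal with a kernel via FFT,
# returning the "same" central part (aligned with x). For kernels whose
# length is more than 1/8 of the signal, stats::convolve direct mode would
# not be faster in R, so FFT is used throughout; a direct path exists for
# short signals to avoid large zero-padding.
#' @keywords internal
conv_same <- function(x, kernel) {
  nx <- length(x)
  nk <- length(kernel)
  nfft <- next_pow2(nx + nk - 1L)
  X <- stats::fft(c(x, rep(0, nfft - nx)))
  K <- stats::fft(c(kernel, rep(0, nfft - nk)))
  full <- stats::fft(X * K, inverse = TRUE) / nfft
  offset <- (nk - 1L) %/% 2L
  full[(offset + 1L):(offset + nx)]
}

# Convolve a multi-column matrix (columns = channels) with one kernel,
# sharing the forward FFT plan across channels via mvfft.
#' @keywords internal
conv_same_mat <- function(xmat, kernel) {
  nx <- nrow(xmat)
  nk <- length(kernel)
  nfft <- next_pow2(nx + nk - 1L)
  pad <- matrix(0, nfft, ncol(xmat))
  pad[seq_len(nx), ] <- xmat
  X <- stats::mvfft(pad)
  K <- stats::fft(c(kernel, rep(0, nfft - nk)))
  full <- stats::mvfft(X * K, inverse = TRUE) / nfft
  offset <- (nk - 1L) %/% 2L
  full[(offset + 1L):(offset + nx), , drop = FALSE]
}

# Analytic signal via the frequency-domain Hilbert construction.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Windowed-sinc linear-phase FIR low-pass (Hamming window). `trans` is the
# transition width in Hz; the length rule (3.3 / normalized transition) is the
# standard Hamming-window design relation.
#' @keywords internal
design_lowpass_fir <- function(fc, fs, trans = 0.25 * fc) {
  ntaps <- ceiling(3.3 / (trans / fs))
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  m <- (ntaps - 1) / 2
  k <- seq(-m, m)
  wc <- 2 * pi * fc / fs
  h <- ifelse(k == 0, wc / pi, sin(wc * k) / (pi * k))
  w <- 0.54 + 0.46 * cos(pi * k / m)
  h <- h * w
  h / sum(h)
}

#' @keywords internal
design_highpass_fir <- function(fc, fs, trans = 0.25 * fc) {
  h <- design_lowpass_fir(fc, fs, trans)
  d <- rep(0, length(h))
  d[(length(h) + 1) / 2] <- 1
  d - h
}

# Apply a symmetric (linear-phase) FIR with zero net delay: convolve and keep
# the centre-aligned part. For an odd-length symmetric kernel this is exactly
# zero-phase.
#' @keywords internal
filt_zero_phase <- function(x, h) {
  if (is.matrix(x)) Re(conv_same_mat(x, h)) else Re(conv_same(x, h))
}

# Resample a signal to a new rate. Integer decimation uses an anti-alias FIR
# followed by index selection; arbitrary ratios go through the same FIR (when
# down-sampling) followed by linear interpolation on the continuous time axis.
#' @keywords internal
resample_sig <- function(x, fs, new_fs) {
  if (new_fs == fs) return(x)
  one_col <- !is.matrix(x)
  if (one_col) x <- matrix(x, ncol = 1)
  if (new_fs < fs) {
    fc <- 0.4 * new_fs
    h <- design_lowpass_fir(fc, fs, trans = 0.2 * new_fs)
    x <- filt_zero_phase(x, h)
  }
  ratio <- fs / new_fs
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1L, nrow(x), by = as.integer(round(ratio)))
    out <- x[idx, , drop = FALSE]
  } else {
    t_new <- seq(0, by = 1 / new_fs, length.out = floor(nrow(x) * new_fs / fs))
    t_old <- seq(0, by = 1 / fs, length.out = nrow(x))
    out <- apply(x, 2, function(col) stats::approx(t_old, col, xout = t_new, rule = 2)$y)
    if (!is.matrix(out)) out <- matrix(out, ncol = ncol(x))
  }
  if (one_col) drop(out) else out
}

# 1/f^a noise by spectral shaping of white Gaussian noise, unit RMS.
#' @keywords internal
one_over_f_noise <- function(n, exponent = 1, fs = 1) {
  nfft <- next_pow2(n)
  w <- stats::rnorm(nfft)
  W <- stats::fft(w)
  freqs <- c(0, seq_len(nfft - 1)) * fs / nfft
  freqs <- pmin(freqs, fs - freqs)  # two-sided axis
  gain <- c(0, freqs[-1]^(-exponent / 2))
  x <- Re(stats::fft(W * gain, inverse = TRUE) / nfft)[seq_len(n)]
  x / stats::sd(x)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
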