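# Core entrainment statistic: Morlet wavelet bank, phase extraction,
# phase-locking values, pulse normalization, metrical-level extraction.

#' Build a log-spaced complex Morlet wavelet bank
#'
#' Center frequencies follow `f_k = fmin * 2^(k / bins_per_octave)` for all
#' `k` with `f_k <= fmax`; the defaults (0.25-5 Hz, 15 bins per octave) give
#' 65 wavelets spanning the range of musical rhythm. The cycle count per
#' wavelet doubles the center frequency and rounds, clamped to \[3, 8\], so
#' slow wavelets keep at least 3 cycles and fast ones at most 8. Each kernel
#' is a Gaussian-enveloped complex exponential with `sigma_t = cycles /
#' (2 pi f)`, truncated at 4 sigma and normalized to unit gain at its center
#' frequency.
#'
#' @param fmin,fmax Frequency range in Hz.
#' @param bins_per_octave Log-spacing density.
#' @param fs Sample rate of the signals to be analyzed, Hz. Must exceed
#'   `2 * fmax`.
#' @param cycles_range Two-element clamp for the cycle rule.
#' @return An object of class `wavelet_bank` with elements `freqs`, `cycles`,
#'   `fs`, `kernels` (list of complex vectors) and `half_support` (samples).
#' @export
build_wavelet_bank <- function(fmin = 0.25, fmax = 5, bins_per_octave = 15,
                               fs, cycles_range = c(3, 8)) {
  stopifnot(fmin > 0, fmin < fmax)
  if (fs <= 2 * fmax) stop("fs must exceed twice the highest wavelet frequency")
  kmax <- floor(bins_per_octave * log2(fmax / fmin) + 1e-9)
  freqs <- fmin * 2^((0:kmax) / bins_per_octave)
  cycles <- pmin(pmax(round(2 * freqs), cycles_range[1]), cycles_range[2])
  kernels <- vector("list", length(freqs))
  half <- integer(length(freqs))
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sigma <- cycles[k] / (2 * pi * f)
    h <- ceiling(4 * sigma * fs)
    t <- seq(-h, h) / fs
    g <- exp(-t^2 / (2 * sigma^2))
    w <- g * exp(2i * pi * f * t)
    kernels[[k]] <- w / sum(g)  # unit gain at the center frequency
    half[k] <- h
  }
  structure(list(freqs = freqs, cycles = cycles, fs = fs,
                 kernels = kernels, half_support = half),
            class = "wavelet_bank")
}

#' @export
print.wavelet_bank <- function(x, ...) {
  cat(sprintf("<wavelet_bank: %d wavelets, %.3g-%.3g Hz, %d-%d cycles @ %g Hz>\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              min(x$cycles), max(x$cycles), x$fs))
  invisible(x)
}

#' Instantaneous phase via wavelet convolution
#'
#' Convolves a signal with every (or a subset of) complex Morlet wavelet in a
#' bank and returns the complex argument per sample. Samples within one
#' wavelet half-support of either signal edge, and samples where the wavelet
#' coefficient magnitude is numerically zero (degenerate input, e.g. a
#' constant signal), are flagged invalid rather than silently returned.
#'
#' @param x Numeric vector sampled at `bank$fs`.
#' @param bank A [build_wavelet_bank()] object.
#' @param subset Optional integer indices of wavelets to evaluate.
#' @return An object of class `phase_series`: list with `phases`
#'   (wavelets-by-time matrix of angles in (-pi, pi\]), `valid` (same-shape
#'   logical), `freqs`, `fs`.
#' @export
wavelet_phase <- function(x, bank, subset = NULL) {
  stopifnot(inherits(bank, "wavelet_bank"))
  x <- as.numeric(x)
  x <- x - mean(x)   # DC leaks through the Gaussian envelope at few cycles
  if (is.null(subset)) subset <- seq_along(bank$freqs)
  longest <- max(2L * bank$half_support[subset] + 1L)
  if (length(x) < longest) {
    stop("signal shorter than the longest wavelet (", longest, " samples)")
  }
  co <- wavelet_coef_multi(matrix(x, ncol = 1), bank, subset)
  phases <- matrix(NA_real_, length(subset), length(x))
  valid <- matrix(FALSE, length(subset), length(x))
  for (j in seq_along(subset)) {
    z <- co$coefs[[j]][, 1]
    phases[j, ] <- Arg(z)
    v <- rep(FALSE, length(x))
    v[co$valid_ranges[[j]]] <- TRUE
    v[Mod(z) < co$mag_floor] <- FALSE
    valid[j, ] <- v
  }
  structure(list(phases = phases, valid = valid,
                 freqs = bank$freqs[subset], fs = bank$fs),
            class = "phase_series")
}

# Shared engine: wavelet coefficients for a time-by-channels matrix, one
# forward FFT per channel reused across wavelets. Kernels are centered at
# index 0 (wrap-around) so all outputs align with the input without
# per-kernel trimming.
#' @keywords internal
wavelet_coef_multi <- function(xmat, bank, subset) {
  nx <- nrow(xmat)
  maxlen <- max(2L * bank$half_support[subset] + 1L)
  nfft <- next_pow2(nx + maxlen)
  pad <- matrix(0, nfft, ncol(xmat))
  pad[seq_len(nx), ] <- xmat
  X <- stats::mvfft(pad)
  coefs <- vector("list", length(subset))
  valid_ranges <- vector("list", length(subset))
  for (j in seq_along(subset)) {
    k <- subset[j]
    kern <- bank$kernels[[k]]
    h <- bank$half_support[k]
    kbuf <- complex(nfft)
    kbuf[1:(h + 1L)] <- kern[(h + 1L):(2L * h + 1L)]
    kbuf[(nfft - h + 1L):nfft] <- kern[1:h]
    K <- stats::fft(kbuf)
    out <- stats::mvfft(X * K, inverse = TRUE) / nfft
    coefs[[j]] <- out[seq_len(nx), , drop = FALSE]
    lo <- h + 1L
    hi <- nx - h
    valid_ranges[[j]] <- if (lo <= hi) lo:hi else integer(0)
  }
  mag_floor <- 1e-12 * max(abs(xmat), 1e-300)
  list(coefs = coefs, valid_ranges = valid_ranges, mag_floor = mag_floor)
}

#' Phase-locking values between a reference and multi-channel phase series
#'
#' For channel `j` and wavelet `k`, the PLV is the magnitude of the mean
#' resultant vector of the relative phase,
#' `PLV_jk = | n^-1 sum_t exp(i (theta1_kt - theta2_jkt)) |`,
#' a scalar in \[0, 1\]: 0 means no consistent phase relation, 1 perfect
#' locking. The sum runs over samples valid in both series (wavelet edge
#' samples are excluded); `n` records the per-wavelet count actually used.
#'
#' @param env_phase A `phase_series` for the reference signal (the music's
#'   amplitude envelope).
#' @param eeg_phase A `phase_series` (one channel) or list of them (one per
#'   channel), all from the same bank subset and of equal length.
#' @param valid_range Optional integer vector of sample indices to restrict
#'   the sum to (intersected with the per-wavelet valid samples).
#' @return An object of class `plv_matrix`: `values` (channels-by-wavelets),
#'   `n` (per-wavelet sample counts), `freqs`.
#' @export
compute_plv <- function(env_phase, eeg_phase, valid_range = NULL) {
  stopifnot(inherits(env_phase, "phase_series"))
  if (inherits(eeg_phase, "phase_series")) eeg_phase <- list(eeg_phase)
  nw <- nrow(env_phase$phases)
  nt <- ncol(env_phase$phases)
  vals <- matrix(NA_real_, length(eeg_phase), nw)
  ns <- matrix(0L, length(eeg_phase), nw)
  for (j in seq_along(eeg_phase)) {
    pj <- eeg_phase[[j]]
    if (!identical(dim(pj$phases), dim(env_phase$phases))) {
      stop("misaligned phase series: channel ", j)
    }
    for (k in seq_len(nw)) {
      ok <- env_phase$valid[k, ] & pj$valid[k, ]
      if (!is.null(valid_range)) {
        keep <- rep(FALSE, nt); keep[valid_range] <- TRUE
        ok <- ok & keep
      }
      n <- sum(ok)
      if (n > 0) {
        d <- env_phase$phases[k, ok] - pj$phases[k, ok]
        vals[j, k] <- min(Mod(mean(exp(1i * d))), 1)
        ns[j, k] <- n
      }
    }
  }
  structure(list(values = vals, n = ns, freqs = env_phase$freqs),
            class = "plv_matrix")
}

#' Wavelet PLV between an amplitude envelope and multi-channel EEG
#'
#' Composite of [wavelet_phase()] and [compute_plv()] that shares one forward
#' FFT per channel across all wavelets and never materializes full phase
#' matrices, making long recordings and many channels tractable. Results are
#' identical to the two-step route (the normalized complex coefficients carry
#' exactly the instantaneous phases).
#'
#' @param env An [envelope_signal()] or numeric vector at `bank$fs`.
#' @param eeg_data Channels-by-time numeric matrix at `bank$fs`.
#' @param bank A [build_wavelet_bank()].
#' @param subset Optional wavelet indices.
#' @return A `plv_matrix` (channels-by-wavelets).
#' @export
plv_music_eeg <- function(env, eeg_data, bank, subset = NULL) {
  if (inherits(env, "envelope_signal")) {
    stopifnot(env$fs == bank$fs)
    env <- env$values
  }
  if (is.null(subset)) subset <- seq_along(bank$freqs)
  eeg_data <- as.matrix(eeg_data)
  stopifnot(ncol(eeg_data) == length(env))
  xmat <- cbind(env, t(eeg_data))
  xmat <- sweep(xmat, 2, colMeans(xmat))
  co <- wavelet_coef_multi(xmat, bank, subset)
  n_chan <- nrow(eeg_data)
  vals <- matrix(NA_real_, n_chan, length(subset))
  ns <- matrix(0L, n_chan, length(subset))
  for (j in seq_along(subset)) {
    z <- co$coefs[[j]]
    rng <- co$valid_ranges[[j]]
    if (!length(rng)) next
    z <- z[rng, , drop = FALSE]
    mag <- Mod(z)
    good <- mag > co$mag_floor
    u <- z / mag                      # unit phasors exp(i * theta)
    ref <- u[, 1]
    ref_ok <- good[, 1]
    for (ch in seq_len(n_chan)) {
      ok <- ref_ok & good[, ch + 1]
      n <- sum(ok)
      if (n > 0) {
        vals[ch, j] <- min(Mod(mean(ref[ok] * Conj(u[ok, ch + 1]))), 1)
        ns[ch, j] <- n
      }
    }
  }
  structure(list(values = vals, n = ns, freqs = bank$freqs[subset]),
            class = "plv_matrix")
}

#' Normalize a PLV spectrum to the detected pulse frequency
#'
#' Rescales the frequency axis so the recording's pulse frequency maps to the
#' dimensionless unit 2: `u(f) = 2 f / pulse_freq`. Each channel's PLV-vs-
#' log2(frequency) curve is linearly interpolated onto a fixed dimensionless
#' grid (15 bins per octave over \[0.5, 8\]); grid points falling outside the
#' measured frequency range are marked missing, never extrapolated. On this
#' axis, 1 is the subharmonic level, 2 the pulse, 4 the harmonic, and 1.5, 3,
#' 5 the off-levels.
#'
#' @param plv A `plv_matrix`.
#' @param pulse_freq Detected pulse frequency in Hz (> 0).
#' @param grid_range,bins_per_octave Dimensionless grid definition.
#' @return An object of class `normalized_plv`: `values`
#'   (channels-by-grid, NA where unmeasured), `axis` (dimensionless units),
#'   `pulse_freq`.
#' @export
normalize_to_pulse <- function(plv, pulse_freq, grid_range = c(0.5, 8),
                               bins_per_octave = 15) {
  stopifnot(inherits(plv, "plv_matrix"))
  if (!is.finite(pulse_freq) || pulse_freq <= 0) {
    stop("pulse_freq must be a positive number")
  }
  jmax <- round(bins_per_octave * log2(grid_range[2] / grid_range[1]))
  axis <- grid_range[1] * 2^((0:jmax) / bins_per_octave)
  u_meas <- 2 * plv$freqs / pulse_freq
  lx <- log2(u_meas)
  lg <- log2(axis)
  vals <- matrix(NA_real_, nrow(plv$values), length(axis))
  for (ch in seq_len(nrow(plv$values))) {
    y <- plv$values[ch, ]
    ok <- is.finite(y)
    if (sum(ok) >= 2) {
      vals[ch, ] <- stats::approx(lx[ok], y[ok], xout = lg, rule = 1)$y
    } else if (sum(ok) == 1) {
      hit <- which(abs(lg - lx[ok]) < 1e-9)
      vals[ch, hit] <- y[ok]
    }
  }
  structure(list(values = vals, axis = axis, pulse_freq = pulse_freq),
            class = "normalized_plv")
}

#' Extract PLVs at the six metrical levels
#'
#' Linear interpolation (in log2 of the dimensionless axis) of each channel's
#' normalized PLV curve at the metrical levels: subharmonic 1,
#' off-subharmonic 1.5, pulse 2, off-pulse 3, harmonic 4, off-harmonic 5.
#' A level lying entirely outside the measured range is returned as `NA`;
#' the others are unaffected.
#'
#' @param norm A [normalize_to_pulse()] result.
#' @param levels Dimensionless levels to extract.
#' @return Channels-by-levels numeric matrix with levels as column names.
#' @export
extract_levels <- function(norm, levels = c(1, 1.5, 2, 3, 4, 5)) {
  stopifnot(inherits(norm, "normalized_plv"))
  lg <- log2(norm$axis)
  lq <- log2(levels)
  out <- matrix(NA_real_, nrow(norm$values), length(levels),
                dimnames = list(NULL, as.character(levels)))
  for (ch in seq_len(nrow(norm$values))) {
    y <- norm$values[ch, ]
    ok <- is.finite(y)
    if (sum(ok) >= 2) {
      out[ch, ] <- stats::approx(lg[ok], y[ok], xout = lq, rule = 1)$y
    } else if (sum(ok) == 1) {
      hit <- abs(lq - lg[ok]) < 1e-9
      out[ch, hit] <- y[ok]
    }
  }
  out
}
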