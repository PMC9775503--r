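# Audio front end: middle-ear filtering, complex-domain onset detection,
# amplitude-envelope extraction.

#' Middle-ear band-pass filter
#'
#' Linear time-invariant band-pass emphasizing roughly 0.5-5 kHz, the band in
#' which the middle ear transmits acoustic energy most efficiently. Realized
#' as a 4th-order Butterworth band-pass (an order-2 `signal::butter` design on
#' each edge); the upper edge is limited to 90% of Nyquist when the sample
#' rate cannot carry the full passband. Applied causally, as a transducer
#' stage would be.
#'
#' @param audio An [audio_recording()] with `fs >= 8000`.
#' @param band Passband edges in Hz.
#' @return A filtered `audio_recording` of identical length.
#' @export
middle_ear_filter <- function(audio, band = c(500, 5000)) {
  stopifnot(inherits(audio, "audio_recording"))
  if (audio$fs < 8000) stop("sample rate too low to realize the passband; need fs >= 8000 Hz")
  hi <- min(band[2], 0.45 * audio$fs)
  bf <- signal::butter(2, c(band[1], hi) / (audio$fs / 2), type = "pass")
  y <- signal::filter(bf, audio$samples)
  audio_recording(as.numeric(y), audio$fs, id = audio$id)
}

#' @keywords internal
default_stft_params <- function() {
  list(win_sec = 0.046, hop_sec = 0.0116, window = "hann")
}

# Short-time Fourier transform; returns positive-frequency bins only.
#' @keywords internal
stft_frames <- function(x, fs, params) {
  win <- round(params$win_sec * fs)
  hop <- round(params$hop_sec * fs)
  if (length(x) < win) stop("analysis window longer than signal")
  n_frames <- floor((length(x) - win) / hop) + 1L
  idx <- outer(seq_len(win), (seq_len(n_frames) - 1L) * hop, "+")
  mat <- matrix(x[idx], nrow = win)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))  # Hann
  X <- stats::mvfft(mat * w)
  X[seq_len(win %/% 2 + 1L), , drop = FALSE]
}

#' Complex-domain onset detection
#'
#' Derives an onset-strength signal containing pulses triggered by the attack
#' of individual acoustic events. Per STFT frame n and bin k, the observed
#' spectrum is compared with a prediction carrying the previous frame's
#' magnitude and a phase linearly extrapolated from the two previous frames;
#' the detection value is the summed complex deviation
#' `sum_k |X_k(n) - Xhat_k(n)|`. Steady-state content (constant magnitude,
#' linearly advancing phase) is predicted exactly and contributes nothing,
#' so the function responds to transients only. The first two frames are
#' defined as 0. The raw detection curve is median-detrended (1-s running
#' median) and half-wave rectified, which stabilizes the forcing amplitude
#' seen by the oscillator bank across recordings.
#'
#' @param audio An [audio_recording()] (typically middle-ear filtered).
#' @param stft_params List with `win_sec`, `hop_sec`, `window`; see
#'   `default_stft_params()` (46 ms window, 11.6 ms hop, ~86 frames/s).
#' @param detrend Logical; apply median detrend + rectification.
#' @return An [onset_signal()] at the STFT frame rate.
#' @export
complex_onset_detect <- function(audio, stft_params = default_stft_params(),
                                 detrend = TRUE) {
  stopifnot(inherits(audio, "audio_recording"))
  X <- stft_frames(audio$samples, audio$fs, stft_params)
  n_frames <- ncol(X)
  fs_frames <- audio$fs / round(stft_params$hop_sec * audio$fs)
  d <- numeric(n_frames)
  if (n_frames >= 3) {
    mag <- Mod(X)
    ph <- Arg(X)
    cur <- X[, 3:n_frames, drop = FALSE]
    # target: previous magnitude, phase extrapolated from two previous frames
    tgt <- mag[, 2:(n_frames - 1), drop = FALSE] *
      exp(1i * (2 * ph[, 2:(n_frames - 1), drop = FALSE] -
                  ph[, 1:(n_frames - 2), drop = FALSE]))
    d[3:n_frames] <- colSums(Mod(cur - tgt))
  }
  if (detrend && n_frames > 5) {
    k <- min(2L * floor(fs_frames / 2) + 1L, 2L * floor((n_frames - 1) / 2) + 1L)
    if (k >= 3) d <- pmax(d - stats::runmed(d, k), 0)
  }
  onset_signal(d, fs_frames, stft_params)
}

#' Broadband amplitude envelope of a musical recording
#'
#' Estimates the slow amplitude modulation of the audio: magnitude of the
#' analytic signal of the (optionally middle-ear filtered) waveform, low-pass
#' filtered at `lp` Hz, and resampled to the EEG analysis rate (default
#' 1000 Hz). The envelope is non-negative and band-limited below
#' `target_fs / 2`. The construction is exposed as the `method` knob so that
#' alternative envelope estimators can be slotted in.
#'
#' @param audio An [audio_recording()].
#' @param target_fs Output sample rate, Hz; must not exceed the audio rate.
#' @param lp Envelope low-pass cutoff, Hz.
#' @param middle_ear Apply [middle_ear_filter()] first (skipped automatically
#'   when the sample rate is too low to realize it).
#' @param method Envelope estimator; only `"hilbert"` is implemented.
#' @return An [envelope_signal()] at `target_fs`.
#' @export
amplitude_envelope <- function(audio, target_fs = 1000, lp = 50,
                               middle_ear = TRUE, method = "hilbert") {
  stopifnot(inherits(audio, "audio_recording"))
  if (target_fs > audio$fs) stop("target_fs exceeds the audio sample rate")
  method <- match.arg(method, "hilbert")
  x <- audio$samples
  if (middle_ear && audio$fs >= 8000) {
    x <- middle_ear_filter(audio)$samples
  }
  env <- Mod(analytic_signal(x))
  h <- design_lowpass_fir(lp, audio$fs, trans = 0.5 * lp)
  env <- filt_zero_phase(env, h)
  env <- resample_sig(env, audio$fs, target_fs)
  envelope_signal(pmax(env, 0), target_fs)
}

#' Write a (time, value) delimited table for an onset or envelope signal
#'
#' @param sig An [onset_signal()] or [envelope_signal()].
#' @param path Output path (tab-separated, two columns with header).
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(sig, path) {
  if (inherits(sig, "onset_signal")) {
    fs <- sig$fs_frames
  } else if (inherits(sig, "envelope_signal")) {
    fs <- sig$fs
  } else stop("unsupported signal type")
  tab <- data.frame(time = (seq_along(sig$values) - 1) / fs,
                    value = sig$values)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
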