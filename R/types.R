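# Lightweight S3 containers shared across the pipeline.

#' Audio recording container
#'
#' @param samples Numeric vector, linear amplitude.
#' @param fs Sample rate in Hz.
#' @param id Recording identifier.
#' @return An object of class `audio_recording`.
#' @export
audio_recording <- function(samples, fs, id = "audio") {
  stopifnot(fs > 0, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), fs = fs, id = id),
            class = "audio_recording")
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording '%s': %.1f s @ %g Hz>\n",
              x$id, length(x$samples) / x$fs, x$fs))
  invisible(x)
}

#' Onset-strength signal
#'
#' Frame-rate non-negative onset strength from complex-domain detection.
#'
#' @param values Non-negative numeric vector, one value per STFT frame.
#' @param fs_frames Frame rate in frames per second.
#' @param stft_params List with `win_sec`, `hop_sec`, `window`.
#' @return An object of class `onset_signal`.
#' @export
onset_signal <- function(values, fs_frames, stft_params = list()) {
  stopifnot(all(values >= 0), fs_frames > 0)
  structure(list(values = as.numeric(values), fs_frames = fs_frames,
                 stft_params = stft_params),
            class = "onset_signal")
}

#' @export
print.onset_signal <- function(x, ...) {
  cat(sprintf("<onset_signal: %d frames @ %.2f fps>\n",
              length(x$values), x$fs_frames))
  invisible(x)
}

#' Amplitude-envelope signal
#'
#' @param values Non-negative numeric vector.
#' @param fs Sample rate in Hz (default analysis rate 1000).
#' @return An object of class `envelope_signal`.
#' @export
envelope_signal <- function(values, fs = 1000) {
  stopifnot(all(values >= 0), fs > 0)
  structure(list(values = as.numeric(values), fs = fs),
            class = "envelope_signal")
}

#' @export
print.envelope_signal <- function(x, ...) {
  cat(sprintf("<envelope_signal: %.1f s @ %g Hz>\n",
              length(x$values) / x$fs, x$fs))
  invisible(x)
}

#' EEG recording container
#'
#' @param data Channels-by-time numeric matrix (microvolts).
#' @param fs Sample rate in Hz.
#' @param labels Character vector of unique channel labels (10-20 names).
#' @param events Data frame with columns `label`, `sample`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels,
                          events = data.frame(label = character(0),
                                              sample = integer(0))) {
  data <- as.matrix(data)
  stopifnot(nrow(data) == length(labels), !anyDuplicated(labels), fs > 0)
  if (nrow(events) && any(events$sample < 1 | events$sample > ncol(data))) {
    stop("event sample indices out of range")
  }
  structure(list(data = data, fs = fs, labels = as.character(labels),
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %d ch x %.1f s @ %g Hz, %d events>\n",
              nrow(x$data), ncol(x$data) / x$fs, x$fs, nrow(x$events)))
  invisible(x)
}
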