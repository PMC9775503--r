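# Minimal RIFF/WAVE reader and writer (PCM 16/32-bit, mono or multi-channel).

#' Read a WAV file
#'
#' Reads a PCM WAV file into an [audio_recording()]. Samples are returned as
#' doubles in \[-1, 1\]. Multi-channel files are averaged to mono.
#'
#' @param path Path to a `.wav` file.
#' @param id Recording identifier; defaults to the file name.
#' @return An `audio_recording`.
#' @export
read_wav <- function(path, id = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL; bits <- NULL; n_chan <- NULL; data <- NULL
  repeat {
    tag <- readChar(con, 4, useBytes = TRUE)
    if (length(tag) == 0 || nchar(tag) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (tag == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little")
      n_chan <- fmt[2]
      fs <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (tag == "data") {
      bytes <- bits / 8
      n <- size / bytes
      data <- readBin(con, "integer", n, bytes, signed = TRUE, endian = "little")
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (!is.null(data) && !is.null(fs)) break
  }
  if (is.null(data)) stop("no data chunk in ", path)
  x <- data / (2^(bits - 1))
  if (n_chan > 1) {
    x <- matrix(x, nrow = n_chan)
    x <- colMeans(x)
  }
  audio_recording(x, fs, id = id)
}

#' Write a WAV file
#'
#' Writes a mono waveform as PCM WAV. Samples are clipped to \[-1, 1\].
#'
#' @param audio An `audio_recording` (or numeric vector with `fs` given).
#' @param path Output path.
#' @param bits Sample width, 16 (default) or 32.
#' @param fs Sample rate, required when `audio` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, bits = 16L, fs = NULL) {
  if (inherits(audio, "audio_recording")) {
    x <- audio$samples
    fs <- audio$fs
  } else {
    x <- as.numeric(audio)
    if (is.null(fs)) stop("fs required when writing a bare vector")
  }
  stopifnot(bits %in% c(16L, 32L))
  x <- pmin(pmax(x, -1), 1)
  scale <- 2^(bits - 1) - 1
  ints <- as.integer(round(x * scale))
  bytes <- bits / 8
  data_size <- length(ints) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")          # PCM
  writeBin(1L, con, 2, endian = "little")          # mono
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * bytes), con, 4, endian = "little")
  writeBin(as.integer(bytes), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  writeBin(ints, con, bytes, endian = "little")
  invisible(path)
}
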