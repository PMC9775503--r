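# BrainVision-style triplet (header .vhdr, markers .vmrk, binary .eeg) and a
# plain delimited channels-by-time fallback.

#' Write an EEG recording as a BrainVision-style triplet
#'
#' Emits `<stem>.vhdr` (text header), `<stem>.vmrk` (text markers) and
#' `<stem>.eeg` (IEEE float32, little-endian, multiplexed) alongside each
#' other, in the layout used by BrainVision amplifiers.
#'
#' @param eeg An [eeg_recording()].
#' @param stem Output path without extension.
#' @return The header path, invisibly.
#' @export
write_brainvision <- function(eeg, stem) {
  stopifnot(inherits(eeg, "eeg_recording"))
  vhdr <- paste0(stem, ".vhdr")
  vmrk <- paste0(stem, ".vmrk")
  dat <- paste0(stem, ".eeg")
  n_chan <- nrow(eeg$data)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", basename(dat)),
    paste0("MarkerFile=", basename(vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_chan),
    paste0("SamplingInterval=", format(1e6 / eeg$fs, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_chan), eeg$labels)
  )
  writeLines(hdr, vhdr)
  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", basename(dat)),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0"
  )
  if (length(eeg$events)) {
    ev <- eeg$events
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_along(ev$label) + 1L, ev$label, ev$sample))
  }
  writeLines(mk, vmrk)
  con <- file(dat, "wb")
  on.exit(close(con))
  # multiplexed: interleave channels sample by sample (column-major of data)
  writeBin(as.numeric(eeg$data), con, size = 4, endian = "little")
  invisible(vhdr)
}

#' Read a BrainVision-style triplet
#'
#' Supports the subset written by [write_brainvision()]: binary multiplexed
#' IEEE float32 or 16-bit integer data with a `[Channel Infos]` section, plus
#' `Stimulus` markers.
#'
#' @param vhdr Path to the `.vhdr` header.
#' @return An [eeg_recording()].
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, warn = FALSE)
  get_kv <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(hit)) stop("missing header key: ", key)
    sub(paste0("^", key, "="), "", hit[1])
  }
  data_file <- file.path(dirname(vhdr), get_kv("DataFile"))
  n_chan <- as.integer(get_kv("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get_kv("SamplingInterval"))
  fmt <- get_kv("BinaryFormat")
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                   `[[`, character(1), 1)
  if (length(labels) != n_chan) stop("channel count mismatch in ", vhdr)
  sz <- file.info(data_file)$size
  if (fmt == "IEEE_FLOAT_32") {
    n <- sz / 4
    raw <- readBin(data_file, "numeric", n, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    n <- sz / 2
    raw <- readBin(data_file, "integer", n, size = 2, signed = TRUE,
                   endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  data <- matrix(raw, nrow = n_chan)
  vmrk <- file.path(dirname(vhdr), get_kv("MarkerFile"))
  events <- data.frame(label = character(0), sample = integer(0))
  if (file.exists(vmrk)) {
    ml <- grep("^Mk[0-9]+=Stimulus,", readLines(vmrk, warn = FALSE), value = TRUE)
    if (length(ml)) {
      parts <- strsplit(sub("^Mk[0-9]+=", "", ml), ",")
      events <- data.frame(
        label = vapply(parts, `[[`, character(1), 2),
        sample = as.integer(vapply(parts, `[[`, character(1), 3))
      )
    }
  }
  eeg_recording(data, fs, labels, events = events)
}

#' Write an EEG recording as a delimited channels-by-time table
#'
#' Tab-separated; first column `label`, remaining columns samples. A sidecar
#' JSON (`<path>.json`) stores the sample rate and events.
#'
#' @param eeg An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eeg_table <- function(eeg, path) {
  tab <- data.frame(label = eeg$labels, eeg$data, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(fs = eeg$fs, events = eeg$events)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a delimited channels-by-time EEG table
#'
#' @param path Path written by [write_eeg_table()].
#' @return An [eeg_recording()].
#' @export
read_eeg_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  labels <- as.character(tab[[1]])
  data <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(data) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  events <- meta$events
  if (is.null(events) || !length(events)) {
    events <- data.frame(label = character(0), sample = integer(0))
  }
  eeg_recording(data, meta$fs, labels, events = as.data.frame(events))
}
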