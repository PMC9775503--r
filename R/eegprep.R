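# Deterministic EEG preprocessing chain: epoching to the stimulation period,
# resampling, mastoid re-referencing, band-pass + notch filtering, and
# joint-probability bad-channel flagging.

#' Trim an EEG recording to the stimulation period
#'
#' Keeps activity from 1 s before the first recording-start event to 1 s
#' after the last recording-end event, removing superfluous activity outside
#' the stimulation. Event indices are shifted into the trimmed time base.
#'
#' @param eeg An [eeg_recording()] with `start` / `end` events.
#' @param start_label,end_label Event labels marking recording boundaries.
#' @param margin Seconds kept on each side.
#' @return A trimmed [eeg_recording()].
#' @export
epoch_to_stimulation <- function(eeg, start_label = "start",
                                 end_label = "end", margin = 1) {
  stopifnot(inherits(eeg, "eeg_recording"))
  ev <- eeg$events
  starts <- ev$sample[ev$label == start_label]
  ends <- ev$sample[ev$label == end_label]
  if (!length(starts) || !length(ends)) {
    stop("missing events; expected labels '", start_label, "' and '",
         end_label, "'")
  }
  m <- round(margin * eeg$fs)
  i0 <- min(starts) - m
  i1 <- max(ends) + m
  if (i0 < 1 || i1 > ncol(eeg$data)) {
    stop("recording leaves less than ", margin, " s margin around the events")
  }
  keep <- ev$sample >= i0 & ev$sample <= i1
  ev <- ev[keep, , drop = FALSE]
  ev$sample <- ev$sample - i0 + 1L
  eeg_recording(eeg$data[, i0:i1, drop = FALSE], eeg$fs, eeg$labels, ev)
}

#' Down-sample an EEG recording
#'
#' Anti-alias filtered down-sampling (e.g. the acquisition 5000 Hz to the
#' 1000 Hz analysis rate). Identity when the rates match; up-sampling is an
#' error.
#'
#' @param eeg An [eeg_recording()].
#' @param new_fs Target rate in Hz.
#' @return The resampled [eeg_recording()].
#' @export
eeg_resample <- function(eeg, new_fs = 1000) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (new_fs > eeg$fs) stop("up-sampling requested; new_fs must be <= fs")
  if (new_fs == eeg$fs) return(eeg)
  out <- t(resample_sig(t(eeg$data), eeg$fs, new_fs))
  ev <- eeg$events
  if (nrow(ev)) {
    ev$sample <- pmin(pmax(round((ev$sample - 1L) * new_fs / eeg$fs) + 1L, 1L),
                      ncol(out))
  }
  eeg_recording(out, new_fs, eeg$labels, ev)
}

#' Re-reference to the bilateral mastoids
#'
#' Subtracts the mean of TP9 and TP10 from every channel and drops the two
#' reference channels from the analysis set.
#'
#' @param eeg An [eeg_recording()] containing both mastoid channels.
#' @param refs Reference channel labels.
#' @return The re-referenced [eeg_recording()] without the mastoid rows.
#' @export
rereference_mastoids <- function(eeg, refs = c("TP9", "TP10")) {
  stopifnot(inherits(eeg, "eeg_recording"))
  miss <- setdiff(refs, eeg$labels)
  if (length(miss)) stop("missing mastoid channel(s): ",
                         paste(miss, collapse = ", "))
  ref_rows <- match(refs, eeg$labels)
  common <- colMeans(eeg$data[ref_rows, , drop = FALSE])
  keep <- setdiff(seq_len(nrow(eeg$data)), ref_rows)
  out <- sweep(eeg$data[keep, , drop = FALSE], 2, common)
  eeg_recording(out, eeg$fs, eeg$labels[keep], eeg$events)
}

#' Zero-phase band-pass plus line-noise notch
#'
#' High-pass (default 1 Hz) and low-pass (default 55 Hz) with Hamming
#' windowed-sinc FIR filters (transition width 25% of cutoff), applied with
#' zero phase; DC is removed. Residual line noise is removed with a
#' zero-phase IIR notch (biquad, Q = 30) at `line` Hz; the notch is skipped
#' when the line frequency lies outside the band that survives sampling.
#'
#' @param eeg An [eeg_recording()] with `fs > 2 * lp`.
#' @param hp,lp Band edges in Hz.
#' @param line Line frequency in Hz.
#' @param notch_q Notch quality factor.
#' @return The filtered [eeg_recording()].
#' @export
bandpass_and_notch <- function(eeg, hp = 1, lp = 55, line = 60,
                               notch_q = 30) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (lp >= eeg$fs / 2) stop("low-pass cutoff must be below Nyquist")
  x <- t(eeg$data)
  x <- sweep(x, 2, colMeans(x))
  h_hp <- design_highpass_fir(hp, eeg$fs)
  h_lp <- design_lowpass_fir(lp, eeg$fs)
  x <- filt_zero_phase(x, h_hp)
  x <- filt_zero_phase(x, h_lp)
  if (!is.null(line) && line < eeg$fs / 2) {
    w0 <- 2 * pi * line / eeg$fs
    alpha <- sin(w0) / (2 * notch_q)
    b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
    a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
    for (j in seq_len(ncol(x))) {
      x[, j] <- signal::filtfilt(signal::Arma(b = b, a = a), x[, j])
    }
  }
  eeg_recording(t(x), eeg$fs, eeg$labels, eeg$events)
}

#' Flag bad channels by joint probability
#'
#' Computes, per channel, the mean negative log-probability of its samples
#' under an amplitude density estimated from the pooled ensemble of all
#' channels, z-scores that statistic across channels, and flags channels
#' whose normalized score exceeds `z` standard deviations (default 5).
#' Channels with aberrant amplitude distributions (e.g. huge variance) land
#' deep in the ensemble tails and score high.
#'
#' @param eeg An [eeg_recording()] with at least 8 channels.
#' @param z Normalized threshold in standard deviations; `Inf` flags none.
#' @param nbins Histogram bins for the pooled density estimate.
#' @return Character vector of flagged channel labels (possibly empty).
#' @export
flag_bad_channels <- function(eeg, z = 5, nbins = 200) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (nrow(eeg$data) < 8) stop("need at least 8 channels for a stable ensemble estimate")
  pooled <- as.numeric(eeg$data)
  rng <- range(pooled)
  if (diff(rng) == 0) return(character(0))
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(pooled, breaks,
                                            all.inside = TRUE), 1L), nbins),
                     nbins)
  p <- counts / length(pooled)
  eps <- 1 / (length(pooled) * nbins)
  p <- pmax(p, eps)
  jp <- apply(eeg$data, 1, function(row) {
    bin <- pmin(pmax(findInterval(row, breaks, all.inside = TRUE), 1L), nbins)
    -mean(log(p[bin]))
  })
  # leave-one-out normalization: a single aberrant channel would otherwise
  # inflate the ensemble s.d. enough to mask itself
  score <- vapply(seq_along(jp), function(i) {
    s <- stats::sd(jp[-i])
    if (!is.finite(s) || s == 0) return(0)
    (jp[i] - mean(jp[-i])) / s
  }, numeric(1))
  eeg$labels[score > z]
}

#' Run the full deterministic preprocessing chain
#'
#' Epoch to the stimulation period (when events are present), resample to the
#' analysis rate, re-reference to the mastoids (when present), band-pass +
#' notch filter, and drop joint-probability-flagged channels.
#'
#' @param eeg An [eeg_recording()].
#' @param analysis_fs Analysis sample rate, Hz.
#' @param hp,lp,line Filter settings; the low-pass is capped below Nyquist of
#'   the analysis rate.
#' @param z Bad-channel threshold.
#' @return A preprocessed [eeg_recording()].
#' @export
preprocess_eeg <- function(eeg, analysis_fs = 1000, hp = 1, lp = 55,
                           line = 60, z = 5) {
  if (nrow(eeg$events) &&
      all(c("start", "end") %in% eeg$events$label)) {
    eeg <- epoch_to_stimulation(eeg)
  }
  if (analysis_fs < eeg$fs) eeg <- eeg_resample(eeg, analysis_fs)
  if (all(c("TP9", "TP10") %in% eeg$labels)) {
    eeg <- rereference_mastoids(eeg)
  }
  lp_eff <- min(lp, 0.45 * eeg$fs)
  line_eff <- if (line < eeg$fs / 2) line else NULL
  eeg <- bandpass_and_notch(eeg, hp = hp, lp = lp_eff, line = line_eff)
  if (nrow(eeg$data) >= 8) {
    bad <- flag_bad_channels(eeg, z = z)
    if (length(bad)) {
      keep <- !(eeg$labels %in% bad)
      eeg <- eeg_recording(eeg$data[keep, , drop = FALSE], eeg$fs,
                           eeg$labels[keep], eeg$events)
    }
  }
  eeg
}
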