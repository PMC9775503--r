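# Gradient-frequency network of canonical Hopf oscillators: pulse/meter
# estimation from an onset signal, and the stable-epoch detector gating
# recordings into the entrainment analysis.

#' Oscillator-bank parameters
#'
#' A gradient-frequency bank of canonical Hopf oscillators. Each oscillator
#' `i` with natural frequency `f_i` evolves (in its own cycle time) as
#' `dz/dt = f_i * ( z * (alpha + i 2 pi + beta1 |z|^2 +
#' eps beta2 |z|^4 / (1 - eps |z|^2)) + c * s(t) )`,
#' driven by the common onset signal `s(t)`. The default regime is the
#' critical Hopf (`alpha = 0`, `beta1 < 0`, `beta2 < 0`): undriven
#' oscillators decay to rest, driven ones resonate selectively near the
#' stimulus frequencies and their harmonic ratios.
#'
#' @param freqs Natural frequencies in Hz, strictly increasing; default a
#'   log-spaced grid with 15 bins per octave over 0.25-8 Hz (76 oscillators),
#'   matching the wavelet density of the PLV analysis.
#' @param alpha,beta1,beta2,epsilon Hopf parameters.
#' @param c_gain Coupling gain applied to the onset signal.
#' @param fs_int Fixed-step integration rate, Hz (RK4).
#' @param smooth_sec Width (s) of the raised-cosine smoothing applied to the
#'   onset signal before it drives the bank. Broadens each onset pulse so
#'   the forcing spectrum rolls off with harmonic number, favoring the
#'   perceived (slower) pulse over its subdivisions, much as perceptual
#'   accent does; 0 disables.
#' @return An object of class `oscillator_bank_params`.
#' @export
oscillator_bank_params <- function(freqs = 0.25 * 2^((0:75) / 15),
                                   alpha = 0, beta1 = -1, beta2 = -0.25,
                                   epsilon = 1, c_gain = 1, fs_int = 250,
                                   smooth_sec = 0.25) {
  stopifnot(all(diff(freqs) > 0), fs_int > 2 * max(freqs), smooth_sec >= 0)
  structure(list(freqs = freqs, alpha = alpha, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, c_gain = c_gain, fs_int = fs_int,
                 smooth_sec = smooth_sec),
            class = "oscillator_bank_params")
}

#' Drive the oscillator bank with an onset signal
#'
#' Integrates the bank with fixed-step RK4 at `params$fs_int` after linearly
#' resampling the onset signal to the integration rate, smoothing it (see
#' [oscillator_bank_params()]), and normalizing its 99th percentile to 1 so
#' the coupling gain has a consistent meaning across recordings. Returns the
#' amplitude trajectories `|z_i(t)|`.
#'
#' @param onset An [onset_signal()] of at least 10 s.
#' @param params An [oscillator_bank_params()].
#' @return An object of class `oscillator_bank_run`: `amplitudes`
#'   (oscillators-by-time), `freqs`, `fs` (the integration rate), `duration`.
#' @export
run_bank <- function(onset, params = oscillator_bank_params()) {
  stopifnot(inherits(onset, "onset_signal"))
  dur <- length(onset$values) / onset$fs_frames
  if (dur < 10) stop("onset signal shorter than 10 s")
  fs <- params$fs_int
  dt <- 1 / fs
  n <- floor(dur * fs)
  t_old <- (seq_along(onset$values) - 1) / onset$fs_frames
  # forcing at full and half steps for the RK4 stages
  t_fine <- (0:(2 * n)) * (dt / 2)
  s_fine <- stats::approx(t_old, onset$values, xout = t_fine, rule = 2)$y
  if (params$smooth_sec > 0) {
    nw <- max(3L, round(params$smooth_sec * 2 * fs))
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = nw))
    s_fine <- as.numeric(stats::filter(s_fine, w / sum(w), sides = 2))
    s_fine[is.na(s_fine)] <- 0
  }
  pos <- s_fine[s_fine > 0]
  if (length(pos)) s_fine <- s_fine / stats::quantile(pos, 0.99)
  f <- params$freqs
  nf <- length(f)
  al <- params$alpha; b1 <- params$beta1; b2 <- params$beta2
  ep <- params$epsilon; cg <- params$c_gain
  i2pi <- 2i * pi
  deriv <- function(z, s) {
    a2 <- Re(z)^2 + Im(z)^2
    # the damping denominator is floored so a transient RK4 stage past the
    # |z|^2 = 1/eps bound damps hard instead of flipping sign
    f * (z * (al + i2pi + b1 * a2 +
                ep * b2 * a2^2 / pmax(1 - ep * a2, 1e-3)) + cg * s)
  }
  z <- complex(real = rep(1e-3, nf), imaginary = rep(0, nf))
  amps <- matrix(0, nf, n)
  for (step in seq_len(n)) {
    s0 <- s_fine[2 * step - 1]
    sh <- s_fine[2 * step]
    s1 <- s_fine[2 * step + 1]
    k1 <- deriv(z, s0)
    k2 <- deriv(z + dt / 2 * k1, sh)
    k3 <- deriv(z + dt / 2 * k2, sh)
    k4 <- deriv(z + dt * k3, s1)
    z <- z + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    a2 <- Re(z)^2 + Im(z)^2
    if (any(ep * a2 >= 1)) {
      bad <- which(ep * a2 >= 1)[1]
      stop(sprintf("oscillator amplitude blow-up at %.2f Hz, t = %.2f s",
                   f[bad], step * dt))
    }
    amps[, step] <- sqrt(a2)
  }
  structure(list(amplitudes = amps, freqs = f, fs = fs, duration = n * dt),
            class = "oscillator_bank_run")
}

#' @export
print.oscillator_bank_run <- function(x, ...) {
  cat(sprintf("<oscillator_bank_run: %d oscillators x %.1f s @ %g Hz>\n",
              length(x$freqs), x$duration, x$fs))
  invisible(x)
}

# Salience profile (time-averaged amplitude) over a window, plus the pulse /
# harmonic / subharmonic selection rules. Returns NULL when no pulse peak is
# found. Shared by the public estimator and the stability tracker.
#' @keywords internal
est_freqs_quiet <- function(run, window, delta_max = 3.5, ratio_tol = 0.06,
                            min_prominence = 2) {
  i0 <- max(1L, floor(window[1] * run$fs) + 1L)
  i1 <- min(ncol(run$amplitudes), ceiling(window[2] * run$fs))
  if (i1 <= i0) return(NULL)
  sal <- rowMeans(run$amplitudes[, i0:i1, drop = FALSE])
  freqs <- run$freqs
  delta <- which(freqs <= delta_max)
  if (!length(delta)) return(NULL)
  sd_ <- sal[delta]
  # require an interior local maximum with some prominence over the
  # delta-range floor; a flat/noise-driven profile has neither
  cand <- delta[sd_ == max(sd_)]
  p_idx <- cand[1]                      # ties: lower frequency wins
  is_local_max <- (p_idx == 1 || sal[p_idx] >= sal[p_idx - 1]) &&
    (p_idx == length(freqs) || sal[p_idx] >= sal[p_idx + 1])
  if (!is_local_max) return(NULL)
  if (max(sd_) < min_prominence * stats::median(sd_)) return(NULL)
  pulse <- freqs[p_idx]
  # harmonic: most salient theta-range oscillator near an integer multiple
  th <- which(freqs >= delta_max & seq_along(freqs) != p_idx)
  harmonic <- NA_real_; sal_h <- NA_real_
  if (length(th)) {
    mult <- round(freqs[th] / pulse)
    ok <- mult >= 2 & abs(freqs[th] / (mult * pulse) - 1) <= ratio_tol
    if (any(ok)) {
      hcand <- th[ok]
      h_idx <- hcand[which.max(sal[hcand])]
      harmonic <- freqs[h_idx]; sal_h <- sal[h_idx]
    }
  }
  # subharmonic: most salient oscillator near pulse/2 or pulse/3
  sub_idx <- which(abs(freqs / (pulse / 2) - 1) <= ratio_tol |
                     abs(freqs / (pulse / 3) - 1) <= ratio_tol)
  subharmonic <- NA_real_; sal_s <- NA_real_
  if (length(sub_idx)) {
    s_idx <- sub_idx[which.max(sal[sub_idx])]
    subharmonic <- freqs[s_idx]; sal_s <- sal[s_idx]
  }
  list(pulse = pulse, harmonic = harmonic, subharmonic = subharmonic,
       saliences = c(pulse = sal[p_idx], harmonic = sal_h,
                     subharmonic = sal_s))
}

#' Estimate pulse, harmonic, and subharmonic frequencies
#'
#' Salience is the time-averaged oscillator amplitude over the window. The
#' pulse is the most salient frequency in the delta range (<= 3.5 Hz,
#' inclusive); the harmonic is the most salient theta-range (>= 3.5 Hz)
#' oscillator lying within `ratio_tol` of an integer multiple of the pulse;
#' the subharmonic is the most salient oscillator near pulse/2 or pulse/3.
#' An oscillator at exactly 3.5 Hz may serve either role, but the pulse takes
#' precedence; absent harmonic/subharmonic are reported as `NA`. Equal
#' saliences break toward the lower frequency (the slower, more commonly
#' perceived pulse). A flat delta-range profile (no local maximum, or peak
#' salience below `min_prominence` times the delta-range median) raises a
#' "no pulse detected" error.
#'
#' @param run An [run_bank()] result.
#' @param window Two-element `c(t0, t1)` in seconds, inside the run.
#' @param delta_max Delta/theta boundary, Hz.
#' @param ratio_tol Relative tolerance for harmonic-ratio admissibility.
#' @param min_prominence Peak-to-median salience ratio below which no pulse
#'   is declared.
#' @return An object of class `pulse_estimate`: `pulse`, `harmonic`,
#'   `subharmonic` (Hz, `NA` when absent) and `saliences`.
#' @export
estimate_metrical_frequencies <- function(run, window = c(0, run$duration),
                                          delta_max = 3.5, ratio_tol = 0.06,
                                          min_prominence = 2) {
  stopifnot(inherits(run, "oscillator_bank_run"))
  if (window[1] < 0 || window[2] > run$duration + 1e-9) {
    stop("window outside run")
  }
  est <- est_freqs_quiet(run, window, delta_max, ratio_tol, min_prominence)
  if (is.null(est)) stop("no pulse detected")
  structure(est, class = "pulse_estimate")
}

#' @export
print.pulse_estimate <- function(x, ...) {
  cat(sprintf("<pulse_estimate: pulse %.3g Hz, subharmonic %.3g, harmonic %.3g>\n",
              x$pulse, x$subharmonic, x$harmonic))
  invisible(x)
}

#' Find the first stable-tempo epoch
#'
#' Slides a short analysis window over the run, tracks the pulse, harmonic
#' and subharmonic frequencies, and returns the earliest interval of at
#' least `min_len` seconds in which every tracked frequency stays within
#' `tol` (relative) of its interval median. Tracks that are absent in more
#' than half of the windows are ignored; within a candidate interval, a
#' window in which a normally-present track disappears breaks stability.
#' Recordings with no such interval are excluded from the entrainment
#' analysis.
#'
#' @param run An [run_bank()] result.
#' @param min_len Minimum epoch length, seconds (default 120 = 2 min).
#' @param tol Relative stability tolerance (default 0.04, "a few percent").
#' @param win,hop Tracking window length and hop, seconds.
#' @param startup_exempt Seconds at the start of the run whose fine-grained
#'   blocks are exempt from the boundary check (the bank rings up from rest,
#'   which is not a property of the stimulus).
#' @param ... Passed to the frequency estimator.
#' @return A `stable_epoch` (list with `start`, `end`, `estimate`) or `NULL`
#'   when no stable interval of the required length exists.
#' @export
find_stable_epoch <- function(run, min_len = 120, tol = 0.04,
                              win = 10, hop = 1, startup_exempt = 3, ...) {
  stopifnot(inherits(run, "oscillator_bank_run"))
  if (run$duration < min_len) return(NULL)
  starts <- seq(0, run$duration - win, by = hop)
  if (!length(starts)) return(NULL)
  tracks <- vapply(starts, function(s) {
    est <- est_freqs_quiet(run, c(s, s + win), ...)
    if (is.null(est)) c(NA_real_, NA_real_, NA_real_)
    else c(est$pulse, est$harmonic, est$subharmonic)
  }, numeric(3))
  use_track <- c(TRUE,
                 mean(is.na(tracks[2, ])) <= 0.5,
                 mean(is.na(tracks[3, ])) <= 0.5)
  # fine-grained (one hop) delta-range amplitude argmax: sharpens epoch
  # boundaries beyond the win-length blur of the sliding windows
  delta <- which(run$freqs <= 3.5)
  nb <- floor(run$duration / hop)
  blocks <- vapply(seq_len(nb), function(b) {
    i0 <- round((b - 1) * hop * run$fs) + 1L
    i1 <- min(round(b * hop * run$fs), ncol(run$amplitudes))
    sal <- rowMeans(run$amplitudes[delta, i0:i1, drop = FALSE])
    run$freqs[delta][which.max(sal)]
  }, numeric(1))
  grid_step <- stats::median(diff(log2(run$freqs)))
  first_block <- floor(startup_exempt / hop) + 1L
  nw <- length(starts)
  stable_span <- function(i, j) {
    for (r in which(use_track)) {
      v <- tracks[r, i:j]
      if (anyNA(v)) return(FALSE)
      med <- stats::median(v)
      if (max(abs(v / med - 1)) > tol) return(FALSE)
    }
    b0 <- max(floor(starts[i] / hop) + 1L, first_block)
    b1 <- min(floor((starts[j] + win) / hop), nb)
    if (b0 <= b1) {
      med_p <- stats::median(tracks[1, i:j])
      if (any(abs(log2(blocks[b0:b1] / med_p)) > 1.1 * grid_step)) {
        return(FALSE)
      }
    }
    TRUE
  }
  for (i in seq_len(nw)) {
    # smallest j reaching min_len from start i
    j0 <- which(starts + win - starts[i] >= min_len)[1]
    if (is.na(j0) || j0 > nw) break
    if (!stable_span(i, j0)) next
    j <- j0
    while (j < nw && stable_span(i, j + 1)) j <- j + 1
    epoch <- c(starts[i], starts[j] + win)
    est <- estimate_metrical_frequencies(run, epoch, ...)
    return(structure(list(start = epoch[1], end = epoch[2], estimate = est),
                     class = "stable_epoch"))
  }
  NULL
}

#' @export
print.stable_epoch <- function(x, ...) {
  cat(sprintf("<stable_epoch: [%.1f, %.1f] s, pulse %.3g Hz>\n",
              x$start, x$end, x$estimate$pulse))
  invisible(x)
}

#' Write a per-recording music-feature JSON summary
#'
#' @param epoch A `stable_epoch` or `NULL` (recording excluded).
#' @param path Output JSON path.
#' @param id Recording identifier.
#' @return `path`, invisibly.
#' @export
write_pulse_json <- function(epoch, path, id = "recording") {
  if (is.null(epoch)) {
    out <- list(id = id, survived = FALSE)
  } else {
    est <- epoch$estimate
    out <- list(id = id, survived = TRUE,
                pulse = est$pulse,
                subharmonic = est$subharmonic,
                harmonic = est$harmonic,
                epoch_start = epoch$start, epoch_end = epoch$end)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
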