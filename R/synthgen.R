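# Synthetic music, EEG, and cohort generation with known ground truth.

#' Specification of a synthetic percussive recording
#'
#' Defines a click-train stimulus with a metrical accent structure. Musical
#' pulse occurs naturally in 0.5-4 Hz (modal ~2 Hz), so pulse frequencies are
#' constrained to that range. The tempo profile is piecewise constant: the
#' inter-onset interval at time t is `1 / tempo_profile(t)`.
#'
#' @param pulse_freq Pulse frequency in Hz, in \[0.5, 4\].
#' @param duration Total duration in seconds (> 0).
#' @param meter Integer beats per measure; every `meter`-th event is
#'   accented, creating a subharmonic accent cycle.
#' @param tempo_profile Optional data frame with columns `time`, `freq`
#'   (piecewise-constant pulse frequency from each `time` onward); overrides
#'   `pulse_freq` where defined. All values must lie in \[0.5, 4\].
#' @param click_timbre `"click"` (5-ms raised-cosine noise burst) or
#'   `"burst"` (20 ms).
#' @param noise_floor Linear amplitude of the added broadband noise floor.
#' @param accent_depth Amplitude reduction of unaccented events (0 = no
#'   accents; unaccented amplitude is `1 - accent_depth`).
#' @param fs Audio sample rate in Hz.
#' @return An object of class `music_spec`.
#' @export
music_spec <- function(pulse_freq = 2, duration = 180, meter = 2L,
                       tempo_profile = NULL, click_timbre = c("click", "burst"),
                       noise_floor = 0.001, accent_depth = 0.4, fs = 12000) {
  click_timbre <- match.arg(click_timbre)
  stopifnot(duration > 0, meter >= 1,
            pulse_freq >= 0.5, pulse_freq <= 4,
            noise_floor >= 0, accent_depth >= 0, accent_depth < 1)
  if (!is.null(tempo_profile)) {
    stopifnot(is.data.frame(tempo_profile),
              all(c("time", "freq") %in% names(tempo_profile)),
              all(tempo_profile$freq >= 0.5 & tempo_profile$freq <= 4))
    tempo_profile <- tempo_profile[order(tempo_profile$time), ]
  }
  structure(list(pulse_freq = pulse_freq, duration = duration,
                 meter = as.integer(meter), tempo_profile = tempo_profile,
                 click_timbre = click_timbre, noise_floor = noise_floor,
                 accent_depth = accent_depth, fs = fs),
            class = "music_spec")
}

#' @keywords internal
tempo_at <- function(spec, t) {
  if (is.null(spec$tempo_profile)) return(spec$pulse_freq)
  tp <- spec$tempo_profile
  idx <- findInterval(t, tp$time)
  if (idx == 0) spec$pulse_freq else tp$freq[idx]
}

#' Generate a synthetic percussive recording
#'
#' Renders percussive events (raised-cosine windowed noise bursts) at onset
#' times dictated by the tempo profile, with every `meter`-th event accented.
#' The exact ground truth (onset times, accent flags, pulse track) is
#' returned alongside the waveform.
#'
#' @param spec A [music_spec()].
#' @param seed Integer seed; output is bit-identical for identical seeds.
#' @return A list of class `music_fixture`: `audio` ([audio_recording()]),
#'   `onsets` (seconds), `accents` (logical), `pulse_track` (data frame
#'   `time`, `freq` describing the piecewise-constant pulse frequency).
#' @export
gen_music <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "music_spec"))
  if (spec$duration < 1 / tempo_at(spec, 0)) {
    stop("duration too short to contain one beat")
  }
  set.seed(child_seed(seed, 1))
  onsets <- numeric(0)
  t <- 0
  while (t < spec$duration - 1e-9) {
    onsets <- c(onsets, t)
    t <- t + 1 / tempo_at(spec, t)
  }
  accents <- (seq_along(onsets) - 1L) %% spec$meter == 0L
  fs <- spec$fs
  n <- round(spec$duration * fs)
  x <- numeric(n)
  burst_len <- round(switch(spec$click_timbre, click = 0.005, burst = 0.020) * fs)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(burst_len) - 1) / (burst_len - 1))
  for (i in seq_along(onsets)) {
    i0 <- round(onsets[i] * fs) + 1L
    i1 <- min(i0 + burst_len - 1L, n)
    len <- i1 - i0 + 1L
    amp <- if (accents[i]) 1 else 1 - spec$accent_depth
    x[i0:i1] <- x[i0:i1] + amp * win[seq_len(len)] * stats::rnorm(len)
  }
  if (spec$noise_floor > 0) x <- x + spec$noise_floor * stats::rnorm(n)
  x <- 0.9 * x / max(abs(x))
  if (is.null(spec$tempo_profile)) {
    track <- data.frame(time = 0, freq = spec$pulse_freq)
  } else {
    track <- spec$tempo_profile
    if (track$time[1] > 0) {
      track <- rbind(data.frame(time = 0, freq = spec$pulse_freq), track)
    }
  }
  structure(list(audio = audio_recording(x, fs, id = "synthetic"),
                 onsets = onsets, accents = accents, pulse_track = track),
            class = "music_fixture")
}

#' Default EEG channel montage
#'
#' The 54 electrodes of the nine auditory-research clusters plus the
#' bilateral mastoid reference channels TP9 and TP10.
#'
#' @return Character vector of 56 channel labels.
#' @export
default_channels <- function() {
  c(unlist(electrode_clusters(), use.names = FALSE), "TP9", "TP10")
}

#' Specification of synthetic phase-locked EEG
#'
#' Each channel is a sum over metrical levels of
#' `kappa(channel, level) * cos(envelope phase at that level + jitter)` plus
#' 1/f background noise. `kappa = 0` channels contain only noise; with
#' `kappa` large relative to the noise, the channel phase-locks tightly to
#' the envelope at that level, so the downstream PLV is a monotone function
#' of `kappa`. Phase jitter is an Ornstein-Uhlenbeck process (correlation
#' time `jitter_tau`) so that it is slow relative to the wavelet analysis and
#' genuinely degrades phase-locking.
#'
#' @param channels Channel labels (default [default_channels()]).
#' @param fs Sample rate in Hz; must exceed twice the highest generated
#'   component frequency.
#' @param coupling Data frame with columns `channel`,
#'   `level` (one of `"sub"`, `"pulse"`, `"harmonic"`), `kappa` (>= 0).
#'   Channels not listed get `kappa = 0`.
#' @param noise_exponent 1/f spectral slope of the background noise.
#' @param noise_rms RMS amplitude of the background noise (same units as
#'   `kappa`).
#' @param phase_jitter Stationary s.d. of the phase noise, radians.
#' @param jitter_tau Correlation time of the phase noise, seconds.
#' @param seed Integer seed.
#' @return An object of class `eeg_spec`.
#' @export
eeg_spec <- function(channels = default_channels(), fs = 1000,
                     coupling = NULL, noise_exponent = 1, noise_rms = 1,
                     phase_jitter = 0, jitter_tau = 1, seed = 1L) {
  if (is.null(coupling)) {
    coupling <- data.frame(channel = character(0), level = character(0),
                           kappa = numeric(0))
  }
  stopifnot(all(coupling$kappa >= 0),
            all(coupling$level %in% c("sub", "pulse", "harmonic")))
  bad <- setdiff(coupling$channel, channels)
  if (length(bad)) stop("unknown channel label(s): ", paste(bad, collapse = ", "))
  structure(list(channels = channels, fs = fs, coupling = coupling,
                 noise_exponent = noise_exponent, noise_rms = noise_rms,
                 phase_jitter = phase_jitter, jitter_tau = jitter_tau,
                 seed = as.integer(seed)),
            class = "eeg_spec")
}

# Instantaneous envelope phase at one metrical level, via the Morlet kernel
# the entrainment analysis itself uses at that frequency.
#' @keywords internal
envelope_phase_at <- function(env_values, fs, freq) {
  cycles <- min(max(round(2 * freq), 3), 8)
  sigma <- cycles / (2 * pi * freq)
  h <- ceiling(4 * sigma * fs)
  t <- seq(-h, h) / fs
  g <- exp(-t^2 / (2 * sigma^2))
  kern <- g * exp(2i * pi * freq * t) / sum(g)
  Arg(conv_same(env_values - mean(env_values), kern))
}

#' Generate synthetic EEG phase-locked to an envelope
#'
#' @param envelope An [envelope_signal()] (or numeric vector at `env_fs`)
#'   whose sample rate equals, or is an integer multiple of, `spec$fs`.
#' @param spec An [eeg_spec()].
#' @param pulse_freq Ground-truth pulse frequency of the envelope, Hz; the
#'   three metrical levels are `pulse/2`, `pulse`, `2*pulse`.
#' @param env_fs Envelope sample rate when `envelope` is a bare vector.
#' @return An [eeg_recording()] at `spec$fs`.
#' @export
gen_eeg <- function(envelope, spec, pulse_freq = 2, env_fs = NULL) {
  stopifnot(inherits(spec, "eeg_spec"))
  if (inherits(envelope, "envelope_signal")) {
    env_fs <- envelope$fs
    envelope <- envelope$values
  }
  if (is.null(env_fs)) stop("env_fs required for a bare envelope vector")
  ratio <- env_fs / spec$fs
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1) {
    stop("envelope sample rate must equal or be an integer multiple of the EEG rate")
  }
  ratio <- as.integer(round(ratio))
  level_freqs <- c(sub = pulse_freq / 2, pulse = pulse_freq,
                   harmonic = 2 * pulse_freq)
  if (spec$fs <= 2 * max(level_freqs)) {
    stop("EEG sample rate too low for the generated component frequencies")
  }
  set.seed(spec$seed)
  phases <- lapply(level_freqs, function(f) {
    ph <- envelope_phase_at(envelope, env_fs, f)
    ph[seq(1L, length(ph), by = ratio)]
  })
  n <- length(phases[[1]])
  a_ou <- exp(-1 / (spec$jitter_tau * spec$fs))
  s_ou <- spec$phase_jitter * sqrt(1 - a_ou^2)
  data <- matrix(0, length(spec$channels), n)
  for (ch in seq_along(spec$channels)) {
    row <- numeric(n)
    cc <- spec$coupling[spec$coupling$channel == spec$channels[ch], , drop = FALSE]
    if (nrow(cc)) {
      for (r in seq_len(nrow(cc))) {
        k <- cc$kappa[r]
        if (k <= 0) next
        ph <- phases[[cc$level[r]]]
        if (spec$phase_jitter > 0) {
          jit <- as.numeric(stats::filter(stats::rnorm(n, sd = s_ou), a_ou,
                                          method = "recursive"))
          ph <- ph + jit
        }
        row <- row + k * cos(ph)
      }
    }
    if (spec$noise_rms > 0) {
      row <- row + spec$noise_rms *
        one_over_f_noise(n, spec$noise_exponent, spec$fs)
    }
    data[ch, ] <- row
  }
  eeg_recording(data, spec$fs, spec$channels)
}

#' Specification of a synthetic two-group cohort
#'
#' Emulates the study design: two age groups (YA, OA) of `n_per_group`
#' participants, each contributing `recordings_per_participant` self-selected
#' recordings. Pulse frequencies are drawn per recording from a log-normal
#' distribution with mode 2 Hz truncated to \[0.5, 4\] (the unimodal shape
#' of naturally occurring musical pulse). Coupling strength is
#' `base_kappa[level]`, multiplied by `group_effect` for OA participants and
#' by any `(group, cluster, level)` modifiers in `cluster_effect`.
#'
#' @param n_per_group Participants per group (>= 1).
#' @param recordings_per_participant Recordings per participant (default 6).
#' @param group_effect Multiplicative kappa ratio OA / YA (>= 0).
#' @param cluster_effect Optional data frame `group`, `cluster`, `level`,
#'   `modifier` (multiplicative, >= 0).
#' @param base_kappa Named numeric, baseline coupling per level.
#' @param noise_rms,phase_jitter,noise_exponent Passed to [eeg_spec()].
#' @param duration Recording duration in seconds.
#' @param audio_fs,eeg_fs Sample rates for generated artifacts.
#' @param pulse_sigma Log-scale s.d. of the pulse-frequency distribution.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 16L, recordings_per_participant = 6L,
                        group_effect = 1, cluster_effect = NULL,
                        base_kappa = c(sub = 0.15, pulse = 0.3,
                                       harmonic = 0.15),
                        noise_rms = 1, phase_jitter = 1, noise_exponent = 1,
                        duration = 150, audio_fs = 12000, eeg_fs = 1000,
                        pulse_sigma = 0.35, seed = 1L) {
  stopifnot(n_per_group >= 1, recordings_per_participant >= 1,
            group_effect >= 0, all(base_kappa >= 0))
  if (!is.null(cluster_effect)) {
    stopifnot(is.data.frame(cluster_effect),
              all(c("group", "cluster", "level", "modifier") %in%
                    names(cluster_effect)),
              all(cluster_effect$modifier >= 0))
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 recordings_per_participant =
                   as.integer(recordings_per_participant),
                 group_effect = group_effect, cluster_effect = cluster_effect,
                 base_kappa = base_kappa, noise_rms = noise_rms,
                 phase_jitter = phase_jitter, noise_exponent = noise_exponent,
                 duration = duration, audio_fs = audio_fs, eeg_fs = eeg_fs,
                 pulse_sigma = pulse_sigma, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Mode-2-Hz truncated log-normal pulse frequency.
#' @keywords internal
draw_pulse_freq <- function(sigma) {
  mu <- log(2) + sigma^2         # lognormal mode exp(mu - sigma^2) = 2
  repeat {
    f <- exp(stats::rnorm(1, mu, sigma))
    if (f >= 0.5 && f <= 4) return(f)
  }
}

# Per-channel coupling table for one participant.
#' @keywords internal
cohort_coupling <- function(spec, group) {
  clusters <- electrode_clusters()
  rows <- list()
  for (cl in names(clusters)) {
    for (lev in names(spec$base_kappa)) {
      k <- spec$base_kappa[[lev]]
      if (group == "OA") k <- k * spec$group_effect
      ce <- spec$cluster_effect
      if (!is.null(ce)) {
        hit <- ce$group == group & ce$cluster == cl & ce$level == lev
        if (any(hit)) k <- k * prod(ce$modifier[hit])
      }
      if (k > 0) {
        rows[[length(rows) + 1L]] <-
          data.frame(channel = clusters[[cl]], level = lev, kappa = k)
      }
    }
  }
  if (!length(rows)) {
    data.frame(channel = character(0), level = character(0),
               kappa = numeric(0))
  } else do.call(rbind, rows)
}

#' Generate a full on-disk synthetic cohort
#'
#' Writes, for every participant and recording, a WAV file, an EEG recording
#' (BrainVision-style triplet), and a JSON manifest holding all ground truth
#' (group labels, pulse frequencies, coupling maps, onset counts). The EEG
#' contains 2 s of noise-only padding on each side of the stimulation, with
#' `start` / `end` events marking the recording boundaries.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
gen_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  participants <- list()
  idx <- 0L
  for (group in c("YA", "OA")) {
    for (p in seq_len(spec$n_per_group)) {
      idx <- idx + 1L
      pid <- sprintf("%s%02d", group, p)
      coupling <- cohort_coupling(spec, group)
      recs <- list()
      for (r in seq_len(spec$recordings_per_participant)) {
        rec_seed <- child_seed(spec$seed, idx * 1000L + r)
        set.seed(rec_seed)
        pf <- draw_pulse_freq(spec$pulse_sigma)
        ms <- music_spec(pulse_freq = pf, duration = spec$duration,
                         fs = spec$audio_fs)
        fx <- gen_music(ms, seed = rec_seed)
        env <- amplitude_envelope(fx$audio, target_fs = spec$eeg_fs)
        es <- eeg_spec(fs = spec$eeg_fs, coupling = coupling,
                       noise_exponent = spec$noise_exponent,
                       noise_rms = spec$noise_rms,
                       phase_jitter = spec$phase_jitter,
                       seed = child_seed(rec_seed, 7))
        eeg <- gen_eeg(env, es, pulse_freq = pf)
        pad <- 2L * spec$eeg_fs
        set.seed(child_seed(rec_seed, 8))
        noise_pad <- function(nc) {
          spec$noise_rms * t(vapply(seq_len(nc), function(i)
            one_over_f_noise(pad, spec$noise_exponent, spec$eeg_fs),
            numeric(pad)))
        }
        full <- cbind(noise_pad(nrow(eeg$data)), eeg$data,
                      noise_pad(nrow(eeg$data)))
        events <- data.frame(label = c("start", "end"),
                             sample = c(pad + 1L, pad + ncol(eeg$data)))
        eeg_full <- eeg_recording(full, spec$eeg_fs, eeg$labels, events)
        stem <- file.path(out_dir, sprintf("%s_rec%02d", pid, r))
        wav <- paste0(stem, ".wav")
        ok <- tryCatch({
          write_wav(fx$audio, wav)
          write_brainvision(eeg_full, stem)
          TRUE
        }, error = function(e) {
          stop("write failure at ", stem, ": ", conditionMessage(e))
        })
        recs[[r]] <- list(id = sprintf("%s_rec%02d", pid, r),
                          wav = basename(wav),
                          vhdr = paste0(basename(stem), ".vhdr"),
                          pulse_freq = pf,
                          n_onsets = length(fx$onsets),
                          duration = spec$duration)
      }
      participants[[idx]] <- list(id = pid, group = group,
                                  coupling = coupling, recordings = recs)
    }
  }
  manifest <- list(seed = spec$seed,
                   n_per_group = spec$n_per_group,
                   recordings_per_participant =
                     spec$recordings_per_participant,
                   group_effect = spec$group_effect,
                   eeg_fs = spec$eeg_fs,
                   participants = participants)
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(mpath)
}

#' Desk-scale cohort simulation of metrical-level PLVs
#'
#' Simulates the post-detection stage of the pipeline for a whole cohort at
#' reduced sample rate and duration: for every recording, a reference
#' envelope with components at the subharmonic, pulse and harmonic
#' frequencies is generated, channel EEG is synthesized from the coupling map
#' by [gen_eeg()], wavelet PLVs are computed at the wavelets bracketing the
#' requested metrical levels, pulse-normalized, and the level values
#' extracted. This exercises the actual PLV/normalization code on cohorts
#' large enough for group-level inference while remaining tractable.
#'
#' @param spec A [cohort_spec()].
#' @param levels Dimensionless metrical levels to extract.
#' @param fs Simulation sample rate, Hz.
#' @param duration Simulated recording duration, seconds.
#' @param pulse_freq Pulse frequency used for every recording (fixed by
#'   default so the level wavelets can be shared; set `NULL` to draw per
#'   recording from the cohort distribution).
#' @param channels Channel subset (default: all 54 cluster electrodes).
#' @param env_amps Named numeric: amplitude of the reference envelope's
#'   oscillatory component at each dimensionless level (names). The default
#'   places energy at the metrical levels 1, 2, 4 only, like rhythmic music.
#'   A null design testing exchangeable levels should place equal amplitude
#'   at every tested level, since a stimulus component frequency-matched to
#'   the analysis wavelet raises the finite-sample chance floor of the PLV
#'   relative to an unmatched one.
#' @return A long data frame: `participant`, `group`, `recording`,
#'   `channel`, `cluster`, `level`, `plv`.
#' @export
simulate_cohort_levels <- function(spec, levels = c(2, 3), fs = 32,
                                   duration = 30, pulse_freq = 2,
                                   channels = NULL,
                                   env_amps = c("1" = 0.5, "2" = 1,
                                                "4" = 0.5)) {
  stopifnot(inherits(spec, "cohort_spec"))
  clusters <- electrode_clusters()
  if (is.null(channels)) channels <- unlist(clusters, use.names = FALSE)
  chan_cluster <- rep(names(clusters), lengths(clusters))
  names(chan_cluster) <- unlist(clusters, use.names = FALSE)
  bank <- build_wavelet_bank(fs = fs)
  fixed_pulse <- !is.null(pulse_freq)
  n <- round(duration * fs)
  tt <- (0:(n - 1)) / fs
  out <- vector("list", 2L * spec$n_per_group *
                  spec$recordings_per_participant)
  oi <- 0L
  idx <- 0L
  for (group in c("YA", "OA")) {
    coupling_full <- cohort_coupling(spec, group)
    for (p in seq_len(spec$n_per_group)) {
      idx <- idx + 1L
      pid <- sprintf("%s%02d", group, p)
      coupling <- coupling_full[coupling_full$channel %in% channels, ,
                                drop = FALSE]
      for (r in seq_len(spec$recordings_per_participant)) {
        rec_seed <- child_seed(spec$seed, idx * 1000L + r)
        set.seed(rec_seed)
        pf <- if (fixed_pulse) pulse_freq else draw_pulse_freq(spec$pulse_sigma)
        env <- numeric(n)
        for (j in seq_along(env_amps)) {
          fj <- as.numeric(names(env_amps)[j]) * pf / 2
          env <- env + env_amps[j] * cos(2 * pi * fj * tt + 0.7 * (j - 1))
        }
        es <- eeg_spec(channels = channels, fs = fs, coupling = coupling,
                       noise_exponent = spec$noise_exponent,
                       noise_rms = spec$noise_rms,
                       phase_jitter = spec$phase_jitter,
                       seed = child_seed(rec_seed, 7))
        eeg <- gen_eeg(env, es, pulse_freq = pf, env_fs = fs)
        subset <- level_wavelet_subset(bank, pf, levels)
        plv <- plv_music_eeg(env, eeg$data, bank, subset = subset)
        norm <- normalize_to_pulse(plv, pf)
        lv <- extract_levels(norm, levels = levels)
        oi <- oi + 1L
        out[[oi]] <- data.frame(
          participant = pid, group = group, recording = r,
          channel = rep(channels, times = length(levels)),
          cluster = rep(unname(chan_cluster[channels]),
                        times = length(levels)),
          level = rep(levels, each = length(channels)),
          plv = as.vector(lv))
      }
    }
  }
  do.call(rbind, out[seq_len(oi)])
}

# Indices of bank wavelets bracketing each requested metrical level for a
# given pulse frequency (plus exact hits), so sparse PLV evaluation still
# interpolates correctly.
#' @keywords internal
level_wavelet_subset <- function(bank, pulse_freq, levels) {
  lx <- log2(bank$freqs)
  idx <- integer(0)
  for (u in levels) {
    f <- u * pulse_freq / 2
    lf <- log2(f)
    if (lf <= lx[1]) { idx <- c(idx, 1L); next }
    if (lf >= lx[length(lx)]) { idx <- c(idx, length(lx)); next }
    lo <- findInterval(lf, lx)
    idx <- c(idx, lo, min(lo + 1L, length(lx)))
  }
  sort(unique(idx))
}
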