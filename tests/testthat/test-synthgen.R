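# Synthetic music, EEG, and cohort generation: ground-truth faithfulness,
# determinism, coupling monotonicity.

test_that("click-train arithmetic matches the spec of the stimulus", {
  fx <- fixture("fx_arith", gen_music(music_spec(pulse_freq = 2, duration = 180,
                                                 meter = 2), seed = 1))
  expect_length(fx$onsets, 360)
  expect_equal(diff(fx$onsets), rep(0.5, 359))
  acc <- fx$onsets[fx$accents]
  expect_equal(diff(acc), rep(1, length(acc) - 1))
  # 2.5 Hz pulse -> inter-onset interval 0.4 s
  fx2 <- gen_music(music_spec(pulse_freq = 2.5, duration = 150), seed = 1)
  expect_equal(diff(fx2$onsets)[1], 0.4)
  expect_error(gen_music(music_spec(pulse_freq = 0.5, duration = 0.3)),
               "one beat")
})

test_that("tempo profile becomes the rendered pulse track and onset spacing", {
  tp <- data.frame(time = c(0, 60), freq = c(2, 2.6))
  fx <- gen_music(music_spec(pulse_freq = 2, duration = 120,
                             tempo_profile = tp), seed = 2)
  expect_equal(fx$pulse_track, tp)
  d <- diff(fx$onsets)
  expect_equal(d[fx$onsets[-length(fx$onsets)] < 59], rep(0.5, sum(fx$onsets[-length(fx$onsets)] < 59)))
  late <- d[fx$onsets[-length(fx$onsets)] > 61]
  expect_true(all(abs(late - 1 / 2.6) < 1e-9))
})

test_that("rendered onsets land where the manifest says, within one sample", {
  fx <- fixture("fx_arith", gen_music(music_spec(pulse_freq = 2, duration = 180,
                                                 meter = 2), seed = 1))
  fs <- fx$audio$fs
  # each onset defines a burst whose first nonzero sample is the onset time
  x <- abs(fx$audio$samples)
  thr <- 0.05 * max(x)
  for (t in fx$onsets[fx$onsets > 0.1][seq(1, 300, by = 37)]) {
    i0 <- round(t * fs) + 1L
    # silent (noise floor only) right before the onset, burst right after
    expect_lt(max(x[(i0 - round(0.02 * fs)):(i0 - 2)]), 0.05 * max(x))
    expect_gt(max(x[i0:(i0 + round(0.005 * fs))]), thr)
  }
})

test_that("music generation is bit-identical under a fixed seed", {
  a <- gen_music(music_spec(duration = 5), seed = 10)
  b <- gen_music(music_spec(duration = 5), seed = 10)
  c <- gen_music(music_spec(duration = 5), seed = 11)
  expect_identical(a$audio$samples, b$audio$samples)
  expect_false(identical(a$audio$samples, c$audio$samples))
})

test_that("EEG generation honors the coupling map", {
  fs <- 64
  tt <- (0:(fs * 30 - 1)) / fs
  env <- cos(2 * pi * 2 * tt)
  # kappa = 0 everywhere -> pure noise, PLV near chance
  es0 <- eeg_spec(channels = c("Cz", "Pz"), fs = fs, seed = 4)
  e0 <- gen_eeg(env, es0, pulse_freq = 2, env_fs = fs)
  b <- build_wavelet_bank(fs = fs)
  k2 <- which.min(abs(b$freqs - 2))
  plv0 <- plv_music_eeg(env, e0$data, b, subset = k2)
  expect_lt(max(plv0$values), 0.45)
  # perfect locking: kappa = 1, no jitter, no noise -> PLV 1
  es1 <- eeg_spec(channels = c("Cz", "Pz"), fs = fs,
                  coupling = data.frame(channel = c("Cz", "Pz"),
                                        level = "pulse", kappa = 1),
                  noise_rms = 0, phase_jitter = 0, seed = 4)
  e1 <- gen_eeg(env, es1, pulse_freq = 2, env_fs = fs)
  plv1 <- plv_music_eeg(env, e1$data, b, subset = k2)
  expect_true(all(plv1$values > 0.999))
  # unknown channel label errors
  expect_error(eeg_spec(channels = "Cz",
                        coupling = data.frame(channel = "Zz",
                                              level = "pulse", kappa = 1)),
               "unknown channel")
  # determinism
  e1b <- gen_eeg(env, es1, pulse_freq = 2, env_fs = fs)
  expect_identical(e1$data, e1b$data)
})

test_that("downstream pulse-level PLV increases monotonically with kappa", {
  fs <- 32
  tt <- (0:(fs * 30 - 1)) / fs
  env <- cos(2 * pi * 2 * tt)
  b <- build_wavelet_bank(fs = fs)
  k2 <- which.min(abs(b$freqs - 2))
  mean_plv <- vapply(c(0, 0.25, 0.5, 1), function(kap) {
    vals <- vapply(1:6, function(s) {
      cp <- if (kap > 0)
        data.frame(channel = "Cz", level = "pulse", kappa = kap)
      else NULL
      es <- eeg_spec(channels = "Cz", fs = fs, coupling = cp,
                     noise_rms = 1, phase_jitter = 1, seed = 40 + s)
      eeg <- gen_eeg(env, es, pulse_freq = 2, env_fs = fs)
      plv_music_eeg(env, eeg$data, b, subset = k2)$values[1, 1]
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_plv) > 0))
})

test_that("cohort generation writes the promised artifacts and ground truth", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_per_group = 1, recordings_per_participant = 2,
                      duration = 12, eeg_fs = 250, seed = 6)
  mpath <- gen_cohort(spec, dir)
  expect_true(file.exists(mpath))
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  expect_length(man$participants, 2)
  files <- list.files(dir)
  expect_equal(sum(grepl("\\.wav$", files)), 4)
  expect_equal(sum(grepl("\\.vhdr$", files)), 4)
  # ground-truth pulse freqs recorded and in range
  pfs <- unlist(lapply(man$participants, function(p)
    vapply(p$recordings, `[[`, numeric(1), "pulse_freq")))
  expect_true(all(pfs >= 0.5 & pfs <= 4))
  # group_effect = 1 -> identical kappa across groups
  k1 <- sapply(man$participants[[1]]$coupling, `[[`, "kappa")
  k2 <- sapply(man$participants[[2]]$coupling, `[[`, "kappa")
  expect_equal(unlist(k1), unlist(k2))
  # round trip through the readers
  rec <- man$participants[[1]]$recordings[[1]]
  wav <- read_wav(file.path(dir, rec$wav))
  expect_equal(wav$fs, spec$audio_fs)
  eeg <- read_brainvision(file.path(dir, rec$vhdr))
  expect_equal(nrow(eeg$data), 56)
  expect_setequal(eeg$events$label, c("start", "end"))
})

test_that("cohort pulse frequencies mode near 2 Hz", {
  set.seed(13)
  pf <- replicate(400, pulselock:::draw_pulse_freq(0.35))
  expect_true(all(pf >= 0.5 & pf <= 4))
  dens <- stats::density(pf)
  expect_equal(dens$x[which.max(dens$y)], 2, tolerance = 0.2)
})

test_that("desk-scale cohort simulation recovers coupling structure", {
  spec <- cohort_spec(n_per_group = 2, recordings_per_participant = 2,
                      seed = 21)
  tab <- simulate_cohort_levels(spec, levels = c(2, 3))
  expect_equal(nrow(tab), 2 * 2 * 2 * 54 * 2)
  agg <- tapply(tab$plv, tab$level, mean)
  expect_gt(agg[["2"]], agg[["3"]] + 0.1)
  # deterministic under the same seed
  tab2 <- simulate_cohort_levels(spec, levels = c(2, 3))
  expect_identical(tab$plv, tab2$plv)
})
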