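# Deterministic EEG preprocessing chain.

make_eeg <- function(data, fs, labels = paste0("ch", seq_len(nrow(data))),
                     events = data.frame(label = character(0),
                                         sample = integer(0))) {
  eeg_recording(data, fs, labels, events)
}

test_that("epoching trims to events with a 1-s margin and shifts indices", {
  fs <- 1000
  n <- 420 * fs
  eeg <- make_eeg(matrix(0, 2, n), fs,
                  events = data.frame(label = c("start", "end"),
                                      sample = c(10 * fs + 1L, 400 * fs + 1L)))
  ep <- epoch_to_stimulation(eeg)
  expect_equal(ncol(ep$data), (400 - 10 + 2) * fs + 1)
  expect_equal(ep$events$sample[ep$events$label == "start"], fs + 1L)
  # single-recording session: epoch = [start - 1, end + 1]
  expect_equal(ep$events$sample[ep$events$label == "end"] + fs,
               ncol(ep$data))
  # margin violation errors
  tight <- make_eeg(matrix(0, 2, 100), 100,
                    events = data.frame(label = c("start", "end"),
                                        sample = c(5L, 95L)))
  expect_error(epoch_to_stimulation(tight), "margin")
  noev <- make_eeg(matrix(0, 2, 100), 100)
  expect_error(epoch_to_stimulation(noev), "expected labels")
})

test_that("resampling decimates with anti-aliasing and preserves slow content", {
  fs <- 5000
  tt <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 2 * tt)
  eeg <- make_eeg(rbind(x, x), fs)
  down <- eeg_resample(eeg, 1000)
  expect_equal(ncol(down$data), 10000)
  t2 <- (seq_len(ncol(down$data)) - 1) / 1000
  ref <- sin(2 * pi * 2 * t2)
  mid <- 500:9500
  expect_lt(max(abs(down$data[1, mid] - ref[mid])), 0.01)
  # identity when rates match; upsampling refused
  expect_identical(eeg_resample(eeg, fs), eeg)
  expect_error(eeg_resample(eeg, 10000), "up-sampling")
})

test_that("mastoid re-referencing removes the common mode exactly", {
  set.seed(7)
  fs <- 100
  n <- 500
  common <- sin(2 * pi * 3 * (0:(n - 1)) / fs)
  sig <- matrix(rnorm(2 * n), 2)
  data <- rbind(sig[1, ] + common, sig[2, ] + common, common, common)
  eeg <- make_eeg(data, fs, c("Cz", "Pz", "TP9", "TP10"))
  rr <- rereference_mastoids(eeg)
  expect_equal(rr$labels, c("Cz", "Pz"))
  expect_equal(rr$data[1, ], sig[1, ], tolerance = 1e-12)
  expect_equal(rr$data[2, ], sig[2, ], tolerance = 1e-12)
  # zero reference leaves data unchanged; identical channels null out
  eeg0 <- make_eeg(rbind(sig, 0 * common, 0 * common), fs,
                   c("Cz", "Pz", "TP9", "TP10"))
  expect_equal(rereference_mastoids(eeg0)$data, sig)
  same <- make_eeg(matrix(rep(common, 4), 4, byrow = TRUE), fs,
                   c("Cz", "Pz", "TP9", "TP10"))
  expect_lt(max(abs(rereference_mastoids(same)$data)), 1e-12)
  expect_error(rereference_mastoids(make_eeg(sig, fs, c("Cz", "Pz"))),
               "mastoid")
})

test_that("band-pass removes DC, notch kills line noise, passband is flat", {
  fs <- 1000
  n <- 20 * fs
  tt <- (0:(n - 1)) / fs
  dc <- rep(1, n)
  line <- sin(2 * pi * 60 * tt)
  slow <- sin(2 * pi * 2 * tt)
  eeg <- make_eeg(rbind(dc, line, slow), fs)
  out <- bandpass_and_notch(eeg, hp = 1, lp = 100, line = 60)
  mid <- (5 * fs):(15 * fs)
  expect_lt(stats::sd(out$data[1, mid]), 0.01)                   # DC gone
  atten <- stats::sd(out$data[2, mid]) / stats::sd(line[mid])
  expect_lt(20 * log10(atten), -40)                              # >= 40 dB
  err <- max(abs(out$data[3, mid] - slow[mid]))
  expect_lt(err, 0.05)                                           # < 5% ripple
  expect_error(bandpass_and_notch(eeg, lp = 600), "Nyquist")
})

test_that("zero-phase filtering leaves passband lag at exactly zero", {
  fs <- 500
  tt <- (0:(20 * fs - 1)) / fs
  x <- sin(2 * pi * 5 * tt)
  eeg <- make_eeg(rbind(x), fs)
  out <- bandpass_and_notch(eeg, hp = 1, lp = 55, line = 60)
  mid <- (5 * fs):(15 * fs)
  cc <- stats::ccf(out$data[1, mid], x[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("joint-probability flags only genuinely aberrant channels", {
  set.seed(8)
  n <- 4000
  data <- matrix(rnorm(20 * n), 20)
  eeg <- make_eeg(data, 250)
  expect_length(flag_bad_channels(eeg), 0)
  data2 <- data
  data2[7, ] <- data2[7, ] * 50
  eeg2 <- make_eeg(data2, 250)
  expect_equal(flag_bad_channels(eeg2), "ch7")
  expect_length(flag_bad_channels(eeg2, z = Inf), 0)
  expect_error(flag_bad_channels(make_eeg(data[1:4, ], 250)), "8 channels")
})

test_that("the full chain preserves perfect phase locking", {
  fs <- 250
  tt <- (0:(40 * fs - 1)) / fs
  env <- 1 + 0.8 * cos(2 * pi * 2 * tt)
  labels <- c("Cz", "Pz", "O1", "O2", "F3", "F4", "C3", "C4", "TP9", "TP10")
  es <- eeg_spec(channels = labels, fs = fs,
                 coupling = data.frame(channel = labels[1:8],
                                       level = "pulse", kappa = 1),
                 noise_rms = 0, phase_jitter = 0, seed = 12)
  eeg <- gen_eeg(env, es, pulse_freq = 2, env_fs = fs)
  pre <- preprocess_eeg(eeg, analysis_fs = fs, lp = 55, line = 60)
  expect_equal(nrow(pre$data), 8)        # mastoids dropped
  b <- build_wavelet_bank(fs = fs)
  k2 <- which.min(abs(b$freqs - 2))
  plv <- plv_music_eeg(env, pre$data, b, subset = k2)
  expect_true(all(plv$values >= 0.99))
  # chain determinism
  pre2 <- preprocess_eeg(eeg, analysis_fs = fs, lp = 55, line = 60)
  expect_identical(pre$data, pre2$data)
})
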