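# Wavelet bank, phase extraction, PLV, pulse normalization, level extraction.

test_that("wavelet bank follows the log-spacing and cycle rules", {
  b <- build_wavelet_bank(fs = 1000)
  expect_length(b$freqs, 65)
  expect_equal(b$freqs[1], 0.25)
  expect_true(all(diff(log2(b$freqs)) - 1 / 15 < 1e-12))
  expect_true(max(b$freqs) <= 5)
  expect_equal(range(b$cycles), c(3, 8))
  expect_true(all(diff(b$cycles) >= 0))
  # doubling rule at 2 Hz: round(4) = 4
  expect_equal(b$cycles[which.min(abs(b$freqs - 2))], 4)
  expect_error(build_wavelet_bank(fs = 8), "fs")
})

test_that("wavelet phase of a pure tone advances at the tone frequency", {
  fs <- 250
  x <- cos(2 * pi * 2 * (0:(fs * 20)) / fs)
  b <- build_wavelet_bank(fs = fs)
  k <- which.min(abs(b$freqs - 2))
  ph <- wavelet_phase(x, b, subset = k)
  d <- diff(ph$phases[1, ph$valid[1, ]])
  d <- (d + pi) %% (2 * pi) - pi
  expect_equal(mean(d), 2 * pi * 2 / fs, tolerance = 1e-4)
})

test_that("a delayed copy shows the analytic phase shift at every wavelet", {
  fs <- 200
  lag_s <- 0.1
  set.seed(8)
  x <- stats::rnorm(fs * 30)   # broadband, so each wavelet rotates at f_k
  lag <- round(lag_s * fs)
  y <- c(rep(0, lag), x)[seq_along(x)]
  b <- build_wavelet_bank(fs = fs)
  sub <- c(25, 36, 55)
  px <- wavelet_phase(x, b, subset = sub)
  py <- wavelet_phase(y, b, subset = sub)
  for (j in seq_along(sub)) {
    ok <- px$valid[j, ] & py$valid[j, ]
    ok[1:(4 * lag)] <- FALSE                      # skip the zero-padded lead
    d <- (px$phases[j, ok] - py$phases[j, ok] + pi) %% (2 * pi) - pi
    expected <- (2 * pi * b$freqs[sub[j]] * lag_s + pi) %% (2 * pi) - pi
    expect_equal(stats::median(d), expected, tolerance = 0.05)
  }
})

test_that("degenerate constant input is flagged invalid, not returned", {
  b <- build_wavelet_bank(fs = 100)
  ph <- wavelet_phase(rep(1, 5000), b, subset = c(40, 64))
  expect_false(any(ph$valid))
  expect_error(wavelet_phase(rep(0, 10), b), "shorter")
})

test_that("PLV obeys the defining identities", {
  ph <- rand_phase_series(5, 400, seed = 2)
  # identical series -> 1
  expect_equal(unname(compute_plv(ph, ph)$values[1, ]), rep(1, 5))
  # constant offset -> 1
  ph2 <- ph
  ph2$phases <- ph$phases + 1.234
  expect_equal(max(abs(compute_plv(ph, ph2)$values - 1)), 0, tolerance = 1e-12)
  # balanced three-point symmetric relative phase -> 0
  base <- rand_phase_series(2, 300, seed = 3)
  off <- base
  off$phases <- base$phases +
    matrix(rep(c(0, 2 * pi / 3, 4 * pi / 3), length.out = 300),
           nrow = 2, ncol = 300, byrow = TRUE)
  expect_lt(max(compute_plv(base, off)$values), 1e-12)
  # misaligned lengths error
  short <- rand_phase_series(5, 399, seed = 4)
  expect_error(compute_plv(ph, short), "misaligned")
})

test_that("vectorized PLV matches the naive direct sum", {
  for (s in 1:10) {
    nw <- sample(2:8, 1)
    nt <- sample(50:300, 1)
    env <- rand_phase_series(nw, nt, seed = 100 + s)
    chans <- lapply(1:3, function(j) rand_phase_series(nw, nt, seed = 200 + 10 * s + j))
    got <- compute_plv(env, chans)$values
    want <- naive_plv(env, chans)
    expect_lt(max(abs(got - want)), 1e-12)
  }
})

test_that("composite envelope-EEG PLV equals the two-step route", {
  fs <- 64
  set.seed(5)
  tt <- (0:(fs * 40)) / fs
  env <- cos(2 * pi * 2 * tt) + 0.2 * rnorm(length(tt))
  eeg <- rbind(cos(2 * pi * 2 * tt + 0.3) + 0.5 * rnorm(length(tt)),
               rnorm(length(tt)))
  b <- build_wavelet_bank(fs = fs)
  sub <- c(31, 46, 61)
  fast <- plv_music_eeg(env, eeg, b, subset = sub)
  pe <- wavelet_phase(env, b, subset = sub)
  p1 <- wavelet_phase(eeg[1, ], b, subset = sub)
  p2 <- wavelet_phase(eeg[2, ], b, subset = sub)
  slow <- compute_plv(pe, list(p1, p2))
  expect_equal(fast$values, slow$values, tolerance = 1e-10)
  expect_equal(fast$n, slow$n)
})

test_that("pulse normalization maps the detected pulse to dimensionless 2", {
  # synthetic PLV spectrum peaked at 2.5 Hz
  b <- build_wavelet_bank(fs = 100)
  vals <- exp(-(log2(b$freqs / 2.5))^2 / 0.02)
  plv <- structure(list(values = rbind(vals), n = rbind(rep(100, 65)),
                        freqs = b$freqs), class = "plv_matrix")
  norm <- normalize_to_pulse(plv, 2.5)
  expect_equal(norm$axis[which.max(norm$values[1, ])], 2, tolerance = 1e-9)
  # pulse 2 -> identity on shared grid points
  norm2 <- normalize_to_pulse(plv, 2)
  shared <- intersect(round(log2(norm2$axis) * 15), round(log2(b$freqs) * 15))
  for (g in shared) {
    i <- which(round(log2(norm2$axis) * 15) == g)
    k <- which(round(log2(b$freqs) * 15) == g)
    expect_equal(norm2$values[1, i], vals[k], tolerance = 1e-9)
  }
  # out-of-range points are missing, not extrapolated
  expect_true(anyNA(norm$values))
  expect_error(normalize_to_pulse(plv, -1), "positive")
})

test_that("normalization round-trips through the inverse pulse mapping", {
  b <- build_wavelet_bank(fs = 100)
  # smooth at the wavelet-bandwidth scale, like a real PLV spectrum
  lx <- log2(b$freqs)
  vals <- 0.3 + 0.15 * sin(2 * pi * lx / 2.5) +
    0.25 * exp(-(lx - 1)^2 / 0.18)
  plv <- structure(list(values = rbind(vals),
                        n = rbind(rep(100, 65)), freqs = b$freqs),
                   class = "plv_matrix")
  f <- 2.5
  n1 <- normalize_to_pulse(plv, f)
  plv2 <- structure(list(values = n1$values, n = n1$values * 0 + 100,
                         freqs = n1$axis), class = "plv_matrix")
  n2 <- normalize_to_pulse(plv2, 4 / f)   # u = 2 x / (4/f) = x f / 2
  # n2's axis values now live on the original frequency axis
  for (k in seq_along(b$freqs)) {
    i <- which(abs(log2(n2$axis) - log2(b$freqs[k])) < 1e-9)
    if (length(i) == 1 && is.finite(n2$values[1, i])) {
      expect_equal(unname(n2$values[1, i]), unname(plv$values[1, k]),
                   tolerance = 0.01)
    }
  }
})

test_that("level extraction interpolates the six metrical levels", {
  axis <- 0.5 * 2^((0:60) / 15)
  flat <- structure(list(values = rbind(rep(0.4, 61)), axis = axis,
                         pulse_freq = 2), class = "normalized_plv")
  lv <- extract_levels(flat)
  expect_equal(unname(lv[1, ]), rep(0.4, 6))
  # level outside measured range -> NA, others intact
  vals <- rep(0.4, 61)
  vals[axis > 4.5] <- NA
  part <- structure(list(values = rbind(vals), axis = axis, pulse_freq = 2),
                    class = "normalized_plv")
  lv2 <- extract_levels(part)
  expect_true(is.na(lv2[1, "5"]))
  expect_equal(unname(lv2[1, "2"]), 0.4)
})

test_that("PLV chance level shrinks as 1/sqrt(n)", {
  set.seed(11)
  for (n in c(500, 5000)) {
    reps <- replicate(200, Mod(mean(exp(1i * runif(n, -pi, pi)))))
    expect_equal(mean(reps), sqrt(pi) / (2 * sqrt(n)), tolerance = 0.1)
  }
})
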