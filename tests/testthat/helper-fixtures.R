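# Shared fixtures, built once per test run and cached (several tests reuse
# the same oscillator-bank run, which is the expensive part).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, expr, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# 60-s 2 Hz click-train fixture and its oscillator-bank run
fix_2hz <- function() fixture("fx2", {
  gen_music(music_spec(pulse_freq = 2, duration = 60), seed = 3)
})

fix_2hz_run <- function() fixture("run2", {
  run_bank(complex_onset_detect(middle_ear_filter(fix_2hz()$audio)))
})

# random phase_series pair for PLV contract tests
rand_phase_series <- function(nw, nt, seed, freqs = seq_len(nw)) {
  set.seed(seed)
  structure(list(
    phases = matrix(stats::runif(nw * nt, -pi, pi), nw, nt),
    valid = matrix(TRUE, nw, nt),
    freqs = freqs, fs = 1),
    class = "phase_series")
}

# brute-force Eq-style PLV: explicit loop over channels, wavelets, samples
naive_plv <- function(env_phase, eeg_phase_list) {
  nw <- nrow(env_phase$phases)
  out <- matrix(NA_real_, length(eeg_phase_list), nw)
  for (j in seq_along(eeg_phase_list)) {
    for (k in seq_len(nw)) {
      ok <- env_phase$valid[k, ] & eeg_phase_list[[j]]$valid[k, ]
      acc <- 0 + 0i
      n <- 0L
      for (t in which(ok)) {
        acc <- acc + exp(1i * (env_phase$phases[k, t] -
                                 eeg_phase_list[[j]]$phases[k, t]))
        n <- n + 1L
      }
      if (n > 0) out[j, k] <- Mod(acc / n)
    }
  }
  out
}
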