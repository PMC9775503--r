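# Orchestration: run configuration, per-recording fan-out, cohort-level
# fan-in, and structured reporting.

#' Default run configuration
#'
#' All tunable parameter blocks of the pipeline in one validated list.
#' Unknown keys in `overrides` are rejected so configuration typos fail
#' loudly.
#'
#' @param overrides Named list of blocks/values to override, nested as in
#'   the default (e.g. `list(stability = list(tol = 0.05))`).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(overrides = list()) {
  cfg <- list(
    stft = default_stft_params(),
    envelope = list(method = "hilbert", target_fs = 1000, lp = 50),
    oscillator = list(alpha = 0, beta1 = -1, beta2 = -0.25, epsilon = 1,
                      c_gain = 1, fs_int = 250, smooth_sec = 0.25),
    stability = list(tol = 0.04, min_len = 120, win = 10, hop = 1),
    wavelet = list(fmin = 0.25, fmax = 5, bins_per_octave = 15),
    levels = c(1, 1.5, 2, 3, 4, 5),
    eeg = list(analysis_fs = 1000, hp = 1, lp = 55, line = 60, bad_z = 5),
    bootstrap = list(n_boot = 10000, level = 0.95),
    alpha = 0.05,
    seed = 1L
  )
  merge_cfg <- function(base, over, path = "") {
    for (nm in names(over)) {
      if (!nm %in% names(base)) {
        stop("unknown configuration key: ", paste0(path, nm))
      }
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_cfg(base[[nm]], over[[nm]],
                                paste0(path, nm, "."))
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  structure(merge_cfg(cfg, overrides), class = "run_config")
}

#' @keywords internal
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # small stable polynomial checksum over the serialized configuration
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 1e9
  sprintf("%09d", h)
}

#' Run the full analysis chain on one paired recording
#'
#' Audio: middle-ear filter, complex-domain onset detection, oscillator
#' network, stable-epoch search. EEG: preprocessing chain. Then the
#' amplitude envelope and the preprocessed EEG are cropped to the stable
#' epoch, wavelet PLVs computed, pulse-normalized, and the metrical-level
#' values extracted. A recording with no stable epoch (or any stage error)
#' yields an exclusion record instead of aborting the run.
#'
#' @param audio An [audio_recording()].
#' @param eeg An [eeg_recording()] whose `start` event marks the onset of
#'   this recording's audio in EEG time (sample 1 when absent).
#' @param config A [run_config()].
#' @param id Recording identifier.
#' @return A list: `id`, `survived`, and either `reason` (exclusion) or
#'   `pulse`, `epoch`, `levels` (long data frame `channel`, `level`, `plv`).
#' @export
run_recording <- function(audio, eeg, config = run_config(), id = audio$id) {
  res <- tryCatch({
    me <- middle_ear_filter(audio)
    onset <- complex_onset_detect(me, config$stft)
    params <- do.call(oscillator_bank_params, config$oscillator)
    bank_run <- run_bank(onset, params)
    epoch <- find_stable_epoch(bank_run,
                               min_len = config$stability$min_len,
                               tol = config$stability$tol,
                               win = config$stability$win,
                               hop = config$stability$hop)
    if (is.null(epoch)) {
      return(list(id = id, survived = FALSE,
                  reason = sprintf("no stable epoch of >= %g s",
                                   config$stability$min_len)))
    }
    fs_an <- config$eeg$analysis_fs
    env <- amplitude_envelope(audio, target_fs = fs_an,
                              lp = config$envelope$lp)
    eegp <- preprocess_eeg(eeg, analysis_fs = fs_an, hp = config$eeg$hp,
                           lp = config$eeg$lp, line = config$eeg$line,
                           z = config$eeg$bad_z)
    start_ev <- eegp$events$sample[eegp$events$label == "start"]
    offset <- if (length(start_ev)) start_ev[1] - 1L else 0L
    i0 <- floor(epoch$start * fs_an) + 1L
    i1 <- min(ceiling(epoch$end * fs_an), length(env$values))
    e0 <- offset + i0
    e1 <- min(offset + i1, ncol(eegp$data))
    len <- min(i1 - i0, e1 - e0)
    env_ep <- env$values[i0:(i0 + len)]
    eeg_ep <- eegp$data[, e0:(e0 + len), drop = FALSE]
    bank <- build_wavelet_bank(fmin = config$wavelet$fmin,
                               fmax = config$wavelet$fmax,
                               bins_per_octave = config$wavelet$bins_per_octave,
                               fs = fs_an)
    plv <- plv_music_eeg(env_ep, eeg_ep, bank)
    norm <- normalize_to_pulse(plv, epoch$estimate$pulse)
    lv <- extract_levels(norm, levels = config$levels)
    levels_tab <- data.frame(
      channel = rep(eegp$labels, times = ncol(lv)),
      level = rep(as.numeric(colnames(lv)), each = nrow(lv)),
      plv = as.vector(lv))
    list(id = id, survived = TRUE,
         pulse = epoch$estimate$pulse,
         subharmonic = epoch$estimate$subharmonic,
         harmonic = epoch$estimate$harmonic,
         epoch = c(epoch$start, epoch$end),
         levels = levels_tab)
  }, error = function(e) {
    list(id = id, survived = FALSE, reason = conditionMessage(e))
  })
  res
}

#' Run a whole cohort from a manifest
#'
#' Fans out [run_recording()] over every manifest entry (results are
#' independent of processing order), then fans in to the group-level
#' statistics: participant grand averages, bootstrap confidence intervals
#' per group, a Kolmogorov-Smirnov comparison of detected pulse-frequency
#' distributions, and the mixed-model level/group (and cluster) contrasts.
#'
#' @param manifest_path Path to a manifest JSON written by [gen_cohort()].
#' @param config A [run_config()].
#' @param out_dir Output directory for tables and the run report.
#' @return A list of class `run_report`: survival records, per-group counts,
#'   statistics, and output paths.
#' @export
run_cohort <- function(manifest_path, config = run_config(),
                       out_dir = NULL) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  base_dir <- dirname(manifest_path)
  records <- list()
  level_rows <- list()
  pulse_rows <- list()
  for (p in man$participants) {
    for (rec in p$recordings) {
      id <- rec$id
      r <- tryCatch({
        audio <- read_wav(file.path(base_dir, rec$wav), id = id)
        eeg <- read_brainvision(file.path(base_dir, rec$vhdr))
        run_recording(audio, eeg, config, id = id)
      }, error = function(e) {
        list(id = id, survived = FALSE, reason = conditionMessage(e))
      })
      r$participant <- p$id
      r$group <- p$group
      records[[id]] <- r
      if (isTRUE(r$survived)) {
        lv <- r$levels
        lv$participant <- p$id
        lv$group <- p$group
        lv$recording <- id
        level_rows[[id]] <- lv
        pulse_rows[[id]] <- data.frame(group = p$group, pulse = r$pulse)
      }
    }
  }
  survived <- vapply(records, function(r) isTRUE(r$survived), logical(1))
  groups <- vapply(records, function(r) r$group, character(1))
  counts <- table(group = groups, survived = survived)
  stats_out <- NULL
  if (length(level_rows)) {
    tab <- do.call(rbind, level_rows)
    clusters <- electrode_clusters()
    chan_cluster <- rep(names(clusters), lengths(clusters))
    names(chan_cluster) <- unlist(clusters, use.names = FALSE)
    tab$cluster <- unname(chan_cluster[tab$channel])
    pulses <- do.call(rbind, pulse_rows)
    ga_rows <- list()
    for (pid in unique(tab$participant)) {
      sub <- tab[tab$participant == pid, ]
      ga <- grand_average(sub)$grand_average
      ga_rows[[pid]] <- data.frame(participant = pid,
                                   group = sub$group[1],
                                   level = as.numeric(names(ga)),
                                   plv = as.numeric(ga))
    }
    ga_tab <- do.call(rbind, ga_rows)
    both_groups <- length(unique(ga_tab$group)) == 2
    cis <- lapply(split(ga_tab$plv[ga_tab$level == 2],
                        ga_tab$group[ga_tab$level == 2]),
                  function(v) if (length(v) >= 2)
                    bootstrap_ci(v, n_boot = config$bootstrap$n_boot,
                                 level = config$bootstrap$level,
                                 seed = config$seed) else NULL)
    ks <- if (both_groups)
      ks_two_sample(pulses$pulse[pulses$group == "YA"],
                    pulses$pulse[pulses$group == "OA"]) else NULL
    po <- ga_tab[ga_tab$level %in% c(2, 3), ]
    po$level <- factor(ifelse(po$level == 2, "pulse", "off-pulse"),
                       levels = c("pulse", "off-pulse"))
    lmm_global <- if (both_groups) {
      tryCatch(fit_level_group_model(po), error = function(e) NULL)
    } else NULL
    cl_tab <- tab[tab$level %in% c(2, 3) & !is.na(tab$cluster) &
                    is.finite(tab$plv), ]
    lmm_cluster <- NULL
    if (both_groups && nrow(cl_tab)) {
      agg <- stats::aggregate(plv ~ participant + group + cluster + level,
                              data = cl_tab, FUN = mean)
      agg$level <- factor(ifelse(agg$level == 2, "pulse", "off-pulse"),
                          levels = c("pulse", "off-pulse"))
      lmm_cluster <- tryCatch(fit_level_group_model(agg),
                              error = function(e) NULL)
    }
    stats_out <- list(grand_averages = ga_tab, pulse_freqs = pulses,
                      bootstrap_ci_pulse = cis, ks_pulse = ks,
                      lmm_global = lmm_global, lmm_cluster = lmm_cluster)
  }
  report <- structure(list(
    records = records,
    counts = counts,
    stats = stats_out,
    config_hash = config_hash(config),
    version = as.character(utils::packageVersion("pulselock"))),
    class = "run_report")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (!is.null(stats_out)) {
      hdr <- sprintf("# pulselock %s config %s", report$version,
                     report$config_hash)
      write_with_header <- function(df, path) {
        con <- file(path, "w"); writeLines(hdr, con); close(con)
        suppressWarnings(utils::write.table(df, path, sep = "\t",
                                            row.names = FALSE, quote = FALSE,
                                            append = TRUE))
      }
      write_with_header(stats_out$grand_averages,
                        file.path(out_dir, "grand_averages.tsv"))
      if (!is.null(stats_out$lmm_global)) {
        write_with_header(stats_out$lmm_global$anova,
                          file.path(out_dir, "anova_global.tsv"))
      }
      if (!is.null(stats_out$lmm_cluster)) {
        write_with_header(stats_out$lmm_cluster$anova,
                          file.path(out_dir, "anova_cluster.tsv"))
        write_with_header(stats_out$lmm_cluster$cell_means,
                          file.path(out_dir, "cluster_cell_means.tsv"))
      }
    }
    excl <- lapply(records, function(r)
      list(id = r$id, participant = r$participant, group = r$group,
           survived = isTRUE(r$survived),
           reason = if (isTRUE(r$survived)) NULL else r$reason,
           pulse = if (isTRUE(r$survived)) r$pulse else NULL))
    jsonlite::write_json(
      list(version = report$version, config_hash = report$config_hash,
           records = excl),
      file.path(out_dir, "run_report.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$counts)
  invisible(x)
}
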