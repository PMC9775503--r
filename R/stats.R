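# Group-level aggregation and inference: electrode clusters, grand averages,
# bootstrap confidence intervals, pulse-frequency distribution comparison,
# mixed-model level/group/cluster contrasts with Holm correction.

#' The nine auditory-research electrode clusters
#'
#' Nine named clusters of six 10-20 channels each (54 assignments, no channel
#' in two clusters), as used in auditory EEG research: left/right frontal,
#' left/midline/right central, left/midline/right parietal, occipital.
#'
#' @return Named list of nine character vectors of length six.
#' @export
electrode_clusters <- function() {
  cl <- list(
    LF = c("AF7", "AF3", "F7", "F5", "F3", "F1"),
    RF = c("AF4", "AF8", "F2", "F4", "F6", "F8"),
    LC = c("FT7", "FC5", "FC3", "T7", "C5", "C3"),
    MC = c("FC1", "FCz", "FC2", "C1", "Cz", "C2"),
    RC = c("FC4", "FC6", "FC8", "C4", "C6", "T8"),
    LP = c("TP7", "CP5", "CP3", "P7", "P5", "P3"),
    MP = c("CP1", "CPZ", "CP2", "P1", "Pz", "P2"),
    RP = c("CP4", "CP6", "CP8", "P4", "P6", "P8"),
    O  = c("PO3", "POZ", "PO4", "O1", "OZ", "O2")
  )
  stopifnot(length(cl) == 9, all(lengths(cl) == 6),
            !anyDuplicated(unlist(cl)))
  cl
}

#' Grand-average level PLVs for one participant
#'
#' Unweighted mean over all recording-by-channel cells per metrical level
#' (order-invariant; with a complete cross, averaging over recordings then
#' channels gives the same result). Missing cells are dropped from the mean
#' and counted.
#'
#' @param level_tab Long data frame with columns `recording`, `channel`,
#'   `level`, `plv` for one participant.
#' @return A list of class `participant_plv`: `grand_average` (named numeric
#'   per level), `n_cells` (cells used per level), `n_recordings`.
#' @export
grand_average <- function(level_tab) {
  stopifnot(all(c("recording", "channel", "level", "plv") %in%
                  names(level_tab)))
  if (!nrow(level_tab) || !length(unique(level_tab$recording))) {
    stop("participant has zero surviving recordings")
  }
  ok <- is.finite(level_tab$plv)
  ga <- tapply(level_tab$plv[ok], level_tab$level[ok], mean)
  n <- tapply(level_tab$plv[ok], level_tab$level[ok], length)
  structure(list(grand_average = ga, n_cells = n,
                 n_recordings = length(unique(level_tab$recording))),
            class = "participant_plv")
}

#' Per-cluster mean level PLVs
#'
#' Unweighted mean over each cluster's six channels (and any recordings
#' present in the table), per metrical level.
#'
#' @param level_tab Long data frame with `channel`, `level`, `plv`.
#' @param clusters Cluster definition, default [electrode_clusters()].
#' @return Data frame `cluster`, `level`, `plv`, `n`.
#' @export
cluster_means <- function(level_tab, clusters = electrode_clusters()) {
  stopifnot(all(c("channel", "level", "plv") %in% names(level_tab)))
  rows <- list()
  for (cl in names(clusters)) {
    sub <- level_tab[level_tab$channel %in% clusters[[cl]] &
                       is.finite(level_tab$plv), , drop = FALSE]
    if (!nrow(sub)) next
    m <- tapply(sub$plv, sub$level, mean)
    n <- tapply(sub$plv, sub$level, length)
    rows[[cl]] <- data.frame(cluster = cl, level = names(m),
                             plv = as.numeric(m), n = as.integer(n))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normal-approximation bootstrap confidence interval
#'
#' Resamples the values (participant grand averages are the intended unit)
#' with replacement `n_boot` times and forms the bias-adjusted normal
#' interval `(2 m - mean(boot)) +/- z * sd(boot)` around the sample mean `m`
#' (the interval `boot.ci(type = "norm")` reports).
#'
#' @param values Numeric vector (length >= 2).
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the resampling.
#' @return Named numeric `c(lo, hi)` with attribute `estimate`.
#' @export
bootstrap_ci <- function(values, n_boot = 10000, level = 0.95, seed = 1L) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 values")
  set.seed(seed)
  m <- mean(values)
  idx <- matrix(sample.int(length(values), length(values) * n_boot,
                           replace = TRUE), nrow = n_boot)
  boots <- rowMeans(matrix(values[idx], nrow = n_boot))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ctr <- 2 * m - mean(boots)
  out <- c(lo = ctr - zq * stats::sd(boots), hi = ctr + zq * stats::sd(boots))
  attr(out, "estimate") <- m
  out
}

#' Two-sample Kolmogorov-Smirnov test of pulse-frequency distributions
#'
#' `D` is the supremum distance between the two empirical CDFs; the p-value
#' is the asymptotic one.
#'
#' @param freqs_a,freqs_b Non-empty numeric samples (Hz).
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(freqs_a, freqs_b) {
  stopifnot(length(freqs_a) > 0, length(freqs_b) > 0)
  kt <- suppressWarnings(stats::ks.test(freqs_a, freqs_b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Holm step-down correction
#'
#' Family-wise error control: sort ascending, multiply the i-th smallest by
#' (m - i + 1), enforce monotonicity, cap at 1, restore the original order.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
holm_correct <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "holm")
}

#' Mixed-model contrasts of PLV by level, group, and optionally cluster
#'
#' Fits `plv ~ level * group + (1 | participant)` — or, when a `cluster`
#' column is present, `plv ~ cluster * group * level` with uncorrelated
#' random intercepts and slopes `(1 | participant) +
#' (1 | participant:cluster) + (1 | participant:level)` — and returns
#' type-III F tests with Satterthwaite degrees of freedom, raw and
#' Holm-adjusted p-values, and cell means with standard errors. When the
#' mixed fit fails (or does not converge), a documented paired-contrast
#' approximation is used instead: per-participant level differences tested
#' against zero, group differences by Welch test on participant means, and
#' the level-by-group interaction by Welch test on the per-participant level
#' differences.
#'
#' @param tab Long data frame with columns `participant`, `group`, `level`,
#'   `plv`, and optionally `cluster`.
#' @return An object of class `contrast_result`: `anova` (data frame with
#'   `effect`, `df1`, `df2`, `F`, `p`, `p_holm`), `cell_means`, `method`
#'   (`"lmm"` or `"paired"`), and the fitted model (when mixed).
#' @export
fit_level_group_model <- function(tab) {
  need <- c("participant", "group", "level", "plv")
  stopifnot(all(need %in% names(tab)))
  tab <- tab[is.finite(tab$plv), , drop = FALSE]
  has_cluster <- "cluster" %in% names(tab) &&
    length(unique(tab$cluster)) > 1
  d <- data.frame(
    plv = tab$plv,
    participant = factor(tab$participant),
    group = factor(tab$group),
    level = factor(tab$level)
  )
  if (has_cluster) d$cluster <- factor(tab$cluster)
  opts <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(opts))
  fml <- if (has_cluster) {
    plv ~ cluster * group * level + (1 | participant) +
      (1 | participant:cluster) + (1 | participant:level)
  } else {
    plv ~ level * group + (1 | participant)
  }
  fit <- tryCatch(
    lmerTest::lmer(fml, data = d,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular =
                                                 lme4::.makeCC("ignore",
                                                               tol = 1e-4))),
    error = function(e) e)
  if (!inherits(fit, "error")) {
    an <- tryCatch(
      as.data.frame(stats::anova(fit, type = 3, ddf = "Satterthwaite")),
      error = function(e) e)
  }
  if (inherits(fit, "error") || inherits(an, "error")) {
    res <- fallback_paired_contrasts(d)
    res$note <- conditionMessage(if (inherits(fit, "error")) fit else an)
    return(res)
  }
  anova_tab <- data.frame(
    effect = rownames(an),
    df1 = an$NumDF, df2 = an$DenDF,
    F = an$`F value`, p = an$`Pr(>F)`,
    stringsAsFactors = FALSE)
  anova_tab$p_holm <- holm_correct(anova_tab$p)
  fixed <- intersect(c("cluster", "group", "level"), names(d))
  cm <- stats::aggregate(d$plv, by = d[fixed], FUN = function(v)
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v))))
  cell_means <- cbind(cm[fixed], as.data.frame(cm$x))
  structure(list(anova = anova_tab, cell_means = cell_means,
                 method = "lmm", model = fit),
            class = "contrast_result")
}

# Paired-contrast approximation used when the mixed model cannot be fit:
# collapse to participant-by-level means, test the level effect on paired
# differences, the group effect on participant means, and their interaction
# on the paired differences across groups.
#' @keywords internal
fallback_paired_contrasts <- function(d) {
  pm <- stats::aggregate(plv ~ participant + group + level, data = d,
                         FUN = mean)
  levs <- levels(pm$level)
  if (length(levs) != 2) stop("paired-contrast fallback requires 2 levels; ",
                              "mixed model failed and no fallback applies")
  wide <- merge(pm[pm$level == levs[1], c("participant", "group", "plv")],
                pm[pm$level == levs[2], c("participant", "plv")],
                by = "participant", suffixes = c("_1", "_2"))
  diffs <- wide$plv_1 - wide$plv_2
  t_lev <- stats::t.test(diffs)
  means <- (wide$plv_1 + wide$plv_2) / 2
  t_grp <- stats::t.test(means ~ wide$group)
  t_int <- stats::t.test(diffs ~ wide$group)
  anova_tab <- data.frame(
    effect = c("level", "group", "level:group"),
    df1 = 1,
    df2 = c(t_lev$parameter, t_grp$parameter, t_int$parameter),
    F = c(t_lev$statistic, t_grp$statistic, t_int$statistic)^2,
    p = c(t_lev$p.value, t_grp$p.value, t_int$p.value),
    stringsAsFactors = FALSE)
  anova_tab$p_holm <- holm_correct(anova_tab$p)
  cm <- stats::aggregate(plv ~ group + level, data = pm, FUN = function(v)
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v))))
  cell_means <- cbind(cm[c("group", "level")], as.data.frame(cm$plv))
  structure(list(anova = anova_tab, cell_means = cell_means,
                 method = "paired", model = NULL),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("Mixed-model ANOVA (", x$method, ")\n", sep = "")
  print(x$anova, row.names = FALSE)
  invisible(x)
}
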