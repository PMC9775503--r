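# Aggregation and inference: clusters, grand averages, bootstrap, KS, Holm,
# mixed-model contrasts.

test_that("electrode clusters are the canonical nine-by-six assignment", {
  cl <- electrode_clusters()
  expect_length(cl, 9)
  expect_true(all(lengths(cl) == 6))
  expect_equal(anyDuplicated(unlist(cl)), 0L)
  expect_equal(cl$O, c("PO3", "POZ", "PO4", "O1", "OZ", "O2"))
  expect_equal(cl$MC, c("FC1", "FCz", "FC2", "C1", "Cz", "C2"))
  expect_setequal(names(cl), c("LF", "RF", "LC", "MC", "RC",
                               "LP", "MP", "RP", "O"))
})

test_that("grand average is the unweighted cell mean and order-invariant", {
  tab <- expand.grid(recording = 1:2, channel = c("Cz", "Pz"),
                     level = c(2, 3), stringsAsFactors = FALSE)
  tab$plv <- ifelse(tab$level == 2, ifelse(tab$recording == 1, 0.2, 0.4), 0.1)
  ga <- grand_average(tab)
  expect_equal(unname(ga$grand_average[["2"]]), 0.3)
  expect_equal(unname(ga$grand_average[["3"]]), 0.1)
  shuf <- tab[sample(nrow(tab)), ]
  expect_equal(grand_average(shuf)$grand_average, ga$grand_average)
  # constant table -> the constant
  tab$plv <- 0.42
  expect_equal(unname(grand_average(tab)$grand_average[["2"]]), 0.42)
  # missing cells are dropped and counted
  tab$plv[1] <- NA
  ga2 <- grand_average(tab)
  expect_equal(unname(ga2$n_cells[["2"]]), 3)
  expect_error(grand_average(tab[0, ]), "zero surviving")
})

test_that("cluster means reproduce a brute-force recomputation", {
  set.seed(3)
  cl <- electrode_clusters()
  tab <- data.frame(channel = unlist(cl), level = 2,
                    plv = runif(54), stringsAsFactors = FALSE)
  cm <- cluster_means(tab)
  for (nm in names(cl)) {
    expect_equal(cm$plv[cm$cluster == nm],
                 mean(tab$plv[tab$channel %in% cl[[nm]]]))
  }
  # indicator case: O channels 1, others 0
  tab$plv <- as.numeric(tab$channel %in% cl$O)
  cm2 <- cluster_means(tab)
  expect_equal(cm2$plv[cm2$cluster == "O"], 1)
  expect_true(all(cm2$plv[cm2$cluster != "O"] == 0))
})

test_that("bootstrap CI behaves like a normal-approximation interval", {
  expect_error(bootstrap_ci(1), "at least 2")
  ci0 <- bootstrap_ci(rep(0.3, 10), n_boot = 200, seed = 1)
  expect_equal(as.numeric(ci0), c(0.3, 0.3))
  set.seed(4)
  x <- rnorm(40, 1, 1)
  ci1 <- bootstrap_ci(x, n_boot = 2000, seed = 2)
  ci2 <- bootstrap_ci(1 + (x - 1) * 3, n_boot = 2000, seed = 2)
  expect_gt(diff(ci2), 2.5 * diff(ci1))   # widens with the sample s.d.
  # coverage of the true mean approximately nominal
  hits <- vapply(1:300, function(s) {
    set.seed(1000 + s)
    y <- rnorm(50)
    ci <- bootstrap_ci(y, n_boot = 400, seed = s)
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gt(mean(hits), 0.9)
  expect_lt(mean(hits), 0.99)
})

test_that("KS statistic equals the brute-force ECDF supremum", {
  brute_D <- function(a, b) {
    g <- sort(unique(c(a, b)))
    max(abs(vapply(g, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
  }
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(1:3, 11:13)$D, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3, 4))$D,
               brute_D(c(1, 2, 3), c(1, 2, 3, 4)))
  set.seed(5)
  for (i in 1:20) {
    a <- sample(1:40, sample(3:20, 1), replace = TRUE) / 7
    b <- sample(1:40, sample(3:20, 1), replace = TRUE) / 7
    expect_equal(ks_two_sample(a, b)$D, brute_D(a, b))
  }
})

test_that("Holm correction matches the hand-applied step-down", {
  expect_equal(holm_correct(0.03), 0.03)
  expect_equal(holm_correct(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_correct(rep(1, 4)), rep(1, 4))
  set.seed(6)
  p <- runif(7)
  adj <- holm_correct(p)
  expect_true(all(adj >= p))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
  expect_error(holm_correct(c(0.5, 1.2)))
})

test_that("mixed model recovers a level effect and respects null groups", {
  spec <- cohort_spec(n_per_group = 6, recordings_per_participant = 3,
                      seed = 301)
  tab <- simulate_cohort_levels(spec, levels = c(2, 3))
  ga <- stats::aggregate(plv ~ participant + group + level, tab, mean)
  ga$level <- factor(ifelse(ga$level == 2, "pulse", "off-pulse"),
                     levels = c("pulse", "off-pulse"))
  res <- fit_level_group_model(ga)
  expect_s3_class(res, "contrast_result")
  a <- res$anova
  expect_lt(a$p[a$effect == "level"], 0.001)
  expect_gt(a$p_holm[a$effect == "group"], 0.05)
  expect_true(all(a$p_holm >= a$p))
  expect_equal(a$df1[a$effect == "level"], 1)
})

test_that("cluster model detects a group-specific occipital pulse boost", {
  ce <- data.frame(group = "YA", cluster = "O", level = "pulse",
                   modifier = 2.5)
  spec <- cohort_spec(n_per_group = 6, recordings_per_participant = 3,
                      cluster_effect = ce, seed = 302)
  tab <- simulate_cohort_levels(spec, levels = c(2, 3))
  agg <- stats::aggregate(plv ~ participant + group + cluster + level, tab,
                          mean)
  agg$level <- factor(ifelse(agg$level == 2, "pulse", "off-pulse"),
                      levels = c("pulse", "off-pulse"))
  res <- fit_level_group_model(agg)
  a <- res$anova
  expect_lt(a$p_holm[a$effect == "cluster:group:level"], 0.01)
})

test_that("paired-contrast fallback agrees with the mixed model direction", {
  spec <- cohort_spec(n_per_group = 5, recordings_per_participant = 2,
                      seed = 303)
  tab <- simulate_cohort_levels(spec, levels = c(2, 3))
  ga <- stats::aggregate(plv ~ participant + group + level, tab, mean)
  ga$level <- factor(ga$level)
  fb <- pulselock:::fallback_paired_contrasts(
    data.frame(plv = ga$plv, participant = factor(ga$participant),
               group = factor(ga$group), level = ga$level))
  expect_equal(fb$method, "paired")
  expect_lt(fb$anova$p[fb$anova$effect == "level"], 0.01)
})
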