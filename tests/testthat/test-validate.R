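# Distribution summaries, ROC, correlation and paired-change statistics.

test_that("distribution tabulates scores and round-trips the fixture", {
  d <- distribution(c(0, 0, 12))
  expect_equal(unname(d$counts[c("0", "12")]), c(2L, 1L))
  expect_equal(d$total_n, 3L)
  empty <- distribution(integer(0))
  expect_equal(empty$total_n, 0L)
  expect_true(all(empty$counts == 0))
  expect_error(distribution(c(1, 13)), "0, 12")
  # expanding the fixture to records and re-tabulating reproduces it
  t3 <- table3_fixture()$admission
  expanded <- rep(0:12, t3$counts)
  expect_equal(distribution(expanded)$counts, t3$counts)
})

test_that("mean/SD of a distribution equal those of the expanded records", {
  t3 <- table3_fixture()
  for (d in t3) {
    expanded <- rep(0:12, d$counts)
    ms <- dist_mean_sd(d)
    expect_equal(unname(ms["mean"]), mean(expanded))
    expect_equal(unname(ms["sd"]), sd(expanded))
  }
  one <- score_distribution(c(0, 0, 5L, rep(0L, 10)))
  expect_equal(unname(dist_mean_sd(one)["sd"]), 0)
  expect_error(dist_mean_sd(score_distribution(c(1L, rep(0L, 12)))),
               "at least 2")
})

test_that("prevalence counts scores at or above the cutoff", {
  t3 <- table3_fixture()
  adm <- prevalence(t3$admission, 6)
  expect_equal(unname(adm["count"]), 19643)
  expect_equal(unname(adm["proportion"]), 19643 / 46743)
  expect_equal(unname(prevalence(t3$admission, 0)["proportion"]), 1)
  # nonincreasing in the cutoff
  props <- vapply(0:12, function(cut)
    prevalence(t3$discharge, cut)[["proportion"]], numeric(1))
  expect_true(all(diff(props) <= 0))
})

test_that("ROC sweep matches pair counting and picks the Youden cutoff", {
  perfect <- roc(c(rep(0, 5), rep(12, 5)), rep(c(FALSE, TRUE), each = 5))
  expect_equal(perfect$auc, 1.0)
  small <- roc(c(1, 3, 2, 4), c(1, 3, 2, 4) %in% c(2, 4))
  expect_equal(small$auc, 0.75)
  expect_error(roc(c(1, 2), c(TRUE, TRUE)), "single class")

  set.seed(202)
  for (rep in 1:20) {
    scores <- sample(0:12, 500, TRUE)
    pos <- runif(500) < plogis((scores - 6) / 2)
    if (all(pos) || !any(pos)) next
    rc <- roc(scores, pos)
    expect_equal(rc$auc, pair_counting_auc(scores, pos),
                 tolerance = 1e-12)
    # lowest cutoff on Youden ties
    j <- rc$sensitivity + rc$specificity - 1
    feas <- rc$thresholds <= 12
    expect_equal(rc$optimal_cutoff,
                 min(rc$thresholds[feas][j[feas] >= max(j[feas]) - 1e-12]))
    # sensitivity nonincreasing as the cutoff rises
    expect_true(all(diff(rc$sensitivity[order(rc$thresholds)]) <= 0))
  }
})

test_that("ROC AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  scores <- sample(0:12, 300, TRUE)
  pos <- runif(300) < plogis((scores - 6) / 2.5)
  rc <- roc(scores, pos)
  ref <- suppressMessages(pROC::auc(pROC::roc(pos, scores,
                                              direction = "<")))
  expect_equal(rc$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("FIM bands follow the published boundaries", {
  expect_equal(fim_categorize(50), "dependent")
  expect_equal(fim_categorize(53), "dependent")
  expect_equal(fim_categorize(54), "modified independence")
  expect_equal(fim_categorize(107), "modified independence")
  expect_equal(fim_categorize(108), "independent")
  expect_equal(fim_categorize(126), "independent")
  expect_error(fim_categorize(10), "18, 126")
})

test_that("spearman uses midranks and matches the rank formula", {
  expect_equal(unname(spearman(1:3, 3:1)["rho"]), -1)
  expect_equal(unname(spearman(1:3, c(1, 3, 2))["rho"]), 0.5)
  # ties: equals explicit midrank Pearson correlation
  x <- c(1, 1, 2, 3, 3, 4)
  y <- c(2, 1, 1, 3, 5, 4)
  expect_equal(unname(spearman(x, y)["rho"]),
               cor(rank(x), rank(y)))
  # invariant under strictly monotone transforms; sign flips under -x
  set.seed(5)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(spearman(exp(a), b)["rho"], spearman(a, b)["rho"])
  expect_equal(unname(spearman(a, -a)["rho"]), -1)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("paired t matches the hand-computed statistic", {
  a <- c(0, 0, 0)
  d <- c(0, 1, 2)
  ch <- paired_t(a, d)
  expect_equal(ch$t_statistic, sqrt(3), tolerance = 1e-12)
  expect_equal(ch$mean_difference, 1)
  expect_equal(ch$df, 2)
  # null case: CI covers zero
  set.seed(10)
  x <- rnorm(100)
  ch0 <- paired_t(x, x + rnorm(100, 0, 0.5))
  expect_true(ch0$ci95[1] <= 0 && ch0$ci95[2] >= 0)
  expect_error(paired_t(1:4, 1:4 + 2), "zero-variance")
})

test_that("signed-rank test matches exact enumeration on small samples", {
  x <- c(10, 12, 9, 14, 8, 11)
  y <- c(12, 11, 13, 21, 8.5, 16)
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(unname(res["p_value"]), brute_wilcoxon_p(y - x),
               tolerance = 1e-12)
  # one-sided structure: all-positive differences give negative-rank sum 0
  res2 <- wilcoxon_signed_rank(c(0, 0, 0), c(1, 2, 3))
  expect_equal(unname(res2["statistic"]), 6)   # positive-rank sum 1+2+3
  # antisymmetry: swapping the phases mirrors the statistic
  res3 <- wilcoxon_signed_rank(y, x)
  n <- sum(y != x)
  expect_equal(unname(res3["statistic"]),
               n * (n + 1) / 2 - unname(res["statistic"]))
  expect_equal(unname(res3["p_value"]), unname(res["p_value"]))
  expect_error(wilcoxon_signed_rank(1:3, 1:3), "zero")
})

test_that("normality check separates normal from uniform samples", {
  set.seed(77)
  gauss <- rnorm(1000)
  unif <- runif(1000)
  kg <- ks_normality(gauss, n_sim = 300, seed = 42)
  ku <- ks_normality(unif, n_sim = 300, seed = 42)
  expect_gt(kg[["p_value"]], 0.05)
  expect_lt(ku[["p_value"]], 0.05)
  expect_true(kg[["statistic"]] >= 0 && kg[["statistic"]] <= 1)
  skip_if_not_installed("nortest")
  expect_equal(kg[["statistic"]], unname(nortest::lillie.test(gauss)$statistic),
               tolerance = 1e-12)
})

test_that("the assembled report reproduces fixture-level statistics", {
  coh <- generate_cohort(cohort_params(n_episodes = 3000, seed = 55))
  rep <- build_report(coh)
  expect_equal(rep$summary$admission[["n"]], 3000)
  expect_equal(sum(rep$score_table$admission_n), 3000L)
  expect_equal(sum(rep$score_table$admission_pct), 100, tolerance = 1e-9)
  expect_s3_class(rep$change, "change_stats")
  expect_true(all(c("frail", "severe") %in% names(rep$fim_roc)))
  # report writing produces the expected delimited tables
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "score_table.csv")))
  expect_true(file.exists(file.path(dir, "roc_frail.csv")))
  st <- read.csv(file.path(dir, "score_table.csv"))
  expect_equal(nrow(st), 13L)
})

test_that("an all-died cohort yields a report without a discharge section", {
  coh <- generate_cohort(cohort_params(n_episodes = 40, seed = 6,
                                       death_rate = 1))
  expect_message(rep <- build_report(coh), "discharge section absent")
  expect_null(rep$summary$discharge)
  expect_equal(rep$n_discharge, 0L)
})
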