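# Score distributions, prevalence, admission-discharge change statistics,
# and ROC/cutpoint validation against the Functional Independence
# Measure.

#' Construct a frailty score distribution
#'
#' @param counts integer vector of counts for scores 0..12 (length 13).
#' @param phase label, e.g. `"admission"`.
#' @return A list of class `score_distribution`: `counts` (named 0..12),
#'   `total_n`, `phase`.
#' @export
score_distribution <- function(counts, phase = NA_character_) {
  counts <- as.integer(counts)
  if (length(counts) != 13 || any(is.na(counts)) || any(counts < 0))
    stop("counts must be 13 nonnegative integers (scores 0..12)")
  structure(list(counts = stats::setNames(counts, 0:12),
                 total_n = sum(counts), phase = phase),
            class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf("score distribution (%s), n = %d\n", x$phase, x$total_n))
  print(x$counts)
  invisible(x)
}

#' Tabulate total scores into a distribution
#'
#' @param scores integer scores in \[0, 12\].
#' @param phase label for the distribution.
#' @return A `score_distribution`.
#' @export
distribution <- function(scores, phase = NA_character_) {
  if (any(is.na(scores)) || any(scores < 0 | scores > 12))
    stop("scores must lie in [0, 12]")
  counts <- tabulate(scores + 1L, nbins = 13L)
  score_distribution(counts, phase)
}

#' Count-weighted mean and sample standard deviation of a distribution
#'
#' @param d a `score_distribution` with at least two observations.
#' @return Named numeric `c(mean, sd)` at full precision (rounding is a
#'   rendering concern).
#' @export
#' @examples
#' dist_mean_sd(table3_fixture()$admission)   # 5.30 (2.59)
dist_mean_sd <- function(d) {
  if (d$total_n < 2) stop("need at least 2 observations for an SD")
  s <- as.numeric(names(d$counts))
  n <- d$total_n
  m <- sum(s * d$counts) / n
  v <- (sum(s^2 * d$counts) - n * m^2) / (n - 1)
  c(mean = m, sd = sqrt(v))
}

#' Frailty prevalence at a cutoff
#'
#' @param d a `score_distribution`.
#' @param cutoff score cutoff; a record counts as frail when its score is
#'   at or above it.
#' @return Named numeric `c(count, proportion)`.
#' @export
#' @examples
#' prevalence(table3_fixture()$admission, 6)   # 19,643 (42.02%)
prevalence <- function(d, cutoff) {
  if (cutoff < 0 || cutoff > 12) stop("cutoff must lie in [0, 12]")
  if (d$total_n == 0) stop("empty distribution")
  s <- as.numeric(names(d$counts))
  cnt <- sum(d$counts[s >= cutoff])
  c(count = cnt, proportion = cnt / d$total_n)
}

#' ROC curve of the frailty score against a reference label
#'
#' Sweeps every integer cutoff: a record is test-positive when its score
#' is at or above the cutoff. AUC by the trapezoidal rule (identical to
#' the tie-adjusted concordant-pair probability); the optimal cutoff
#' maximizes Youden's J (sensitivity + specificity - 1), taking the
#' lowest cutoff on ties.
#'
#' @param scores integer frailty scores in \[0, 12\].
#' @param reference_positive logical reference labels (both classes must
#'   be present).
#' @return A list of class `roc_curve`: `thresholds` (descending),
#'   `sensitivity`, `specificity`, `auc`, `optimal_cutoff`, `youden_j`.
#' @export
roc <- function(scores, reference_positive) {
  stopifnot(length(scores) == length(reference_positive))
  pos <- as.logical(reference_positive)
  if (all(pos) || !any(pos)) stop("reference contains a single class")
  thr <- 13:0                              # >=13 is never positive
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  j <- sens + spec - 1
  feasible <- thr <= 12
  jmax <- max(j[feasible])
  optimal <- min(thr[feasible][j[feasible] >= jmax - 1e-12])
  structure(list(thresholds = thr, sensitivity = sens,
                 specificity = spec, auc = auc,
                 optimal_cutoff = optimal, youden_j = jmax),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  i <- match(x$optimal_cutoff, x$thresholds)
  cat(sprintf(
    "ROC: AUC %.3f; optimal cutoff >=%d (sens %.2f, spec %.2f, J %.2f)\n",
    x$auc, x$optimal_cutoff, x$sensitivity[i], x$specificity[i],
    x$youden_j))
  invisible(x)
}

#' Categorize a Functional Independence Measure total
#'
#' 18--53 dependent, 54--107 modified independence, 108--126 independent.
#'
#' @param fim_total integer totals in \[18, 126\].
#' @return Character vector of categories.
#' @export
fim_categorize <- function(fim_total) {
  if (any(!is.na(fim_total) & (fim_total < 18 | fim_total > 126)))
    stop("FIM totals lie in [18, 126]")
  ifelse(is.na(fim_total), NA_character_,
    ifelse(fim_total <= 53, "dependent",
      ifelse(fim_total <= 107, "modified independence", "independent")))
}

#' Spearman rank correlation with a t-approximation p value
#'
#' Midranks for ties; two-sided p via the t approximation with n - 2
#' degrees of freedom.
#'
#' @param x,y equal-length numeric vectors (n of at least 3).
#' @return Named numeric `c(rho, p_value)`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  rho <- stats::cor(x, y, method = "spearman")
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (abs(rho) >= 1) 0 else 2 * stats::pt(-abs(tstat), n - 2)
  c(rho = rho, p_value = p)
}

#' Paired comparison of admission and discharge scores
#'
#' Two-tailed paired t test on the survivor episodes with both phases,
#' reporting the mean difference (discharge minus admission) with its
#' 95% confidence interval alongside the conventional t statistic.
#'
#' @param admission_scores,discharge_scores paired numeric vectors.
#' @return A list of class `change_stats`: means and SDs per phase,
#'   `mean_difference`, `ci95`, `t_statistic`, `df`, `p_value`, `n`.
#' @export
paired_t <- function(admission_scores, discharge_scores) {
  stopifnot(length(admission_scores) == length(discharge_scores))
  keep <- !is.na(admission_scores) & !is.na(discharge_scores)
  a <- admission_scores[keep]
  d <- discharge_scores[keep]
  if (length(a) < 2) stop("need at least 2 complete pairs")
  if (stats::sd(d - a) == 0) stop("zero-variance differences")
  tt <- stats::t.test(d, a, paired = TRUE)
  structure(list(
    n = length(a),
    mean_admission = mean(a), sd_admission = stats::sd(a),
    mean_discharge = mean(d), sd_discharge = stats::sd(d),
    mean_difference = unname(tt$estimate),
    ci95 = unname(tt$conf.int),
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value
  ), class = "change_stats")
}

#' @export
print.change_stats <- function(x, ...) {
  cat(sprintf(
    paste0("paired change (n=%d): %.2f (SD %.2f) -> %.2f (SD %.2f); ",
           "diff %.2f [%.2f, %.2f], t=%.2f, p=%.3g\n"),
    x$n, x$mean_admission, x$sd_admission, x$mean_discharge,
    x$sd_discharge, x$mean_difference, x$ci95[1], x$ci95[2],
    x$t_statistic, x$p_value))
  invisible(x)
}

#' Wilcoxon signed rank test for paired indicators
#'
#' Zero differences are dropped; midranks on ties; exact null
#' enumeration for 25 or fewer nonzero pairs, normal approximation with
#' continuity correction otherwise. Two-sided.
#'
#' @param x,y paired numeric vectors.
#' @return Named numeric `c(statistic, p_value)` (statistic = positive
#'   rank sum of y - x).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- y - x
  d <- d[!is.na(d) & d != 0]
  if (!length(d)) stop("all differences are zero")
  n <- length(d)
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = n <= 25, correct = TRUE))
  c(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Lilliefors-style normality check
#'
#' One-sample Kolmogorov-Smirnov statistic against a normal with
#' estimated mean and SD; p value by seeded Monte-Carlo resampling of
#' the null.
#'
#' @param values numeric sample (n of at least 5).
#' @param n_sim Monte-Carlo replicates.
#' @param seed integer seed for the null simulation.
#' @return Named numeric `c(statistic, p_value)`.
#' @export
ks_normality <- function(values, n_sim = 500, seed = 1) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 5) stop("need at least 5 observations")
  if (stats::sd(values) == 0) stop("constant input")
  stat <- function(x) {
    z <- stats::pnorm(sort(x), mean(x), stats::sd(x))
    i <- seq_along(z)
    max(i / length(z) - z, z - (i - 1) / length(z))
  }
  d0 <- stat(values)
  set.seed(seed)
  null <- vapply(seq_len(n_sim), function(i) stat(stats::rnorm(n)),
                 numeric(1))
  c(statistic = d0, p_value = (1 + sum(null >= d0)) / (n_sim + 1))
}
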