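# Assembled validation report: demographic, dimension-level and
# score-level summary tables, change statistics and FIM validation.

#' Build the full validation report for a scored cohort
#'
#' Computes demographic marginals, per-phase score distributions with
#' mean/SD and frailty prevalence, paired admission-discharge change
#' statistics, per-indicator Wilcoxon signed-rank tests, the Spearman
#' association of discharge score with the Functional Independence
#' Measure, and ROC validation against the FIM reference bands. All
#' values are kept at full precision; rounding happens only when tables
#' are rendered.
#'
#' @param cohort cohort data frame.
#' @param scores output of [score_cohort()] for `cohort` (computed here
#'   when omitted).
#' @param frail_cutoff,severe_cutoff classification cutoffs.
#' @param rule_tables optional cluster-derived rule tables.
#' @return A list of class `efrail_report` with elements `demographics`,
#'   `score_table` (per-phase counts and percentages by score),
#'   `summary` (per-phase mean/SD/prevalence), `change` (a
#'   `change_stats`, or `NA` when no survivor has both phases),
#'   `indicator_tests` (Wilcoxon per indicator), `fim_spearman`,
#'   `fim_roc` (list with `frail` and `severe` anchors), `n_admission`,
#'   `n_discharge`.
#' @export
build_report <- function(cohort, scores = NULL, frail_cutoff = 6,
                         severe_cutoff = 9, rule_tables = NULL) {
  if (is.null(scores))
    scores <- score_cohort(cohort, "both", rule_tables, frail_cutoff,
                           severe_cutoff)
  adm <- scores[scores$phase == "admission", ]
  dis <- scores[scores$phase == "discharge", ]

  demographics <- list(
    n = nrow(cohort),
    women = c(count = sum(cohort$gender == "woman"),
              pct = 100 * mean(cohort$gender == "woman")),
    age = c(mean = mean(cohort$age), sd = stats::sd(cohort$age),
            median = stats::median(cohort$age)),
    admitted_from_home = c(count = sum(cohort$admitted_from == "home"),
                           pct = 100 * mean(cohort$admitted_from == "home")),
    died = c(count = sum(cohort$discharged_to == "died"),
             pct = 100 * mean(cohort$discharged_to == "died")),
    length_of_stay = c(mean = mean(cohort$length_of_stay),
                       median = stats::median(cohort$length_of_stay))
  )

  dists <- list(admission = distribution(adm$total, "admission"),
                discharge = if (nrow(dis)) distribution(dis$total,
                                                        "discharge"))
  score_table <- data.frame(score = 0:12)
  summaries <- list()
  for (ph in names(dists)) {
    d <- dists[[ph]]
    if (is.null(d)) next
    score_table[[paste0(ph, "_n")]] <- as.integer(d$counts)
    score_table[[paste0(ph, "_pct")]] <- 100 * d$counts / d$total_n
    ms <- dist_mean_sd(d)
    pv <- prevalence(d, frail_cutoff)
    summaries[[ph]] <- c(n = d$total_n, ms,
                         frail_count = unname(pv["count"]),
                         frail_pct = unname(100 * pv["proportion"]))
  }
  if (is.null(dists$discharge))
    message("no discharge scores (all episodes died): ",
            "discharge section absent")

  paired <- merge(adm[c("episode_id", "total")],
                  dis[c("episode_id", "total")], by = "episode_id",
                  suffixes = c("_adm", "_dis"))
  change <- if (nrow(paired) >= 2 &&
                stats::sd(paired$total_dis - paired$total_adm) > 0)
    paired_t(paired$total_adm, paired$total_dis)
  else NA

  indicator_tests <- indicator_wilcoxon(cohort)

  survivors <- cohort$discharged_to != "died" & !is.na(cohort$fim_total)
  fim <- cohort$fim_total[survivors]
  dis_total <- dis$total[match(cohort$episode_id[survivors],
                               dis$episode_id)]
  fim_spearman <- NULL
  fim_roc <- NULL
  if (sum(survivors) >= 3 && stats::sd(fim) > 0) {
    fim_spearman <- spearman(dis_total, fim)
    band <- fim_categorize(fim)
    fim_roc <- list()
    # functionally impaired (not independent) anchors the frail cutoff
    impaired <- band != "independent"
    if (any(impaired) && !all(impaired))
      fim_roc$frail <- roc(dis_total, impaired)
    # severe dependence anchors the severe cutoff
    dependent <- band == "dependent"
    if (any(dependent) && !all(dependent))
      fim_roc$severe <- roc(dis_total, dependent)
  }

  structure(list(
    demographics = demographics,
    score_table = score_table,
    summary = summaries,
    change = change,
    indicator_tests = indicator_tests,
    fim_spearman = fim_spearman,
    fim_roc = fim_roc,
    n_admission = nrow(adm),
    n_discharge = nrow(dis)
  ), class = "efrail_report")
}

# Wilcoxon signed-rank test of each paired indicator across phases
# (survivors only).
indicator_wilcoxon <- function(cohort) {
  surv <- cohort$discharged_to != "died"
  adm_cols <- unlist(dimension_columns("admission")[
    c("cognition", "functional", "continence", "performance", "mood")],
    use.names = FALSE)
  dis_cols <- sub("^adm", "dis", adm_cols)
  out <- lapply(seq_along(adm_cols), function(i) {
    a <- cohort[[adm_cols[i]]][surv]
    d <- cohort[[dis_cols[i]]][surv]
    res <- tryCatch(wilcoxon_signed_rank(a, d),
                    error = function(e) c(statistic = NA_real_,
                                          p_value = NA_real_))
    data.frame(indicator = adm_cols[i], statistic = res["statistic"],
               p_value = res["p_value"], row.names = NULL)
  })
  do.call(rbind, out)
}

#' @export
print.efrail_report <- function(x, ...) {
  cat(sprintf("validation report: %d admissions, %d discharges\n",
              x$n_admission, x$n_discharge))
  for (ph in names(x$summary)) {
    s <- x$summary[[ph]]
    cat(sprintf("  %s: mean %.2f (SD %.2f), frail %d (%.2f%%)\n", ph,
                s["mean"], s["sd"], as.integer(s["frail_count"]),
                s["frail_pct"]))
  }
  if (inherits(x$change, "change_stats"))
    cat(sprintf("  mean change %.2f [%.2f, %.2f], p=%.3g\n",
                x$change$mean_difference, x$change$ci95[1],
                x$change$ci95[2], x$change$p_value))
  if (!is.null(x$fim_spearman))
    cat(sprintf("  Spearman score vs FIM: %.3f (p=%.3g)\n",
                x$fim_spearman["rho"], x$fim_spearman["p_value"]))
  if (!is.null(x$fim_roc$frail))
    cat(sprintf("  AUC vs FIM impairment: %.3f (optimal cutoff >=%d)\n",
                x$fim_roc$frail$auc, x$fim_roc$frail$optimal_cutoff))
  if (!is.null(x$fim_roc$severe))
    cat(sprintf("  AUC vs FIM dependence: %.3f (optimal cutoff >=%d)\n",
                x$fim_roc$severe$auc, x$fim_roc$severe$optimal_cutoff))
  invisible(x)
}

#' Write the report tables as delimited text
#'
#' Emits the score table, per-phase summaries, ROC points and a markdown
#' overview under `dir`. Percentages, means and SDs are rendered to two
#' decimals, correlations to three.
#'
#' @param report an [build_report()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- report$score_table
  for (col in grep("_pct$", names(st), value = TRUE))
    st[[col]] <- round(st[[col]], 2)
  utils::write.table(st, file.path(dir, "score_table.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  summ <- do.call(rbind, lapply(names(report$summary), function(ph)
    data.frame(phase = ph, t(round(report$summary[[ph]], 2)))))
  utils::write.table(summ, file.path(dir, "summary.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  for (anchor in names(report$fim_roc)) {
    rc <- report$fim_roc[[anchor]]
    utils::write.table(
      data.frame(threshold = rc$thresholds,
                 sensitivity = round(rc$sensitivity, 4),
                 specificity = round(rc$specificity, 4)),
      file.path(dir, paste0("roc_", anchor, ".csv")), sep = ",",
      row.names = FALSE, quote = FALSE)
  }
  md <- utils::capture.output(print(report))
  writeLines(c("# e-Frail-CH validation report", "", "```", md, "```"),
             file.path(dir, "report.md"))
  invisible(dir)
}
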