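# Deterministic 0-12 frailty scoring: one rule per dimension, summed.
#
# All condition strings live in this file so any revision of their reading
# is a one-file change. Each graded dimension's intermediate category is
# formalized as the downward-closed region bounded by its printed worst
# pattern, which keeps every dimension score monotone in its indicators
# (worsening an indicator can never lower a score). Missing indicators
# always score as the worst level of their dimension: the instrument is a
# clinical alert, so absence of evidence is treated conservatively.

DIMENSIONS <- c("cognition", "general_health", "functional",
                "social_support", "medication", "mood", "continence",
                "performance")
DIMENSION_MAX <- c(cognition = 2L, general_health = 2L, functional = 2L,
                   social_support = 2L, medication = 1L, mood = 1L,
                   continence = 1L, performance = 1L)

# ---- vectorized cores (matrix in, integer vector out) ----------------

# Validate a panel matrix and recode missing as the worst level.
as_panel_matrix <- function(ind, len, levels) {
  m <- if (is.matrix(ind)) ind else matrix(as.numeric(ind), ncol = len,
                                           byrow = TRUE)
  if (ncol(m) != len)
    stop(sprintf("expected %d indicators, got %d", len, ncol(m)))
  if (any(!is.na(m) & !(m %in% levels)))
    stop("indicator level outside declared set")
  m[is.na(m)] <- max(levels)
  m
}

cognition_scores <- function(m, phase) {
  m <- as_panel_matrix(m, 4L, 0:2)
  zero <- rowSums(m != 0) == 0
  mid <- if (phase == "admission") {
    # alert and oriented, concentration/learning at worst mildly impaired
    m[, 1] == 0 & m[, 2] == 0 & m[, 3] <= 1 & m[, 4] <= 1
  } else {
    # alert, at most one mild impairment among the other three
    m[, 1] == 0 & rowSums(m[, 2:4, drop = FALSE] != 0) <= 1 &
      apply(m[, 2:4, drop = FALSE], 1, max) <= 1
  }
  ifelse(zero, 0L, ifelse(mid, 1L, 2L))
}

functional_scores <- function(m, phase) {
  m <- as_panel_matrix(m, 4L, 0:2)
  zero <- rowSums(m != 0) == 0
  mid <- if (phase == "admission") {
    # dressing unimpaired, self-care at worst mildly impaired
    m[, 1] <= 1 & m[, 2] <= 1 & m[, 3] == 0 & m[, 4] == 0
  } else {
    # dressing unimpaired, at most one self-care impairment (any level)
    m[, 3] == 0 & m[, 4] == 0 & rowSums(m[, 1:2, drop = FALSE] != 0) <= 1
  }
  ifelse(zero, 0L, ifelse(mid, 1L, 2L))
}

continence_scores <- function(m) {
  m <- as_panel_matrix(m, 2L, 0:1)
  as.integer(rowSums(m != 0) > 0)
}

performance_scores <- function(m) {
  m <- as_panel_matrix(m, 5L, 0:1)
  as.integer(rowSums(m != 0) > 0)
}

general_health_scores <- function(n_codes) {
  if (any(!is.na(n_codes) & n_codes < 1))
    stop("a hospitalization carries at least one code")
  out <- ifelse(n_codes == 1, 0L, ifelse(n_codes == 2, 1L, 2L))
  out[is.na(out)] <- 2L
  as.integer(out)
}

medication_scores <- function(n_medications) {
  if (any(!is.na(n_medications) & n_medications < 0))
    stop("medication count must be nonnegative")
  out <- as.integer(n_medications >= 5)
  out[is.na(out)] <- 1L
  out
}

mood_scores <- function(exhaustion, mood_disorder_code) {
  e <- as.logical(exhaustion)
  d <- as.logical(mood_disorder_code)
  e[is.na(e)] <- FALSE
  d[is.na(d)] <- FALSE
  as.integer(e | d)
}

social_scores <- function(marital_status, residence) {
  out <- rep(2L, length(marital_status))
  home <- !is.na(residence) & residence == "home" & !is.na(marital_status)
  out[home & marital_status == "married"] <- 0L
  out[home & marital_status %in% c("single", "divorced")] <- 1L
  out
}

# ---- scalar user-facing rules ----------------------------------------

#' Score the cognition dimension (0, 1 or 2)
#'
#' Four ordinal indicators in \{0,1,2\}: alertness/consciousness,
#' orientation, concentration, capacity to learn / react to daily-life
#' demands. At admission the intermediate category covers patients who are
#' alert and fully oriented with concentration and learning at worst
#' mildly impaired (reference pattern `0+0+(1+1)`); at discharge it covers
#' full alertness with at most one mild impairment among the other three
#' indicators (`0+(1 or 1 or 1)`). Anything worse is category 2. Missing
#' indicators count as level 2.
#'
#' @param ind numeric vector of length 4, levels in \{0,1,2\} or `NA`.
#' @param phase `"admission"` or `"discharge"`.
#' @return Integer score 0, 1 or 2.
#' @export
#' @examples
#' score_cognition(c(0, 0, 1, 1), "admission")
score_cognition <- function(ind, phase = c("admission", "discharge")) {
  phase <- match.arg(phase)
  cognition_scores(matrix(as.numeric(ind), nrow = 1), phase)
}

#' Score general health status from diagnosis/procedure code counts
#'
#' Number of diagnosis (ICD-10) plus surgical-procedure (CHOP) codes at
#' discharge: one code scores 0, two score 1, more than two score 2. A
#' hospitalization implies at least one code.
#'
#' @param n_codes positive integer count of codes.
#' @return Integer score 0, 1 or 2.
#' @export
score_general_health <- function(n_codes) {
  general_health_scores(n_codes)[1]
}

#' Score the functional-independence dimension (0, 1 or 2)
#'
#' Four ordinal self-care indicators in \{0,1,2\}: upper-body care,
#' lower-body care, upper-body dressing, lower-body dressing. At admission
#' the intermediate category covers unimpaired dressing with self-care at
#' worst mildly impaired (reference pattern `(0 or 1) + 1+0+0`); at
#' discharge, unimpaired dressing with at most one self-care impairment of
#' any level (`One or (1 or 2)+0+0`). Missing indicators count as level 2.
#'
#' @inheritParams score_cognition
#' @return Integer score 0, 1 or 2.
#' @export
score_functional <- function(ind, phase = c("admission", "discharge")) {
  phase <- match.arg(phase)
  functional_scores(matrix(as.numeric(ind), nrow = 1), phase)
}

#' Score informal social support from marital status and residence
#'
#' Married and living at home scores 0; single or divorced while living at
#' home scores 1; any other combination (including unknown categories)
#' scores 2.
#'
#' @param marital_status character, e.g. `"married"`, `"single"`,
#'   `"divorced"`, `"widowed"`.
#' @param residence character, `"home"` or a health-care setting.
#' @return Integer score 0, 1 or 2.
#' @export
score_social <- function(marital_status, residence) {
  social_scores(marital_status, residence)[1]
}

#' Score the medication dimension: polypharmacy flag
#'
#' Fewer than five concurrent medications scores 0; five or more
#' (polypharmacy) scores 1.
#'
#' @param n_medications nonnegative count.
#' @return Integer score 0 or 1.
#' @export
score_medication <- function(n_medications) {
  medication_scores(n_medications)[1]
}

#' Score the mood dimension
#'
#' Logical OR of self-reported exhaustion and a coded mood disorder.
#' Missing flags are read as absent.
#'
#' @param exhaustion,mood_disorder_code logical flags (or `NA`).
#' @return Integer score 0 or 1.
#' @export
score_mood <- function(exhaustion, mood_disorder_code) {
  mood_scores(exhaustion, mood_disorder_code)[1]
}

#' Score the continence dimension
#'
#' Two flags: urinary incontinence and presence of a urine drainage
#' device. Both absent scores 0; anything else scores 1.
#'
#' @param ind numeric vector of length 2, flags in \{0,1\} or `NA`.
#' @return Integer score 0 or 1.
#' @export
score_continence <- function(ind) {
  continence_scores(matrix(as.numeric(ind), nrow = 1))[1]
}

#' Score the self-reported performance dimension
#'
#' Five flags: general mobility, mobility for changing position, gait,
#' balance disorder, fall risk. All absent scores 0; anything else 1.
#'
#' @param ind numeric vector of length 5, flags in \{0,1\} or `NA`.
#' @return Integer score 0 or 1.
#' @export
score_performance <- function(ind) {
  performance_scores(matrix(as.numeric(ind), nrow = 1))[1]
}

#' Classify a total frailty score
#'
#' Scores below the frailty cutoff are "not frail"; scores at or above the
#' severe cutoff are "severely frail"; the rest are "frail". Defaults (6
#' and 9) are the cutoffs anchored on the Functional Independence Measure
#' reference bands.
#'
#' @param total integer total score in \[0, 12\].
#' @param frail_cutoff,severe_cutoff integer cutoffs.
#' @return One of `"not frail"`, `"frail"`, `"severely frail"`.
#' @export
#' @examples
#' classify(5); classify(6); classify(9)
classify <- function(total, frail_cutoff = 6, severe_cutoff = 9) {
  if (is.na(total) || total < 0 || total > 12)
    stop("total score must lie in [0, 12]")
  if (total >= severe_cutoff) "severely frail"
  else if (total >= frail_cutoff) "frail"
  else "not frail"
}

# Legacy annotation only: band labels of the 0-17 ancestor scale, never
# used for the frail flag (this instrument spans 0-12).
efs_style_category <- function(total) {
  ifelse(total <= 7, "not frail",
    ifelse(total <= 9, "mild", ifelse(total <= 11, "moderate", "severe")))
}

# ---- per-episode and per-cohort drivers ------------------------------

phase_panels <- function(cohort, phase) {
  p <- if (phase == "admission") "adm" else "dis"
  g <- function(stem, k)
    as.matrix(cohort[paste0(p, "_", stem, seq_len(k))])
  list(
    cog = g("cog", 4), fun = g("fun", 4), con = g("con", 2),
    perf = g("perf", 5),
    exhaustion = cohort[[paste0(p, "_exhaustion")]],
    mood_code = cohort[[paste0(p, "_mood_code")]],
    n_med = if (phase == "admission") cohort$n_medications_admission
            else cohort$n_medications_discharge
  )
}

# All eight dimension scores for every row of a cohort at one phase.
dimension_score_matrix <- function(cohort, phase, rule_tables = NULL) {
  pp <- phase_panels(cohort, phase)
  clustered <- function(dim, combos, fallback) {
    if (!is.null(rule_tables) && !is.null(rule_tables[[dim]]))
      apply_rule_table(rule_tables[[dim]], combos)
    else fallback
  }
  social_combo <- cbind(cohort$marital_status, cohort$residence)
  out <- cbind(
    cognition = clustered("cognition", pp$cog,
                          cognition_scores(pp$cog, phase)),
    general_health = general_health_scores(cohort$n_codes),
    functional = clustered("functional", pp$fun,
                           functional_scores(pp$fun, phase)),
    social_support = clustered("social_support", social_combo,
                               social_scores(cohort$marital_status,
                                             cohort$residence)),
    medication = medication_scores(pp$n_med),
    mood = mood_scores(pp$exhaustion, pp$mood_code),
    continence = clustered("continence", pp$con,
                           continence_scores(pp$con)),
    performance = clustered("performance", pp$perf,
                            performance_scores(pp$perf))
  )
  storage.mode(out) <- "integer"
  out
}

#' Compute the eight dimension scores and 0--12 total for one episode
#'
#' Applies the per-dimension rules to one hospitalization record at the
#' requested phase and sums them into the total frailty score.
#' Cluster-derived rule tables, when supplied, replace the built-in
#' condition strings for the clustered dimensions; the manually allocated
#' dimensions (general health, medication, mood) always use their fixed
#' rules.
#'
#' @param record a single-row data frame in the cohort schema (see
#'   [generate_cohort()]).
#' @param phase `"admission"` or `"discharge"`.
#' @param rule_tables optional named list of rule tables from
#'   [derive_dimension_rules()], keyed by dimension name.
#' @param frail_cutoff,severe_cutoff classification cutoffs.
#' @return A list of class `efrail_result`: `phase`, `dimension_scores`
#'   (named integer vector of length 8), `total`, `frail`, `severe`,
#'   `category`, `category_efs_style`.
#' @export
compute_total <- function(record, phase = c("admission", "discharge"),
                          rule_tables = NULL,
                          frail_cutoff = 6, severe_cutoff = 9) {
  phase <- match.arg(phase)
  stopifnot(nrow(record) == 1)
  if (phase == "discharge" && identical(record$discharged_to, "died"))
    stop("cannot score a died episode at discharge")
  ds <- dimension_score_matrix(record, phase, rule_tables)[1, ]
  total <- sum(ds)
  structure(list(
    phase = phase,
    dimension_scores = ds,
    total = total,
    frail = total >= frail_cutoff,
    severe = total >= severe_cutoff,
    category = classify(total, frail_cutoff, severe_cutoff),
    category_efs_style = efs_style_category(total)
  ), class = "efrail_result")
}

#' @export
print.efrail_result <- function(x, ...) {
  cat(sprintf("frailty score at %s: %d (%s)\n", x$phase, x$total,
              x$category))
  print(x$dimension_scores)
  invisible(x)
}

#' Score every episode of a cohort at one or both phases
#'
#' Vectorized driver over the per-dimension rules. Died episodes are
#' skipped at discharge (no discharge row is emitted for them).
#'
#' @param cohort cohort data frame.
#' @param phase `"admission"`, `"discharge"` or `"both"`.
#' @inheritParams compute_total
#' @return A data frame with `episode_id`, `phase`, one column per
#'   dimension score, `total` and `category`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_params(n_episodes = 50, seed = 1))
#' head(score_cohort(coh, "admission"))
score_cohort <- function(cohort, phase = c("both", "admission", "discharge"),
                         rule_tables = NULL,
                         frail_cutoff = 6, severe_cutoff = 9) {
  phase <- match.arg(phase)
  phases <- if (phase == "both") c("admission", "discharge") else phase
  out <- lapply(phases, function(ph) {
    rows <- if (ph == "discharge") which(cohort$discharged_to != "died")
            else seq_len(nrow(cohort))
    if (!length(rows)) return(NULL)
    sub <- cohort[rows, , drop = FALSE]
    scores <- dimension_score_matrix(sub, ph, rule_tables)
    total <- rowSums(scores)
    data.frame(
      episode_id = sub$episode_id,
      phase = ph,
      scores,
      total = as.integer(total),
      category = ifelse(total >= severe_cutoff, "severely frail",
                   ifelse(total >= frail_cutoff, "frail", "not frail")),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
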