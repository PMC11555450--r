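# Cohort table schema, delimited-text reading/writing, and the study's
# inclusion/exclusion and sparse-dimension rules.

# Canonical column schema: name -> type ("integer", "numeric",
# "character"). Indicator, count and flag columns are integers; missing
# values are empty strings on disk.
cohort_schema <- function() {
  ind <- c(paste0("adm_cog", 1:4), paste0("adm_fun", 1:4),
           paste0("adm_con", 1:2), paste0("adm_perf", 1:5),
           "adm_exhaustion", "adm_mood_code",
           paste0("dis_cog", 1:4), paste0("dis_fun", 1:4),
           paste0("dis_con", 1:2), paste0("dis_perf", 1:5),
           "dis_exhaustion", "dis_mood_code")
  types <- c(
    episode_id = "character", age = "integer", gender = "character",
    admitted_from = "character", discharged_to = "character",
    length_of_stay = "integer", marital_status = "character",
    residence = "character", n_codes = "integer",
    n_medications_admission = "integer",
    n_medications_discharge = "integer", fim_total = "integer",
    nutrition_weight_loss_admission = "integer",
    nutrition_weight_loss_discharge = "integer",
    stats::setNames(rep("integer", length(ind)), ind),
    latent_admission = "numeric", latent_discharge = "numeric"
  )
  types
}

# Columns a dimension draws on, per phase; used by the missingness rules.
dimension_columns <- function(phase = c("admission", "discharge")) {
  phase <- match.arg(phase)
  p <- if (phase == "admission") "adm" else "dis"
  list(
    cognition = paste0(p, "_cog", 1:4),
    functional = paste0(p, "_fun", 1:4),
    continence = paste0(p, "_con", 1:2),
    performance = paste0(p, "_perf", 1:5),
    mood = paste0(p, c("_exhaustion", "_mood_code")),
    social_support = c("marital_status", "residence"),
    nutrition = paste0("nutrition_weight_loss_",
                       if (p == "adm") "admission" else "discharge"),
    general_health = "n_codes",
    medication = paste0("n_medications_",
                        if (p == "adm") "admission" else "discharge")
  )
}

sociodemo_columns <- function() {
  c("age", "gender", "admitted_from", "discharged_to", "length_of_stay",
    "marital_status", "residence")
}

# Health fields entering the 20%-missingness denominator: indicator
# panels plus code and medication counts. Social support (marital
# status, residence) belongs to the sociodemographic block; nutrition is
# assessed separately by drop_sparse_dimensions().
health_columns <- function(phase) {
  cols <- dimension_columns(phase)
  unlist(cols[setdiff(names(cols), c("nutrition", "social_support"))],
         use.names = FALSE)
}

#' Write a cohort as delimited text
#'
#' One row per hospitalization, UTF-8, `.` decimal separator, empty
#' string for missing values.
#'
#' @param cohort cohort data frame.
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  utils::write.table(cohort, path, sep = sep, na = "", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from delimited text
#'
#' Reads a cohort table written by [write_cohort()] (or by a site export
#' renamed through `schema`). Cells that fail to parse under the declared
#' column type become missing and are counted in the attached parse log.
#'
#' @param path input file path.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @param schema optional named character vector mapping canonical column
#'   names to the file's column names (for site-specific headers).
#' @return Cohort data frame; attribute `parse_log` counts coerced cells
#'   per column. Missing mandatory columns raise an error; an empty file
#'   yields an empty cohort with a warning.
#' @export
read_cohort <- function(path, sep = ",", schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", na.strings = "",
                           stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8", check.names = FALSE)
  if (!is.null(schema)) {
    hit <- match(schema, names(raw))
    if (anyNA(hit)) stop("schema names columns absent from the file: ",
                         paste(schema[is.na(hit)], collapse = ", "))
    names(raw)[hit] <- names(schema)
  }
  types <- cohort_schema()
  mandatory <- setdiff(names(types), c("latent_admission",
                                       "latent_discharge"))
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop("mandatory columns missing: ", paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0) {
    warning("empty cohort file")
  }
  parse_log <- integer(0)
  for (col in intersect(names(types), names(raw))) {
    if (types[[col]] == "character") next
    before <- is.na(raw[[col]])
    coerced <- suppressWarnings(as.numeric(raw[[col]]))
    n_bad <- sum(is.na(coerced) & !before)
    if (n_bad) parse_log[col] <- n_bad
    raw[[col]] <- if (types[[col]] == "integer") as.integer(round(coerced))
                  else coerced
  }
  # a died destination with a FIM present is kept but flagged
  inconsistent <- !is.na(raw$discharged_to) & raw$discharged_to == "died" &
    !is.na(raw$fim_total)
  attr(raw, "parse_log") <- parse_log
  attr(raw, "inconsistent_fim") <- which(inconsistent)
  raw
}

#' Apply the study inclusion rules
#'
#' Retains records with age at least 65, a complete sociodemographic
#' block, and at most `missing_threshold` of their health-indicator
#' fields missing. Exclusion reasons are assigned with fixed precedence
#' (age, then sociodemographics, then missingness) so the report counts
#' are unambiguous. Health fields are the indicator panels plus code and
#' medication counts; for died episodes only admission-phase fields enter
#' the denominator. `missing_rule = "per_phase"` applies the threshold
#' within each phase instead of pooled.
#'
#' @param cohort cohort data frame.
#' @param missing_threshold maximum tolerated fraction of missing health
#'   fields (default 0.20).
#' @param missing_rule `"pooled"` (default) or `"per_phase"`.
#' @return A list with `cohort` (retained rows) and `report` (class
#'   `exclusion_report`: `n_input`, `n_retained`, `n_excluded_age`,
#'   `n_excluded_sociodemo`, `n_excluded_missing`).
#' @export
apply_inclusion <- function(cohort, missing_threshold = 0.20,
                            missing_rule = c("pooled", "per_phase")) {
  missing_rule <- match.arg(missing_rule)
  if (is.na(missing_threshold) || missing_threshold < 0 ||
      missing_threshold > 1)
    stop("missing_threshold must lie in [0, 1]")
  n <- nrow(cohort)
  bad_age <- is.na(cohort$age) | cohort$age < 65
  socio <- cohort[sociodemo_columns()]
  bad_socio <- Reduce(`|`, lapply(socio, is.na))
  died <- !is.na(cohort$discharged_to) & cohort$discharged_to == "died"

  frac_missing <- function(cols, rows = TRUE) {
    m <- is.na(as.matrix(cohort[cols]))
    rowMeans(m)
  }
  adm_frac <- frac_missing(health_columns("admission"))
  dis_frac <- frac_missing(health_columns("discharge"))
  n_adm <- length(health_columns("admission"))
  n_dis <- length(health_columns("discharge"))
  pooled_frac <- ifelse(died, adm_frac,
                        (adm_frac * n_adm + dis_frac * n_dis) /
                          (n_adm + n_dis))
  bad_missing <- switch(missing_rule,
    pooled = pooled_frac > missing_threshold,
    per_phase = adm_frac > missing_threshold |
      (!died & dis_frac > missing_threshold))

  reason <- rep("retained", n)
  reason[bad_missing] <- "missing"
  reason[bad_socio] <- "sociodemo"
  reason[bad_age] <- "age"
  keep <- reason == "retained"
  report <- structure(list(
    n_input = n,
    n_retained = sum(keep),
    n_excluded_age = sum(reason == "age"),
    n_excluded_sociodemo = sum(reason == "sociodemo"),
    n_excluded_missing = sum(reason == "missing")
  ), class = "exclusion_report")
  list(cohort = cohort[keep, , drop = FALSE], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf(
    "inclusion: %d of %d retained (%d age, %d sociodemo, %d missingness)\n",
    x$n_retained, x$n_input, x$n_excluded_age, x$n_excluded_sociodemo,
    x$n_excluded_missing))
  invisible(x)
}

#' Drop dimensions with excessive missingness
#'
#' A dimension is dropped when the fraction of missing cells among its
#' fields exceeds the threshold in either phase (the fate of the
#' nutrition dimension in the source register: 92.7% missing at
#' admission, 83.8% at discharge).
#'
#' @param cohort cohort data frame.
#' @param dimensions character vector of dimension names to assess.
#' @param missing_rate_threshold drop threshold (default 0.50).
#' @return A list with `retained` (dimension names kept), `dropped`, and
#'   `missingness`, a data frame of realized per-dimension, per-phase
#'   missing rates.
#' @export
drop_sparse_dimensions <- function(cohort,
                                   dimensions = c(DIMENSIONS, "nutrition"),
                                   missing_rate_threshold = 0.50) {
  known <- union(DIMENSIONS, "nutrition")
  unknown <- setdiff(dimensions, known)
  if (length(unknown))
    stop("unknown dimension name: ", paste(unknown, collapse = ", "))
  rate <- function(dim, phase) {
    cols <- dimension_columns(phase)[[dim]]
    rows <- if (phase == "discharge")
      !is.na(cohort$discharged_to) & cohort$discharged_to != "died"
    else rep(TRUE, nrow(cohort))
    mean(is.na(as.matrix(cohort[rows, cols, drop = FALSE])))
  }
  miss <- data.frame(
    dimension = dimensions,
    admission = vapply(dimensions, rate, numeric(1), phase = "admission"),
    discharge = vapply(dimensions, rate, numeric(1), phase = "discharge"),
    row.names = NULL
  )
  drop <- miss$admission > missing_rate_threshold |
    miss$discharge > missing_rate_threshold
  list(retained = dimensions[!drop], dropped = dimensions[drop],
       missingness = miss)
}
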