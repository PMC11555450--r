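# Packaged register summaries used for calibration and desk-scale checks.

#' Published frailty-score distributions at admission and discharge
#'
#' Returns the printed distribution of total frailty scores (0--12) in the
#' source register: 46,743 scored admissions and 47,361 scored discharges.
#' These count tables are the desk-scale anchor for prevalence, mean and
#' standard-deviation checks, independent of any simulated cohort.
#'
#' @return A list with elements `admission` and `discharge`, each a
#'   `score_distribution` (see [score_distribution()]).
#' @seealso [dist_mean_sd()], [prevalence()]
#' @export
#' @examples
#' t3 <- table3_fixture()
#' prevalence(t3$admission, cutoff = 6)
table3_fixture <- function() {
  adm <- c(268L, 1040L, 5078L, 6871L, 7297L, 6546L, 5438L,
           4373L, 3436L, 2670L, 1878L, 1488L, 360L)
  dis <- c(226L, 782L, 2784L, 6710L, 7350L, 6664L, 5766L,
           5249L, 3900L, 2677L, 2008L, 2511L, 734L)
  list(
    admission = score_distribution(counts = adm, phase = "admission"),
    discharge = score_distribution(counts = dis, phase = "discharge")
  )
}

#' Published sociodemographic marginals of the source register
#'
#' Demographic calibration record for the cohort generator and for report
#' comparison: gender counts, age summaries, provenance, destination,
#' in-hospital deaths and length-of-stay summaries of the 53,690
#' hospitalizations behind the instrument.
#'
#' @return A named list of marginal summaries.
#' @export
table1_marginals <- function() {
  list(
    n_hospitalizations = 53690L,
    gender = c(men = 25672L, women = 28018L),
    age = list(mean = 78.37, sd = 7.91, median = 78, iqr = c(72, 84),
               range = c(65, 106)),
    age_categories = c(`65-74` = 18882L, `>=75` = 34808L),
    admitted_from = c(home = 36792L, healthcare = 16898L),
    discharged_to = c(home = 33738L, healthcare = 17306L, died = 2646L),
    length_of_stay = list(mean = 12.26, sd = 16.5, median = 8,
                          iqr = c(4, 15), range = c(1, 1316))
  )
}

# Per-dimension score-level proportions used to place the ordinal cut
# points of the generator's latent propensities. Social support and
# general health carry a single printed distribution (the measure is the
# same at both phases); all others use the admission column.
dimension_marginals <- function() {
  list(
    cognition      = c(0.719, 0.100, 0.181),
    general_health = c(0.024, 0.062, 0.914),
    functional     = c(0.490, 0.314, 0.197),
    social_support = c(0.299, 0.328, 0.373),
    medication     = c(0.757, 0.243),
    mood           = c(0.757, 0.243),
    continence     = c(0.846, 0.154),
    performance    = c(0.459, 0.541)
  )
}
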