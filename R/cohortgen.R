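# Synthetic hospital-register cohort generator.
#
# One latent frailty factor per episode; each dimension's score is an
# ordinal cut of a noisy propensity u = sqrt(r)*z + sqrt(1-r)*e, with cut
# points placed at the normal quantiles of the published per-dimension
# category marginals. Indicator panels are then materialized as
# combinations consistent with the drawn score, so scoring a generated
# panel recovers the generating score exactly. Admission-to-discharge
# deterioration is a shift of the latent factor, calibrated so the mean
# scored difference equals the configured drift in score points.

#' Parameters of the synthetic cohort generator
#'
#' Defaults reproduce the source register's published structure: age 78.4
#' (SD 7.9), 52.18% women, 68.52% admitted from home, 4.92% in-hospital
#' deaths, nutrition missing for 92.7%/83.8% of admissions/discharges, and
#' a mean admission-to-discharge frailty drift of 0.45 score points.
#'
#' @param n_episodes number of hospitalizations to generate.
#' @param seed integer seed; identical parameters and seed give a
#'   byte-identical cohort.
#' @param latent_mean_admission,latent_sd location/scale of the latent
#'   frailty factor (the score distribution is invariant to them; they
#'   only set the reporting scale of the latent values).
#' @param discharge_drift mean admission-to-discharge deterioration in
#'   score points (applied on the latent scale after calibration).
#' @param death_rate in-hospital death proportion.
#' @param death_latent_logodds optional log-odds coupling of death to the
#'   latent factor (0 = death independent of frailty).
#' @param nutrition_missing_admission,nutrition_missing_discharge
#'   missingness proportions of the nutrition weight-loss flag.
#' @param age_mean,age_sd age distribution before truncation at 65 years.
#' @param prop_women,prop_home_admission demographic proportions.
#' @param factor_loading share of each dimension propensity's variance
#'   carried by the shared latent factor (controls inter-dimension
#'   correlation and hence the total-score spread).
#' @param fim_intercept,fim_slope,fim_noise_sd affine map from the
#'   standardized discharge latent to the Functional Independence Measure
#'   total (slope negative: frailer means less independent), plus
#'   Gaussian measurement noise; totals are clipped to \[18, 126\].
#' @return A validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_episodes, seed,
                          latent_mean_admission = 0, latent_sd = 1,
                          discharge_drift = 0.45,
                          death_rate = 0.0492,
                          death_latent_logodds = 0,
                          nutrition_missing_admission = 0.927,
                          nutrition_missing_discharge = 0.838,
                          age_mean = 78.4, age_sd = 7.9,
                          prop_women = 0.5218,
                          prop_home_admission = 0.6852,
                          factor_loading = 0.4,
                          fim_intercept = 108, fim_slope = -22,
                          fim_noise_sd = 8) {
  p <- as.list(environment())
  if (length(n_episodes) != 1 || is.na(n_episodes) || n_episodes < 1)
    stop("n_episodes must be a positive count")
  props <- c(death_rate, nutrition_missing_admission,
             nutrition_missing_discharge, prop_women,
             prop_home_admission, factor_loading)
  if (any(props < 0 | props > 1))
    stop("proportions must lie in [0, 1]")
  if (latent_sd <= 0 || fim_noise_sd <= 0 || age_sd <= 0)
    stop("scale parameters must be positive")
  p$n_episodes <- as.integer(n_episodes)
  structure(p, class = "cohort_params")
}

# Named substream: a per-block seed derived from the master seed, so each
# variable block draws from its own reproducible stream.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) %% 65011 + 1) * 30011 + h * 7919) %% 2147483629L
}

use_substream <- function(seed, name) set.seed(substream_seed(seed, name))

# Upper ordinal cut points of each dimension propensity: score = number
# of cut points exceeded by u ~ N(0, 1) at admission.
dimension_taus <- function() {
  lapply(dimension_marginals(), function(p) {
    cum <- cumsum(p)
    stats::qnorm(cum[-length(cum)])
  })
}

# Dimensions whose inputs can change between admission and discharge.
# General health (one discharge code count) and social support (marital
# status, residence) are measured once and identical at both phases.
DRIFTING_DIMENSIONS <- c("cognition", "functional", "medication", "mood",
                         "continence", "performance")

# Expected mean total-score shift when the standardized latent moves by
# delta: sum over the drifting dimensions' cut points of
# Phi(sqrt(r)*delta - tau) - Phi(-tau).
expected_score_shift <- function(delta, factor_loading) {
  taus <- unlist(dimension_taus()[DRIFTING_DIMENSIONS], use.names = FALSE)
  sum(stats::pnorm(sqrt(factor_loading) * delta - taus) -
      stats::pnorm(-taus))
}

# Latent shift whose expected scored drift equals `drift` points.
calibrate_drift <- function(drift, factor_loading) {
  if (drift == 0) return(0)
  stats::uniroot(function(d) expected_score_shift(d, factor_loading) - drift,
                 interval = c(-10, 10), extendInt = "yes",
                 tol = 1e-10)$root
}

# Canonical indicator combinations per dimension score, phase-specific
# where the scoring conditions are. Each row scores back to its level.
combo_pool <- function(dimension, phase, score) {
  key <- paste(dimension, phase, score, sep = ".")
  pools <- list(
    cognition.admission.0 = rbind(c(0, 0, 0, 0)),
    cognition.admission.1 = rbind(c(0, 0, 1, 1), c(0, 0, 1, 0),
                                  c(0, 0, 0, 1)),
    cognition.admission.2 = rbind(c(1, 0, 0, 0), c(2, 0, 0, 0),
                                  c(0, 1, 1, 1), c(1, 1, 1, 1),
                                  c(0, 0, 2, 1), c(2, 2, 2, 2)),
    cognition.discharge.0 = rbind(c(0, 0, 0, 0)),
    cognition.discharge.1 = rbind(c(0, 1, 0, 0), c(0, 0, 1, 0),
                                  c(0, 0, 0, 1)),
    cognition.discharge.2 = rbind(c(1, 0, 0, 0), c(0, 1, 1, 0),
                                  c(0, 0, 2, 0), c(2, 1, 1, 1)),
    functional.admission.0 = rbind(c(0, 0, 0, 0)),
    functional.admission.1 = rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                                   c(1, 1, 0, 0)),
    functional.admission.2 = rbind(c(2, 1, 0, 0), c(0, 0, 1, 0),
                                   c(1, 1, 1, 0), c(2, 2, 2, 2)),
    functional.discharge.0 = rbind(c(0, 0, 0, 0)),
    functional.discharge.1 = rbind(c(1, 0, 0, 0), c(2, 0, 0, 0),
                                   c(0, 1, 0, 0), c(0, 2, 0, 0)),
    functional.discharge.2 = rbind(c(1, 1, 0, 0), c(0, 0, 1, 0),
                                   c(2, 2, 1, 1)),
    continence.any.0 = rbind(c(0, 0)),
    continence.any.1 = rbind(c(1, 0), c(0, 1), c(1, 1)),
    performance.any.0 = rbind(c(0, 0, 0, 0, 0)),
    performance.any.1 = rbind(c(1, 0, 0, 0, 0), c(0, 0, 1, 0, 1),
                              c(1, 1, 1, 0, 0), c(1, 1, 1, 1, 1),
                              c(0, 0, 0, 1, 0))
  )
  pools[[key]]
}

social_pool <- function(score) {
  switch(as.character(score),
    "0" = rbind(c("married", "home")),
    "1" = rbind(c("single", "home"), c("divorced", "home")),
    "2" = rbind(c("widowed", "home"), c("married", "healthcare"),
                c("widowed", "healthcare"), c("single", "healthcare")))
}

draw_pool_rows <- function(pools_by_score, scores) {
  ncolp <- ncol(pools_by_score[[1]])
  out <- matrix(NA, nrow = length(scores), ncol = ncolp)
  for (s in seq_along(pools_by_score) - 1L) {
    idx <- which(scores == s)
    if (!length(idx)) next
    pool <- pools_by_score[[s + 1L]]
    out[idx, ] <- pool[sample.int(nrow(pool), length(idx),
                                  replace = TRUE), , drop = FALSE]
  }
  out
}

# Ordinal score of each propensity: number of cut points exceeded.
cut_scores <- function(u, taus) {
  s <- integer(length(u))
  for (tau in taus) s <- s + (u > tau)
  s
}

#' Generate a synthetic hospital-register cohort
#'
#' Draws one latent frailty factor per episode, scores every dimension at
#' admission and discharge through ordinal cuts of noisy propensities,
#' materializes indicator panels consistent with those scores, and adds
#' demographics, code/medication counts, nutrition missingness and a
#' Functional Independence Measure total anchored (negatively) on the
#' discharge latent. Died episodes carry no discharge panel and no FIM.
#'
#' @param params a [cohort_params()] object.
#' @return A data frame, one row per hospitalization, with demographic
#'   columns, `adm_*`/`dis_*` indicator panels, code and medication
#'   counts, `fim_total` and nutrition flags. The generating latent
#'   values are attached as columns `latent_admission` /
#'   `latent_discharge` (the observable register never contains them; they
#'   are retained for calibration checks).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_params(n_episodes = 100, seed = 42))
#' table(coh$discharged_to)
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_episodes
  seed <- params$seed
  r <- params$factor_loading
  taus <- dimension_taus()

  use_substream(seed, "latent")
  z <- stats::rnorm(n)                       # standardized admission latent
  delta <- calibrate_drift(params$discharge_drift, r)
  z_dis <- z + delta

  use_substream(seed, "death")
  p_die <- stats::plogis(stats::qlogis(params$death_rate) +
                         params$death_latent_logodds * z)
  p_die[is.nan(p_die)] <- params$death_rate  # death_rate 0 or 1
  died <- stats::runif(n) < p_die

  propensity <- function(phase, dim) {
    use_substream(seed, paste("prop", phase, dim))
    zz <- if (phase == "admission") z else z_dis
    sqrt(r) * zz + sqrt(1 - r) * stats::rnorm(n)
  }
  dim_scores <- function(phase) {
    s <- vapply(names(taus), function(d)
      cut_scores(propensity(phase, d), taus[[d]]), integer(n))
    matrix(s, nrow = n, dimnames = list(NULL, names(taus)))
  }
  s_adm <- dim_scores("admission")
  s_dis <- dim_scores("discharge")

  panel <- function(phase, dim, scores, stems) {
    ph_key <- if (dim %in% c("cognition", "functional")) phase else "any"
    use_substream(seed, paste("panel", phase, dim))
    pools <- lapply(0:max(DIMENSION_MAX[dim]), function(s)
      combo_pool(dim, ph_key, s))
    m <- draw_pool_rows(pools, scores)
    colnames(m) <- stems
    m
  }
  pfx <- function(phase) if (phase == "admission") "adm" else "dis"
  panels <- function(phase, s) {
    p <- pfx(phase)
    cbind(
      panel(phase, "cognition", s[, "cognition"],
            paste0(p, "_cog", 1:4)),
      panel(phase, "functional", s[, "functional"],
            paste0(p, "_fun", 1:4)),
      panel(phase, "continence", s[, "continence"],
            paste0(p, "_con", 1:2)),
      panel(phase, "performance", s[, "performance"],
            paste0(p, "_perf", 1:5))
    )
  }
  adm_panels <- panels("admission", s_adm)
  dis_panels <- panels("discharge", s_dis)

  use_substream(seed, "social")
  soc <- draw_pool_rows(lapply(0:2, social_pool), s_adm[, "social_support"])

  use_substream(seed, "codes")
  n_codes <- ifelse(s_adm[, "general_health"] == 0, 1L,
              ifelse(s_adm[, "general_health"] == 1, 2L,
                     3L + stats::rpois(n, 4)))

  meds <- function(phase, s) {
    use_substream(seed, paste("meds", phase))
    ifelse(s == 0, sample(0:4, n, replace = TRUE),
           5L + stats::rpois(n, 2))
  }
  n_med_adm <- meds("admission", s_adm[, "medication"])
  n_med_dis <- meds("discharge", s_dis[, "medication"])

  mood_flags <- function(phase, s) {
    use_substream(seed, paste("mood", phase))
    pick <- sample.int(3L, n, replace = TRUE)   # which flag(s) when scored 1
    exh <- s == 1 & pick != 2L
    dx  <- s == 1 & pick != 1L
    cbind(exhaustion = exh, mood_code = dx)
  }
  mood_adm <- mood_flags("admission", s_adm[, "mood"])
  mood_dis <- mood_flags("discharge", s_dis[, "mood"])

  use_substream(seed, "age")
  lo <- stats::pnorm(65, params$age_mean, params$age_sd)
  age <- floor(stats::qnorm(stats::runif(n, lo, 1),
                            params$age_mean, params$age_sd))

  use_substream(seed, "gender")
  gender <- ifelse(stats::runif(n) < params$prop_women, "woman", "man")

  use_substream(seed, "provenance")
  admitted_from <- ifelse(stats::runif(n) < params$prop_home_admission,
                          "home", "healthcare")
  use_substream(seed, "destination")
  discharged_to <- ifelse(died, "died",
                          ifelse(stats::runif(n) < 0.661, "home",
                                 "healthcare"))

  use_substream(seed, "los")
  length_of_stay <- pmin(pmax(round(stats::rlnorm(n, log(8), 0.98)), 1),
                         1316)

  use_substream(seed, "fim")
  fim <- round(params$fim_intercept + params$fim_slope * z_dis +
               stats::rnorm(n, 0, params$fim_noise_sd))
  fim <- pmin(pmax(fim, 18L), 126L)
  fim[died] <- NA_integer_

  use_substream(seed, "nutrition")
  nut_latent <- sqrt(r) * z + sqrt(1 - r) * stats::rnorm(n)
  nut_adm <- as.integer(nut_latent > stats::qnorm(0.85))
  nut_dis <- as.integer((nut_latent + sqrt(r) * delta) > stats::qnorm(0.85))
  nut_adm[stats::runif(n) < params$nutrition_missing_admission] <- NA
  nut_dis[stats::runif(n) < params$nutrition_missing_discharge] <- NA

  coh <- data.frame(
    episode_id = sprintf("E%06d", seq_len(n)),
    age = as.integer(age),
    gender = gender,
    admitted_from = admitted_from,
    discharged_to = discharged_to,
    length_of_stay = as.integer(length_of_stay),
    marital_status = soc[, 1],
    residence = soc[, 2],
    n_codes = as.integer(n_codes),
    n_medications_admission = as.integer(n_med_adm),
    n_medications_discharge = as.integer(n_med_dis),
    fim_total = as.integer(fim),
    nutrition_weight_loss_admission = nut_adm,
    nutrition_weight_loss_discharge = nut_dis,
    adm_panels,
    adm_exhaustion = as.integer(mood_adm[, "exhaustion"]),
    adm_mood_code = as.integer(mood_adm[, "mood_code"]),
    dis_panels,
    dis_exhaustion = as.integer(mood_dis[, "exhaustion"]),
    dis_mood_code = as.integer(mood_dis[, "mood_code"]),
    latent_admission = params$latent_mean_admission + params$latent_sd * z,
    latent_discharge = params$latent_mean_admission +
      params$latent_sd * z_dis,
    stringsAsFactors = FALSE
  )
  dis_cols <- c(grep("^dis_", names(coh), value = TRUE),
                "n_medications_discharge",
                "nutrition_weight_loss_discharge", "latent_discharge")
  coh[died, dis_cols] <- NA
  attr(coh, "params") <- params
  coh
}
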