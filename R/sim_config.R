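# Simulation configuration for the synthetic cohort generator.

#' The nine smoking-associated CpG sites
#'
#' Array identifiers of the nine blood-DNA CpG sites carried through all
#' modules: *AHRR* (cg05575921, cg21161138, cg23576855), *F2RL3*
#' (cg03636183), *2q37.1* (cg21566642, cg01940273, cg05951221, cg06644428)
#' and *6p21.33* (cg06126421).
#' @export
methrisk_cpgs <- c(
  "cg05575921", "cg21161138", "cg23576855", "cg03636183",
  "cg21566642", "cg01940273", "cg05951221", "cg06644428",
  "cg06126421"
)

#' The two CpGs entering the methylation score
#' @export
methrisk_score_cpgs <- c("cg05575921", "cg06126421")

#' Default per-CpG generative profiles
#'
#' One row per CpG: the never-smoker median beta-value, the current-smoker
#' and former-smoker median offsets (beta-value units, at the reference doses
#' of the dose-response component), and the logit-scale dispersion.  The two
#' score CpGs are calibrated to published stratified medians of an
#' older-adult cohort (never 0.88 / current 0.63 at cg05575921; never 0.70 /
#' current 0.57 at cg06126421); the remaining seven sites carry plausible
#' synthetic values chosen to span low- and high-methylation sites.
#'
#' @return A data frame with columns `cpg`, `never_mean`, `current_offset`,
#'   `former_offset`, `dispersion`.
#' @export
default_cpg_profiles <- function() {
  data.frame(
    cpg = methrisk_cpgs,
    never_mean = c(0.88, 0.58, 0.85, 0.80, 0.85, 0.55, 0.65, 0.08, 0.70),
    current_offset = c(
      -0.25, -0.10, -0.05, -0.12, -0.15, -0.10, -0.06,
      -0.015, -0.13
    ),
    former_offset = c(
      -0.05, -0.035, -0.015, -0.04, -0.05, -0.035, -0.02,
      -0.005, -0.06
    ),
    dispersion = c(0.28, 0.20, 0.30, 0.25, 0.25, 0.20, 0.22, 0.30, 0.25),
    stringsAsFactors = FALSE
  )
}

#' Default inter-CpG residual correlation matrix
#'
#' Residual (copula) correlation of the logit-scale noise after smoking
#' effects: 0.55 among the eight strongly inter-correlated sites (0.56 for
#' the two score CpGs) and 0.35 between cg06644428 and all others, so that
#' the marginal rank correlations -- which also pick up the shared smoking
#' signal -- land in the published 0.46-0.93 (and 0.18-0.66 for cg06644428)
#' ranges.
#' @return A 9 x 9 symmetric PSD matrix.
#' @export
default_cpg_correlation <- function() {
  p <- length(methrisk_cpgs)
  R <- matrix(0.55, p, p)
  dimnames(R) <- list(methrisk_cpgs, methrisk_cpgs)
  R["cg06644428", ] <- R[, "cg06644428"] <- 0.35
  R["cg05575921", "cg06126421"] <- R["cg06126421", "cg05575921"] <- 0.56
  diag(R) <- 1
  R
}

#' @keywords internal
default_missing_rates <- function() {
  list(
    smoking_status = 0.022, cigarettes_per_day = 0.004, pack_years = 0.046,
    years_since_cessation = 0.001, bmi_category = 0.003,
    physical_activity = 0.001, prevalent_diabetes = 0.001,
    prevalent_cvd = 0.001,
    cpg = c(
      cg21566642 = 0.003, cg23576855 = 0.001, cg21161138 = 0.001
    )
  )
}

#' Build and validate a simulation configuration
#'
#' Assembles the full parameter set of the synthetic cohort generator and
#' validates its invariants.  Defaults emulate the structure of a
#' population-based cohort of 1,000 older adults (ages 50-75, equal sexes,
#' smoking prevalence 48/33/19% never/former/current, roughly 14% deaths
#' over a median 10.3 years of follow-up split between cardiovascular,
#' cancer and other causes).
#'
#' @param n_participants Cohort size.
#' @param seed Integer seed making generation fully deterministic.
#' @param smoking_prevalence Length-3 vector (never, former, current)
#'   summing to 1.
#' @param cpg_profiles Data frame as returned by [default_cpg_profiles()].
#' @param inter_cpg_correlation Symmetric PSD matrix (one row/column per CpG).
#' @param dose_response_params Named vector: `half_sat_intensity`
#'   (cigarettes/day at which half of the current-smoking methylation effect
#'   is reached), `half_sat_packyears` (pack-years analogue), and
#'   `cessation_tau` (years; exponential time constant of methylation
#'   recovery after quitting).
#' @param hazard_params Named vector: Weibull `shape` and `scale` (years) of
#'   the baseline hazard, plus log hazard ratios `log_hr_score` (per unit of
#'   the two-CpG score), `log_hr_age10` (per 10 years of age) and
#'   `log_hr_male` (male vs female).
#' @param cause_mix Length-3 vector (CVD, cancer, other) of baseline
#'   cause-of-death probabilities, summing to 1.
#' @param admin_censor_years Administrative censoring horizon (years).
#' @param batch_count Number of array batches (plates).
#' @param age_range Length-2 vector of minimum and maximum age.
#' @param missing_rates Per-field MCAR missingness rates (see
#'   `default_missing_rates`); `cpg` is a named sub-vector of per-CpG rates.
#' @param cause_known_rate Probability that a death certificate (hence the
#'   cause of death) is available for a death.
#' @return A validated list of class `methrisk_sim_config`.
#' @export
sim_config <- function(n_participants = 1000,
                       seed = 1,
                       smoking_prevalence = c(never = 0.48, former = 0.33, current = 0.19),
                       cpg_profiles = default_cpg_profiles(),
                       inter_cpg_correlation = default_cpg_correlation(),
                       dose_response_params = c(
                         half_sat_intensity = 7,
                         half_sat_packyears = 15,
                         cessation_tau = 10
                       ),
                       hazard_params = c(
                         shape = 1.4, scale = 74,
                         log_hr_score = 0.6, log_hr_age10 = 0.7,
                         log_hr_male = 0.45
                       ),
                       cause_mix = c(cvd = 0.30, cancer = 0.41, other = 0.29),
                       admin_censor_years = 11.3,
                       batch_count = 5,
                       age_range = c(50, 75),
                       missing_rates = default_missing_rates(),
                       cause_known_rate = 0.944) {
  stopifnot(
    n_participants >= 0, length(seed) == 1,
    length(smoking_prevalence) == 3, length(cause_mix) == 3,
    admin_censor_years > 0, batch_count >= 1,
    length(age_range) == 2, age_range[1] < age_range[2]
  )
  if (abs(sum(smoking_prevalence) - 1) > 1e-9) {
    stop("smoking_prevalence must sum to 1", call. = FALSE)
  }
  if (abs(sum(cause_mix) - 1) > 1e-9) {
    stop("cause_mix must sum to 1", call. = FALSE)
  }
  stopifnot(
    is.data.frame(cpg_profiles),
    all(c("cpg", "never_mean", "current_offset", "former_offset", "dispersion")
    %in% names(cpg_profiles))
  )
  if (any(cpg_profiles$never_mean <= 0 | cpg_profiles$never_mean >= 1)) {
    stop("never-smoker beta means must lie in (0, 1)", call. = FALSE)
  }
  ncpg <- nrow(cpg_profiles)
  stopifnot(nrow(inter_cpg_correlation) == ncpg, ncol(inter_cpg_correlation) == ncpg)
  check_psd(inter_cpg_correlation)
  req <- c(
    "half_sat_intensity", "half_sat_packyears", "cessation_tau"
  )
  stopifnot(all(req %in% names(dose_response_params)))
  req_h <- c("shape", "scale", "log_hr_score", "log_hr_age10", "log_hr_male")
  stopifnot(all(req_h %in% names(hazard_params)))

  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    smoking_prevalence = smoking_prevalence, cpg_profiles = cpg_profiles,
    inter_cpg_correlation = inter_cpg_correlation,
    dose_response_params = dose_response_params,
    hazard_params = hazard_params, cause_mix = cause_mix,
    admin_censor_years = admin_censor_years, batch_count = as.integer(batch_count),
    age_range = age_range, missing_rates = missing_rates,
    cause_known_rate = cause_known_rate
  ), class = "methrisk_sim_config")
}
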