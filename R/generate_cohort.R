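# Synthetic cohort generator: joint smoking / methylation / covariate /
# cause-specific survival structure used by every downstream stage.

# exponential-saturation curve with half-saturation at h
#' @keywords internal
sat_curve <- function(x, h) 1 - 2^(-x / h)

# Reference doses at which the configured status offsets apply exactly
# (typical current/former smoker of the emulated cohort).
.methrisk_ref <- list(
  cpd = 20, packyears_current = 40, packyears_former = 29, cessation = 15
)

#' Generator mean beta-value for given smoking exposure
#'
#' The noise-free mean of the generative model for each CpG: never smokers
#' sit at the configured never-smoker mean; current smokers decline with
#' current intensity and pack-years along exponential-saturation curves;
#' former smokers recover exponentially with years since cessation.  Offsets
#' are calibrated so that a typical current smoker (20 cigarettes/day,
#' 40 pack-years) and a typical former smoker (29 pack-years, 15 years since
#' quitting) realize exactly the configured current/former median offsets.
#'
#' @param config A `methrisk_sim_config`.
#' @param status `"never"`, `"former"` or `"current"` (scalar or vector).
#' @param cigarettes_per_day,pack_years,years_since_cessation Exposures
#'   (vectors recycled against `status`).
#' @return Matrix (length(status) x CpGs) of mean beta-values, clipped to
#'   \[0.02, 0.98\].
#' @export
generator_mean_beta <- function(config, status, cigarettes_per_day = 0,
                                pack_years = 0, years_since_cessation = 0) {
  stopifnot(inherits(config, "methrisk_sim_config"))
  prof <- config$cpg_profiles
  dr <- config$dose_response_params
  nn <- max(length(status), length(cigarettes_per_day), length(pack_years),
    length(years_since_cessation))
  status <- rep_len(status, nn)
  cpd <- rep_len(cigarettes_per_day, nn)
  py <- rep_len(pack_years, nn)
  ysc <- rep_len(years_since_cessation, nn)
  ref <- .methrisk_ref
  out <- matrix(NA_real_, nn, nrow(prof), dimnames = list(NULL, prof$cpg))
  for (j in seq_len(nrow(prof))) {
    eff <- numeric(nn)
    cur <- status == "current"
    fmr <- status == "former"
    if (any(cur)) {
      mult <- 0.7 * sat_curve(cpd[cur], dr[["half_sat_intensity"]]) /
        sat_curve(ref$cpd, dr[["half_sat_intensity"]]) +
        0.3 * sat_curve(py[cur], dr[["half_sat_packyears"]]) /
          sat_curve(ref$packyears_current, dr[["half_sat_packyears"]])
      eff[cur] <- prof$current_offset[j] * mult
    }
    if (any(fmr)) {
      raw <- prof$former_offset[j] *
        sat_curve(py[fmr], dr[["half_sat_packyears"]]) /
        sat_curve(ref$packyears_former, dr[["half_sat_packyears"]]) *
        exp(-(ysc[fmr] - ref$cessation) / dr[["cessation_tau"]])
      cap <- abs(prof$current_offset[j])
      eff[fmr] <- sign(raw) * pmin(abs(raw), cap)
    }
    out[, j] <- pmin(pmax(prof$never_mean[j] + eff, 0.02), 0.98)
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws a full synthetic cohort -- demographics, smoking history, clinical
#' covariates, beta-values at the nine CpGs, and cause-specific survival --
#' under the generative model described in the package vignette:
#' logit-normal beta-values with a Gaussian copula carrying the configured
#' inter-CpG correlation; mean methylation following saturating dose-response
#' and cessation-recovery curves; event times from a Weibull
#' proportional-hazards model whose linear predictor contains the two-CpG
#' methylation score, age and sex; censoring as the administrative horizon
#' minus a uniform entry stagger (0.3 years).  Output is bit-identical for a
#' fixed seed.
#'
#' @param config A validated [sim_config()].
#' @return An object of class `methrisk_cohort`: a list with data frames
#'   `cohort`, `methylation`, `survival` (keyed by `participant_id`) and
#'   attribute `config`.
#' @examples
#' cc <- generate_cohort(sim_config(n_participants = 100, seed = 7))
#' table(cc$cohort$smoking_status)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "methrisk_sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  prof <- config$cpg_profiles
  cpgs <- prof$cpg

  if (n == 0L) {
    empty <- empty_cohort_tables(cpgs)
    return(structure(empty, class = "methrisk_cohort", config = config))
  }

  id <- seq_len(n)
  sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
  age <- stats::runif(n, config$age_range[1], config$age_range[2])

  # smoking status with a mild male tilt for current/former smoking,
  # preserving the configured marginal prevalence
  prev <- config$smoking_prevalence
  tilt <- function(p_m) {
    p <- rbind(
      male = c(NA, prev[2] * 2 * 0.60, prev[3] * 2 * 0.613),
      female = c(NA, prev[2] * 2 * 0.40, prev[3] * 2 * 0.387)
    )
    p[, 2:3] <- pmin(p[, 2:3], 0.95 / 2)
    p[, 1] <- 1 - rowSums(p[, 2:3, drop = FALSE])
    p[p < 0] <- 0
    p / rowSums(p)
  }
  pm <- tilt()
  u <- stats::runif(n)
  smoking <- character(n)
  for (s in c("male", "female")) {
    rows <- sex == s
    br <- cumsum(pm[s, ])
    smoking[rows] <- c("never", "former", "current")[
      1 + findInterval(u[rows], br[-3])
    ]
  }

  cpd <- numeric(n)
  cur <- smoking == "current"
  cpd[cur] <- pmin(pmax(round(stats::rlnorm(sum(cur), log(20), 0.35)), 1), 60)

  start_age <- pmin(pmax(stats::rnorm(n, 18, 3), 14), 30)
  ysc <- rep(NA_real_, n)
  fmr <- smoking == "former"
  ysc[fmr] <- pmin(
    pmax(stats::rgamma(sum(fmr), shape = 2.2, scale = 8), 0.5),
    age[fmr] - start_age[fmr] - 1
  )
  years_smoked <- numeric(n)
  years_smoked[cur] <- pmax(age[cur] - start_age[cur], 1)
  years_smoked[fmr] <- pmax(age[fmr] - start_age[fmr] - ysc[fmr], 1)
  cpd_hist <- numeric(n)
  cpd_hist[cur] <- cpd[cur]
  cpd_hist[fmr] <- pmin(pmax(round(stats::rlnorm(sum(fmr), log(18), 0.4)), 1), 60)
  pack_years <- cpd_hist / 20 * years_smoked

  bmi_category <- sample(c("under", "normal", "over", "obese"), n,
    replace = TRUE, prob = c(0.008, 0.244, 0.485, 0.263)
  )
  physical_activity <- sample(c("inactive", "insufficient", "sufficient"), n,
    replace = TRUE, prob = c(0.203, 0.438, 0.359)
  )
  systolic_bp <- round(stats::rnorm(n, 140, 18), 1)
  total_cholesterol <- round(stats::rnorm(n, 220, 40), 1)
  prevalent_cvd <- stats::runif(n) < 0.216
  prevalent_diabetes <- stats::runif(n) < 0.162
  prevalent_cancer <- stats::runif(n) < 0.066
  batch <- sprintf("batch%02d", sample.int(config$batch_count, n, replace = TRUE))

  # methylation: logit-normal with Gaussian copula on the residuals
  mu <- generator_mean_beta(config, smoking, cpd, pack_years,
    ifelse(is.na(ysc), 0, ysc))
  R <- config$inter_cpg_correlation
  D <- diag(prof$dispersion, nrow(prof))
  Sig <- D %*% R %*% D
  ee <- eigen(Sig, symmetric = TRUE)
  A <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), nrow(prof))
  Z <- matrix(stats::rnorm(n * nrow(prof)), n, nrow(prof))
  eps <- Z %*% t(A)
  beta <- stats::plogis(stats::qlogis(mu) + eps)
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  colnames(beta) <- cpgs

  # methylation score drives the hazard
  score <- if (n >= 8) {
    qa <- assign_quartiles(as.data.frame(beta))
    as.numeric(build_score(qa))
  } else {
    numeric(n)
  }

  hz <- config$hazard_params
  lp <- hz[["log_hr_score"]] * score +
    hz[["log_hr_age10"]] * (age - 62) / 10 +
    hz[["log_hr_male"]] * (sex == "male")
  Tdeath <- hz[["scale"]] * (-log(stats::runif(n)) * exp(-lp))^(1 / hz[["shape"]])
  Cens <- config$admin_censor_years - stats::runif(n, 0, 0.3)
  time <- pmin(Tdeath, Cens)
  event <- as.integer(Tdeath <= Cens)

  # cause of death: multinomial with logits tilted by score and smoking
  cause <- rep("none", n)
  dead <- which(event == 1L)
  if (length(dead)) {
    lg <- matrix(log(config$cause_mix), length(dead), 3, byrow = TRUE)
    lg[, 1] <- lg[, 1] + 0.35 * score[dead] + 0.2 * (smoking[dead] == "current")
    lg[, 3] <- lg[, 3] + 0.1 * score[dead]
    pr <- exp(lg) / rowSums(exp(lg))
    uu <- stats::runif(length(dead))
    pick <- 1 + (uu > pr[, 1]) + (uu > pr[, 1] + pr[, 2])
    cause[dead] <- c("cvd", "cancer", "other")[pick]
  }
  cause_known <- rep(TRUE, n)
  cause_known[dead] <- stats::runif(length(dead)) < config$cause_known_rate
  cause[dead][!cause_known[dead]] <- NA_character_

  cohort <- data.frame(
    participant_id = id, sex = sex, age = age, smoking_status = smoking,
    cigarettes_per_day = cpd, pack_years = pack_years,
    years_since_cessation = ysc, bmi_category = bmi_category,
    physical_activity = physical_activity, systolic_bp = systolic_bp,
    total_cholesterol = total_cholesterol,
    prevalent_cvd = prevalent_cvd, prevalent_diabetes = prevalent_diabetes,
    prevalent_cancer = prevalent_cancer, batch = batch,
    stringsAsFactors = FALSE
  )
  methylation <- data.frame(participant_id = id, beta, stringsAsFactors = FALSE)
  surv <- data.frame(
    participant_id = id, time = time, event = event, cause = cause,
    cause_known = cause_known, stringsAsFactors = FALSE
  )

  # MCAR missingness
  mr <- config$missing_rates
  mask <- function(rate, eligible = rep(TRUE, n)) {
    eligible & stats::runif(n) < rate
  }
  m_status <- mask(mr$smoking_status %||% 0)
  cohort$smoking_status[m_status] <- NA
  cohort$cigarettes_per_day[m_status | mask(mr$cigarettes_per_day %||% 0, cur)] <- NA
  cohort$pack_years[m_status | mask(mr$pack_years %||% 0, cur | fmr)] <- NA
  cohort$years_since_cessation[
    (m_status & fmr) | mask(mr$years_since_cessation %||% 0, fmr)
  ] <- NA
  cohort$bmi_category[mask(mr$bmi_category %||% 0)] <- NA
  cohort$physical_activity[mask(mr$physical_activity %||% 0)] <- NA
  cohort$prevalent_diabetes[mask(mr$prevalent_diabetes %||% 0)] <- NA
  cohort$prevalent_cvd[mask(mr$prevalent_cvd %||% 0)] <- NA
  if (length(mr$cpg)) {
    for (cg in names(mr$cpg)) {
      k <- round(mr$cpg[[cg]] * n)
      if (k > 0 && cg %in% names(methylation)) {
        methylation[[cg]][sample.int(n, k)] <- NA
      }
    }
  }

  structure(
    list(cohort = cohort, methylation = methylation, survival = surv),
    class = "methrisk_cohort", config = config
  )
}

#' @keywords internal
empty_cohort_tables <- function(cpgs) {
  cohort <- data.frame(
    participant_id = integer(0), sex = character(0), age = numeric(0),
    smoking_status = character(0), cigarettes_per_day = numeric(0),
    pack_years = numeric(0), years_since_cessation = numeric(0),
    bmi_category = character(0), physical_activity = character(0),
    systolic_bp = numeric(0), total_cholesterol = numeric(0),
    prevalent_cvd = logical(0), prevalent_diabetes = logical(0),
    prevalent_cancer = logical(0), batch = character(0),
    stringsAsFactors = FALSE
  )
  meth <- cbind(
    data.frame(participant_id = integer(0)),
    as.data.frame(matrix(numeric(0), 0, length(cpgs),
      dimnames = list(NULL, cpgs)
    ))
  )
  surv <- data.frame(
    participant_id = integer(0), time = numeric(0), event = integer(0),
    cause = character(0), cause_known = logical(0), stringsAsFactors = FALSE
  )
  list(cohort = cohort, methylation = meth, survival = surv)
}

#' @export
print.methrisk_cohort <- function(x, ...) {
  cat(
    "Synthetic cohort: n =", nrow(x$cohort), "participants,",
    sum(x$survival$event), "deaths\n"
  )
  invisible(x)
}
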