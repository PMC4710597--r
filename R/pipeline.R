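# End-to-end pipeline: simulate -> describe -> dose-response -> cox ->
# score -> evaluate, producing paper-style CSV tables, a plain-text log and
# a manifest with content hashes.  All randomness flows from a single root
# seed split per stage, so repeated runs with the same configuration are
# identical file for file.

#' Pipeline configuration
#'
#' Assembles (and validates) the configuration consumed by
#' [run_pipeline()].  `config` may also be the path of a YAML file holding
#' any subset of these fields (the simulation block is passed to
#' [sim_config()]).
#'
#' @param sim A [sim_config()] for the synthetic cohort (or a list of its
#'   arguments).
#' @param out_dir Output directory.
#' @param seed Root seed; per-stage seeds are derived from it.
#' @param horizon Risk-prediction horizon in years.
#' @param bootstrap_B Bootstrap replicates for the optimism correction.
#' @param ties Cox tie handling.
#' @param knots Spline knot count for dose-response curves.
#' @param dose_cpgs CpGs for which dose-response curves are produced.
#' @param eval_cpgs CpGs added to the SCORE model in the evaluation stage.
#' @param score_vars Covariates of the base risk model (SCORE variables plus
#'   batch).
#' @param models Named list of covariate sets for Cox models 1-3.
#' @param sensitivity_exclude_prevalent_cvd Also run the evaluation on
#'   participants free of CVD at baseline.
#' @return A list of class `methrisk_run_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            out_dir = tempfile("methrisk_run_"),
                            seed = 1,
                            horizon = 10,
                            bootstrap_B = 200,
                            ties = "breslow",
                            knots = 4,
                            dose_cpgs = methrisk_score_cpgs,
                            eval_cpgs = methrisk_score_cpgs,
                            score_vars = c(
                              "age", "sex", "systolic_bp",
                              "current_smoker", "total_cholesterol", "batch"
                            ),
                            models = list(
                              model1 = c("age", "sex", "batch"),
                              model2 = c(
                                "age", "sex", "batch", "smoking_status",
                                "meth_score"
                              ),
                              model3 = c(
                                "age", "sex", "batch", "smoking_status",
                                "meth_score", "bmi_category",
                                "physical_activity", "systolic_bp",
                                "total_cholesterol", "prevalent_cvd",
                                "prevalent_diabetes", "prevalent_cancer"
                              )
                            ),
                            sensitivity_exclude_prevalent_cvd = FALSE) {
  if (is.character(sim)) sim <- yaml::read_yaml(sim)
  if (!inherits(sim, "methrisk_sim_config")) sim <- do.call(sim_config, sim)
  known <- c(
    "participant_id", "sex", "age", "smoking_status", "cigarettes_per_day",
    "pack_years", "years_since_cessation", "bmi_category",
    "physical_activity", "systolic_bp", "total_cholesterol",
    "prevalent_cvd", "prevalent_diabetes", "prevalent_cancer", "batch",
    "current_smoker", "meth_score", sim$cpg_profiles$cpg
  )
  for (nm in names(models)) {
    bad <- setdiff(models[[nm]], known)
    if (length(bad)) {
      stop(
        "model '", nm, "' references unknown column(s): ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  bad <- setdiff(score_vars, known)
  if (length(bad)) {
    stop("score_vars references unknown column(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- setdiff(c(dose_cpgs, eval_cpgs), sim$cpg_profiles$cpg)
  if (length(bad)) {
    stop("unknown CpG(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(
    sim = sim, out_dir = out_dir, seed = as.integer(seed), horizon = horizon,
    bootstrap_B = bootstrap_B, ties = ties, knots = knots,
    dose_cpgs = dose_cpgs, eval_cpgs = eval_cpgs, score_vars = score_vars,
    models = models,
    sensitivity_exclude_prevalent_cvd = sensitivity_exclude_prevalent_cvd
  ), class = "methrisk_run_config")
}

#' @keywords internal
pipeline_analysis_frame <- function(tabs) {
  d <- merge(tabs$cohort, tabs$methylation, by = "participant_id")
  d <- merge(d, tabs$survival, by = "participant_id")
  d <- d[order(d$participant_id), , drop = FALSE]
  d$current_smoker <- ifelse(is.na(d$smoking_status), NA,
    as.numeric(d$smoking_status == "current")
  )
  cpgs <- intersect(methrisk_cpgs, names(d))
  qa <- assign_quartiles(d[, c("participant_id", cpgs)])
  d$meth_score <- as.character(build_score(qa))
  rownames(d) <- NULL
  list(data = d, quartiles = qa, cpgs = cpgs)
}

# cause-specific event indicator: competing (and unknown-cause) deaths are
# censored at the death time
#' @keywords internal
cause_event <- function(surv, outcome) {
  if (outcome == "all") {
    return(surv$event)
  }
  as.integer(surv$event == 1 & !is.na(surv$cause) & surv$cause == outcome)
}

#' Run the full analysis pipeline
#'
#' Executes simulate, describe, dose-response, cox, score and evaluate in
#' sequence, writing paper-style CSV tables under `out_dir`, a `log.txt`
#' with per-stage timings and per-model complete-case drop counts, and a
#' `manifest.yaml` listing every output file with its MD5 hash and the
#' per-stage seeds.  Deterministic for a fixed configuration.
#'
#' @param config A [pipeline_config()] (or path to a YAML file of its
#'   fields).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  if (!inherits(config, "methrisk_run_config")) {
    config <- do.call(pipeline_config, config)
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "log.txt")
  cat("methrisk pipeline run\n", file = logf)
  note <- function(...) {
    cat(paste0(..., "\n"), file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    note(sprintf("stage %-14s %.2f s", name, proc.time()[["elapsed"]] - t0))
    res
  }
  files <- character(0)
  emit <- function(df, name) {
    f <- file.path(out, name)
    utils::write.csv(df, f, row.names = FALSE, na = "")
    files <<- c(files, f)
    f
  }
  seeds <- c(
    simulate = derive_seed(config$seed, 1),
    evaluate = derive_seed(config$seed, 2)
  )

  # -- simulate ---------------------------------------------------------
  tabs <- stage("simulate", {
    sim <- config$sim
    sim$seed <- seeds[["simulate"]]
    cc <- generate_cohort(sim)
    files <<- c(files, write_cohort(cc, file.path(out, "data")))
    cc
  })
  af <- pipeline_analysis_frame(tabs)
  d <- af$data
  cpgs <- af$cpgs

  # -- describe ---------------------------------------------------------
  stage("describe", {
    strat_vars <- c(
      "sex", "smoking_status", "bmi_category", "physical_activity",
      "prevalent_diabetes", "prevalent_cvd", "prevalent_cancer"
    )
    rows <- list()
    for (v in strat_vars) {
      for (cg in cpgs) {
        s <- stratified_medians(d[[cg]], d[[v]])
        s <- cbind(variable = v, cpg = cg, s)
        rows[[length(rows) + 1]] <- s
      }
    }
    emit(do.call(rbind, rows), "table1_stratified_medians.csv")
    cm <- spearman_matrix(d[, cpgs])
    emit(cbind(cpg = rownames(cm), as.data.frame(cm)), "table_s2_spearman.csv")
    ir_rows <- list()
    for (outc in c("all", "cvd", "cancer", "other")) {
      evs <- cause_event(d, outc)
      for (v in c("meth_score", "smoking_status")) {
        ok <- !is.na(d[[v]])
        agg_n <- table(d[[v]][ok])
        agg_c <- tapply(evs[ok], d[[v]][ok], sum)
        agg_py <- tapply(d$time[ok], d[[v]][ok], sum)
        ir <- incidence_rate(as.vector(agg_c), as.vector(agg_py))
        ir_rows[[length(ir_rows) + 1]] <- data.frame(
          outcome = outc, variable = v, level = names(agg_n),
          n = as.vector(agg_n), cases = ir$cases,
          person_years = round(ir$person_years, 2),
          incidence_rate = round(ir$rate, 2)
        )
      }
    }
    emit(do.call(rbind, ir_rows), "table3_incidence_rates.csv")
  })

  # -- dose-response ----------------------------------------------------
  stage("dose_response", {
    adj <- c(
      "age", "sex", "bmi_category", "physical_activity",
      "prevalent_cvd", "prevalent_diabetes", "prevalent_cancer", "batch"
    )
    cov <- as.data.frame(build_design(d, adj))
    coef_rows <- list()
    for (cg in config$dose_cpgs) {
      ols <- fit_adjusted_ols(
        d[[cg]],
        cbind(
          as.data.frame(build_design(d, "smoking_status",
            references = c(smoking_status = "never")
          )),
          cov
        )
      )
      cf <- ols$coefficients
      cf <- cf[grep("smoking_status", cf$term), , drop = FALSE]
      coef_rows[[length(coef_rows) + 1]] <- cbind(cpg = cg, cf, n = ols$n)
      exposures <- list(
        intensity = list(
          x = ifelse(is.na(d$cigarettes_per_day), NA, d$cigarettes_per_day),
          ref = !is.na(d$smoking_status) & d$smoking_status != "current"
        ),
        packyears = list(
          x = d$pack_years,
          ref = !is.na(d$smoking_status) & d$smoking_status == "never"
        ),
        cessation = list(
          x = ifelse(!is.na(d$smoking_status) & d$smoking_status == "current",
            0, d$years_since_cessation
          ),
          ref = !is.na(d$smoking_status) & d$smoking_status == "current"
        )
      )
      for (en in names(exposures)) {
        ex <- exposures[[en]]
        sub <- if (en == "cessation") {
          !is.na(d$smoking_status) & d$smoking_status %in% c("former", "current")
        } else {
          rep(TRUE, nrow(d))
        }
        cv <- dose_response_curve(
          d[[cg]][sub], ex$x[sub], ex$ref[sub],
          covariates = cov[sub, , drop = FALSE]
        )
        emit(
          as.data.frame(cv),
          sprintf("fig1_curve_%s_%s.csv", cg, en)
        )
      }
    }
    emit(do.call(rbind, coef_rows), "table2_smoking_coefficients.csv")
  })

  # -- cox --------------------------------------------------------------
  stage("cox", {
    hr_rows <- list()
    refs <- c(smoking_status = "never", meth_score = "0")
    for (outc in c("all", "cvd", "cancer", "other")) {
      evs <- cause_event(d, outc)
      for (mn in names(config$models)) {
        X <- build_design(d, config$models[[mn]], references = refs)
        fit <- suppressWarnings(
          fit_cox(d$time, evs, X, ties = config$ties)
        )
        note(sprintf(
          "cox %s/%s: n=%d events=%d dropped=%d",
          outc, mn, fit$n, fit$nevent, fit$n_dropped
        ))
        se <- sqrt(diag(fit$var))
        keep <- grep("meth_score|smoking_status", names(fit$coef))
        if (length(keep)) {
          hr_rows[[length(hr_rows) + 1]] <- data.frame(
            outcome = outc, model = mn, term = names(fit$coef)[keep],
            hr = exp(fit$coef[keep]),
            lower = exp(fit$coef[keep] - 1.96 * se[keep]),
            upper = exp(fit$coef[keep] + 1.96 * se[keep]),
            p_value = 2 * stats::pnorm(-abs(fit$coef[keep] / se[keep])),
            n = fit$n, events = fit$nevent, row.names = NULL
          )
        }
      }
    }
    emit(do.call(rbind, hr_rows), "table3_hazard_ratios.csv")
    km <- kaplan_meier(d$time, d$event, d$meth_score)
    emit(as.data.frame(km), "fig_s2_km_by_score.csv")
  })

  # -- score ------------------------------------------------------------
  stage("score", {
    q <- af$quartiles$quartile
    emit(data.frame(
      participant_id = d$participant_id,
      q_flag_cg05575921 = as.integer(q$cg05575921 == 1L),
      q_flag_cg06126421 = as.integer(q$cg06126421 == 1L),
      score = d$meth_score
    ), "scores.csv")
  })

  # -- evaluate ---------------------------------------------------------
  stage("evaluate", {
    runs <- list(full = rep(TRUE, nrow(d)))
    if (isTRUE(config$sensitivity_exclude_prevalent_cvd)) {
      runs$no_prevalent_cvd <- !is.na(d$prevalent_cvd) & !d$prevalent_cvd
    }
    ev_rows <- list()
    for (rn in names(runs)) {
      sub <- d[runs[[rn]], , drop = FALSE]
      rep_df <- evaluate_risk_models(
        sub,
        base_vars = config$score_vars, add_cpgs = config$eval_cpgs,
        horizon = config$horizon, B = config$bootstrap_B,
        seed = seeds[["evaluate"]], ties = config$ties
      )
      ev_rows[[length(ev_rows) + 1]] <- cbind(analysis = rn, rep_df)
    }
    emit(do.call(rbind, ev_rows), "table4_evaluation.csv")
  })

  manifest <- list(
    package = "methrisk",
    root_seed = config$seed,
    stage_seeds = as.list(seeds),
    n_participants = nrow(d),
    files = lapply(sort(files), function(f) {
      list(
        path = sub(paste0("^", out, "/?"), "", f),
        md5 = unname(tools::md5sum(f))
      )
    })
  )
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(manifest)
}

#' Evaluate the incremental value of methylation markers for fatal CVD
#'
#' Fits the base risk model (SCORE variables plus batch) for cardiovascular
#' mortality and the model additionally containing the requested CpGs, then
#' assembles the full evaluation report: -2 log L / df / AIC, the
#' likelihood-ratio test, apparent and .632-bootstrap optimism-corrected
#' Harrell's C, categorical NRI and IDI at the recommended 10-year risk
#' categories, Gronnesby-Borgan calibration, and VIF/tolerance of the added
#' CpGs.  Cases for NRI/IDI are deaths from CVD during follow-up; all other
#' participants (including other deaths) are controls.
#'
#' @param data Analysis frame from the pipeline (cohort + methylation +
#'   survival + derived columns).
#' @param base_vars Covariates of the base model.
#' @param add_cpgs CpGs to add (evaluated jointly).
#' @param horizon Risk horizon in years.
#' @param B Bootstrap replicates.
#' @param seed Seed for the bootstrap.
#' @param ties Cox tie handling.
#' @return A data frame with one row per reported quantity (`metric`,
#'   `model`, `value`).
#' @export
evaluate_risk_models <- function(data, base_vars, add_cpgs, horizon = 10,
                                 B = 200, seed = 1, ties = "breslow") {
  evs <- cause_event(data, "cvd")
  Xb <- build_design(data, base_vars)
  Xa <- cbind(Xb, as.matrix(data[, add_cpgs, drop = FALSE]))
  rows_ok <- stats::complete.cases(Xa) & !is.na(data$time) & !is.na(evs)
  Xb <- Xb[rows_ok, , drop = FALSE]
  Xa <- Xa[rows_ok, , drop = FALSE]
  tt <- data$time[rows_ok]
  ss <- evs[rows_ok]

  fb <- fit_cox(tt, ss, Xb, ties = ties)
  fa <- fit_cox(tt, ss, Xa, ties = ties)
  cmp <- model_compare(fb, fa)

  cb <- harrell_c(tt, ss, fb$lp)
  ca <- harrell_c(tt, ss, fa$lp)
  ob <- optimism_corrected_c(tt, ss, Xb, B = B, seed = seed, ties = ties)
  oa <- optimism_corrected_c(tt, ss, Xa, B = B, seed = derive_seed(seed, 3),
    ties = ties)

  rb <- absolute_risk(fb, horizon)
  ra <- absolute_risk(fa, horizon)
  case <- ss == 1
  nr <- nri(categorize_risk(rb), categorize_risk(ra), case)
  id <- idi(rb, ra, case)
  cal_b <- calibration_gb(fb)
  cal_a <- calibration_gb(fa)
  vif <- collinearity(Xa, add_cpgs)

  metric <- function(metric, model, value) {
    data.frame(metric = metric, model = model, value = value)
  }
  out <- rbind(
    metric("n", "both", fb$n),
    metric("events", "both", fb$nevent),
    metric("minus2logl", "base", fb$minus2loglik),
    metric("minus2logl", "augmented", fa$minus2loglik),
    metric("df", "base", fb$df),
    metric("df", "augmented", fa$df),
    metric("aic", "base", cmp$aic[["base"]]),
    metric("aic", "augmented", cmp$aic[["augmented"]]),
    metric("lr_p", "augmented", cmp$p_value),
    metric("harrell_c", "base", cb$c),
    metric("harrell_c", "augmented", ca$c),
    metric("harrell_c_lower", "base", cb$lower),
    metric("harrell_c_upper", "base", cb$upper),
    metric("harrell_c_lower", "augmented", ca$lower),
    metric("harrell_c_upper", "augmented", ca$upper),
    metric("corrected_c", "base", ob$c_corrected),
    metric("corrected_c", "augmented", oa$c_corrected),
    metric("corrected_c_lower", "augmented", oa$lower),
    metric("corrected_c_upper", "augmented", oa$upper),
    metric("cases_up", "augmented", nr$cases$up),
    metric("cases_down", "augmented", nr$cases$down),
    metric("controls_up", "augmented", nr$controls$up),
    metric("controls_down", "augmented", nr$controls$down),
    metric("nri_pct", "augmented", nr$nri_pct),
    metric("nri_p", "augmented", nr$p_value),
    metric("idi_pct", "augmented", id$idi_pct),
    metric("idi_p", "augmented", id$p_value),
    metric("calibration_p", "base", cal_b$p_value),
    metric("calibration_p", "augmented", cal_a$p_value)
  )
  for (i in seq_len(nrow(vif))) {
    out <- rbind(
      out,
      metric(paste0("vif_", vif$term[i]), "augmented", vif$vif[i]),
      metric(paste0("tolerance_", vif$term[i]), "augmented", vif$tolerance[i])
    )
  }
  out
}
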