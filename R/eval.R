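# Incremental-value evaluation of fatal-CVD risk prediction models:
# absolute 10-year risks, Harrell's C with .632-bootstrap optimism
# correction, categorical NRI, IDI, Gronnesby-Borgan calibration (May-Hosmer
# grouping), AIC/likelihood-ratio comparison and collinearity diagnostics.

#' Absolute risk at a horizon from a Cox fit
#'
#' Per-participant predicted event probability at a horizon,
#' \eqn{1 - \exp(-\hat H_0(h) e^{\hat\eta_i})} using the Breslow baseline.
#' If the horizon exceeds the last observed event time the last value of the
#' baseline is used and the result is flagged as extrapolated.
#'
#' @param fit A converged `methrisk_cox` object.
#' @param horizon Horizon in years (default 10).
#' @param lp Optional linear predictor vector; defaults to the fit's own.
#' @return Numeric vector of probabilities in \[0, 1) with attribute
#'   `extrapolated`.
#' @export
absolute_risk <- function(fit, horizon = 10, lp = NULL) {
  stopifnot(inherits(fit, "methrisk_cox"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (is.null(lp)) lp <- fit$lp
  H0 <- cumhaz_at(fit$baseline, horizon)
  risk <- 1 - exp(-as.numeric(H0) * exp(lp))
  attr(risk, "extrapolated") <- horizon > max(fit$baseline$time)
  risk
}

#' Harrell's C-statistic for censored survival data
#'
#' Concordance over usable pairs: a pair is usable when the member with the
#' shorter follow-up had an event (including an event tied in time with a
#' censoring).  A pair is concordant when the higher predicted risk belongs
#' to the earlier event; ties in the risk score count 1/2.  The confidence
#' interval uses an asymptotic variance built from per-subject concordance
#' aggregates.
#'
#' @param time Follow-up times.
#' @param status Event indicators (0/1).
#' @param risk Predicted risk scores (higher = riskier); any monotone
#'   transform, e.g. the Cox linear predictor, gives the same C.
#' @return A list with `c` (the statistic), `se`, `lower`, `upper`,
#'   `concordant`, `tied`, `usable_pairs`.
#' @export
harrell_c <- function(time, status, risk) {
  keep <- !is.na(time) & !is.na(status) & !is.na(risk)
  time <- time[keep]
  status <- as.integer(status[keep])
  risk <- risk[keep]
  n <- length(time)
  ord <- order(time, -status)
  tt <- time[ord]
  dd <- status[ord]
  rr <- risk[ord]
  conc <- tied <- usable <- 0
  ci <- ui <- numeric(n)
  ev <- which(dd == 1)
  for (i in ev) {
    later <- which(tt > tt[i])
    same_c <- which(tt == tt[i] & dd == 0)
    js <- c(later, same_c)
    if (!length(js)) next
    cmp <- (rr[i] > rr[js]) + 0.5 * (rr[i] == rr[js])
    conc <- conc + sum(rr[i] > rr[js])
    tied <- tied + sum(rr[i] == rr[js])
    usable <- usable + length(js)
    ci[i] <- ci[i] + sum(cmp)
    ci[js] <- ci[js] + cmp
    ui[i] <- ui[i] + length(js)
    ui[js] <- ui[js] + 1
  }
  if (usable == 0) stop("no usable pairs", call. = FALSE)
  C <- (conc + 0.5 * tied) / usable
  se <- sqrt(sum((ci - C * ui)^2)) / usable
  list(
    c = C, se = se,
    lower = max(0, C - 1.96 * se), upper = min(1, C + 1.96 * se),
    concordant = conc, tied = tied, usable_pairs = usable
  )
}

#' Optimism-corrected Harrell's C via the .632 bootstrap
#'
#' For each bootstrap resample the Cox model is refit and its C-statistic
#' evaluated on the out-of-bag records; the corrected statistic is
#' \eqn{0.368\,C_{apparent} + 0.632\,\bar C_{oob}} with a percentile
#' confidence interval over the per-replicate corrected values.  Resamples
#' without events, with a failed fit, or with an empty out-of-bag set are
#' skipped and counted (an empty out-of-bag set is evaluated on the full
#' data instead, which reduces to the apparent C).
#'
#' @param time,status Survival outcome.
#' @param design Covariate matrix/data frame of the risk model.
#' @param B Number of bootstrap replicates (1000 in full analyses; reduce
#'   for quick checks).
#' @param seed Integer seed.
#' @param ties Tie handling passed to [fit_cox()].
#' @param resamples Optional list of index vectors overriding the bootstrap
#'   draw (for deterministic checks).
#' @return A list: `c_apparent`, `c_oob` (mean out-of-bag C), `c_corrected`,
#'   `lower`, `upper` (percentile CI), `optimism`
#'   (`c_apparent - c_corrected`), `replicates` (per-replicate corrected
#'   values), `n_skipped`.
#' @export
optimism_corrected_c <- function(time, status, design, B = 1000, seed = 1,
                                 ties = "breslow", resamples = NULL) {
  stopifnot(B >= 1)
  design <- as.matrix(as.data.frame(design))
  keep <- stats::complete.cases(design) & !is.na(time) & !is.na(status)
  design <- design[keep, , drop = FALSE]
  time <- time[keep]
  status <- as.integer(status[keep])
  n <- length(time)
  full <- fit_cox(time, status, design, ties = ties)
  c_app <- harrell_c(time, status, full$lp)$c

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  vals <- numeric(0)
  skipped <- 0L
  for (b in seq_len(B)) {
    idx <- if (!is.null(resamples)) resamples[[b]] else sample.int(n, n, replace = TRUE)
    if (sum(status[idx]) < 1L) {
      skipped <- skipped + 1L
      next
    }
    fit_b <- tryCatch(
      suppressWarnings(fit_cox(time[idx], status[idx],
        design[idx, , drop = FALSE],
        ties = ties
      )),
      error = function(e) NULL
    )
    if (is.null(fit_b) || !fit_b$converged) {
      skipped <- skipped + 1L
      next
    }
    oob <- setdiff(seq_len(n), unique(idx))
    eval_idx <- if (length(oob) && sum(status[oob]) > 0) oob else seq_len(n)
    lp_oob <- drop(design[eval_idx, , drop = FALSE] %*% fit_b$coef)
    c_b <- tryCatch(
      harrell_c(time[eval_idx], status[eval_idx], lp_oob)$c,
      error = function(e) NA_real_
    )
    if (is.na(c_b)) {
      skipped <- skipped + 1L
      next
    }
    vals <- c(vals, 0.368 * c_app + 0.632 * c_b)
  }
  if (!length(vals)) stop("all bootstrap replicates were skipped", call. = FALSE)
  c_oob <- (mean(vals) - 0.368 * c_app) / 0.632
  corrected <- 0.368 * c_app + 0.632 * c_oob
  qs <- stats::quantile(vals, c(0.025, 0.975), type = 7, names = FALSE)
  list(
    c_apparent = c_app, c_oob = c_oob, c_corrected = corrected,
    lower = qs[1], upper = qs[2], optimism = c_app - corrected,
    replicates = vals, n_skipped = skipped
  )
}

#' Assign recommended 10-year risk categories
#'
#' Categorizes predicted probabilities into the recommended fatal-CVD risk
#' bands 0-5%, >5-10%, >10-20%, >20%.  Boundaries belong to the lower
#' category (a predicted 5.0% is category 1).
#'
#' @param probabilities Predicted probabilities in \[0, 1\].
#' @param boundaries Strictly increasing internal boundaries.
#' @return Integer category per participant (1 .. length(boundaries) + 1).
#' @export
categorize_risk <- function(probabilities, boundaries = c(0.05, 0.10, 0.20)) {
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("boundaries must be strictly increasing", call. = FALSE)
  }
  out <- rowSums(outer(probabilities, boundaries, ">")) + 1L
  as.integer(out)
}

#' Categorical net reclassification improvement
#'
#' NRI between risk-category assignments from a base and an augmented model:
#' `[(cases up - cases down)/cases] - [(controls up - controls down)/
#' controls]`, expressed in percent, with the standard asymptotic z-test for
#' the categorical NRI.
#'
#' @param old_cat,new_cat Integer risk categories from the same boundary
#'   set.
#' @param case Logical: event (e.g. fatal CVD within the horizon) vs
#'   control.
#' @param n_categories Number of categories (for the movement tables).
#' @return A list: `nri_pct`, `p_value`, `z`, `cases`
#'   (`n`, `up`, `down`), `controls` (same), and `table_cases` /
#'   `table_controls` (old x new movement counts).
#' @export
nri <- function(old_cat, new_cat, case, n_categories = 4) {
  keep <- !is.na(old_cat) & !is.na(new_cat) & !is.na(case)
  old_cat <- old_cat[keep]
  new_cat <- new_cat[keep]
  case <- as.logical(case[keep])
  n_c <- sum(case)
  n_k <- sum(!case)
  if (n_c == 0 || n_k == 0) stop("need both cases and controls", call. = FALSE)
  lv <- seq_len(n_categories)
  tab <- function(sel) {
    table(
      old = factor(old_cat[sel], levels = lv),
      new = factor(new_cat[sel], levels = lv)
    )
  }
  up_c <- sum(new_cat > old_cat & case)
  dn_c <- sum(new_cat < old_cat & case)
  up_k <- sum(new_cat > old_cat & !case)
  dn_k <- sum(new_cat < old_cat & !case)
  nri_val <- (up_c - dn_c) / n_c - (up_k - dn_k) / n_k
  v <- (up_c + dn_c - (up_c - dn_c)^2 / n_c) / n_c^2 +
    (up_k + dn_k - (up_k - dn_k)^2 / n_k) / n_k^2
  z <- if (v > 0) nri_val / sqrt(v) else 0
  list(
    nri_pct = 100 * nri_val, z = z,
    p_value = if (v > 0) 2 * stats::pnorm(-abs(z)) else 1,
    cases = list(n = n_c, up = up_c, down = dn_c),
    controls = list(n = n_k, up = up_k, down = dn_k),
    table_cases = tab(case), table_controls = tab(!case)
  )
}

#' Integrated discrimination improvement
#'
#' IDI between two risk models: the mean improvement in predicted
#' probability among cases minus the mean improvement among controls,
#' expressed in percent, with the standard paired z-test over per-subject
#' differences.
#'
#' @param old_prob,new_prob Predicted probabilities from the base and
#'   augmented model (aligned).
#' @param case Logical case indicator.
#' @return A list: `idi_pct`, `z`, `p_value`.
#' @export
idi <- function(old_prob, new_prob, case) {
  keep <- !is.na(old_prob) & !is.na(new_prob) & !is.na(case)
  d <- (new_prob - old_prob)[keep]
  case <- as.logical(case[keep])
  n_c <- sum(case)
  n_k <- sum(!case)
  if (n_c == 0 || n_k == 0) stop("need both cases and controls", call. = FALSE)
  est <- mean(d[case]) - mean(d[!case])
  se <- sqrt(
    stats::var(d[case]) / n_c + stats::var(d[!case]) / n_k
  )
  z <- if (is.finite(se) && se > 0) est / se else 0
  list(
    idi_pct = 100 * est, z = z,
    p_value = if (is.finite(se) && se > 0) 2 * stats::pnorm(-abs(z)) else 1
  )
}

#' Gronnesby-Borgan calibration test (May-Hosmer grouping)
#'
#' Splits participants into groups by quintiles of the ranks of their
#' estimated risk, compares observed events with the model-expected events
#' (sums of estimated cumulative hazards, the martingale expectation) per
#' group with a normal approximation \eqn{z = (O - E)/\sqrt{E}}, and forms
#' the overall chi-square (groups - 1 df) as the score test of adding the
#' group indicators to the fitted model.
#'
#' @param fit A converged `methrisk_cox` object.
#' @param groups Number of risk groups (default 5).
#' @param group Optional explicit group assignment (overrides the quantile
#'   grouping; useful for diagnostics).
#' @return A list of class `methrisk_calibration`: `table` (per-group
#'   `n`, `observed`, `expected`, `z`, `p_value`), `statistic`, `df`,
#'   `p_value`.
#' @export
calibration_gb <- function(fit, groups = 5, group = NULL) {
  stopifnot(inherits(fit, "methrisk_cox"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  n <- fit$n
  expected_i <- exp(fit$lp) *
    as.numeric(cumhaz_at(fit$baseline, fit$time))
  if (is.null(group)) {
    if (n < 2 * groups) {
      stop("too few participants for ", groups, " groups", call. = FALSE)
    }
    rk <- rank(fit$lp, ties.method = "first")
    group <- as.integer(cut(rk, breaks = groups, labels = FALSE))
  } else {
    group <- as.integer(factor(group))
    groups <- max(group)
  }
  O <- as.vector(rowsum(fit$status, group))
  E <- as.vector(rowsum(expected_i, group))
  ng <- as.vector(table(factor(group, levels = seq_len(groups))))
  if (any(ng == 0)) stop("empty calibration group", call. = FALSE)
  z <- ifelse(E > 0, (O - E) / sqrt(E), 0)
  tab <- data.frame(
    group = seq_len(groups), n = ng, observed = O, expected = E,
    z = z, p_value = 2 * stats::pnorm(-abs(z))
  )
  # score test: group indicators (dropping the first) added to the fit
  Z <- sapply(2:groups, function(g) as.numeric(group == g))
  Z <- matrix(Z, ncol = groups - 1)
  Xa <- cbind(fit$design, Z)
  dv <- cox_derivs(fit$time, fit$status, Xa, c(fit$coef, numeric(groups - 1)),
    ties = fit$ties, what = "all"
  )
  p <- ncol(fit$design)
  zi <- (p + 1):(p + groups - 1)
  Uz <- dv$score[zi]
  Izz <- dv$info[zi, zi, drop = FALSE]
  Izx <- dv$info[zi, seq_len(p), drop = FALSE]
  Ixx <- dv$info[seq_len(p), seq_len(p), drop = FALSE]
  effinfo <- Izz - Izx %*% psolve(Ixx) %*% t(Izx)
  stat <- drop(t(Uz) %*% psolve(effinfo, Uz))
  structure(list(
    table = tab, statistic = stat, df = groups - 1L,
    p_value = stats::pchisq(stat, df = groups - 1L, lower.tail = FALSE)
  ), class = "methrisk_calibration")
}

#' @export
print.methrisk_calibration <- function(x, digits = 3, ...) {
  print(transform(x$table,
    expected = round(expected, digits),
    z = round(z, digits), p_value = round(p_value, digits)
  ))
  cat(
    "overall chi-square =", round(x$statistic, digits), "on", x$df,
    "df, p =", format.pval(x$p_value, digits = digits), "\n"
  )
  invisible(x)
}

#' Akaike information criterion from a deviance and coefficient count
#'
#' `AIC = -2 log L + 2 k` for a Cox model with `k` estimated coefficients.
#'
#' @param minus2loglik `-2` times the maximized log (partial) likelihood.
#' @param n_coef Number of estimated coefficients.
#' @return The AIC.
#' @export
aic_value <- function(minus2loglik, n_coef) {
  minus2loglik + 2 * n_coef
}

#' Compare nested Cox models by AIC and likelihood ratio
#'
#' `AIC = -2 log L + 2 (number of coefficients)`; the likelihood-ratio
#' statistic is the difference in `-2 log L` on the difference in
#' coefficient counts.  The models must be fitted on identical rows and be
#' nested (the base model's covariates a subset of the augmented model's).
#'
#' @param base_fit,augmented_fit `methrisk_cox` objects.
#' @return A list: `aic` (named pair), `minus2loglik` (named pair),
#'   `df` (named pair), `lr`, `lr_df`, `p_value`.
#' @export
model_compare <- function(base_fit, augmented_fit) {
  stopifnot(inherits(base_fit, "methrisk_cox"), inherits(augmented_fit, "methrisk_cox"))
  if (base_fit$n != augmented_fit$n || base_fit$nevent != augmented_fit$nevent) {
    stop("models were fitted on different rows", call. = FALSE)
  }
  if (!all(names(base_fit$coef) %in% names(augmented_fit$coef)) ||
    augmented_fit$df < base_fit$df) {
    stop("models are not nested", call. = FALSE)
  }
  lr <- base_fit$minus2loglik - augmented_fit$minus2loglik
  lr_df <- augmented_fit$df - base_fit$df
  list(
    aic = c(
      base = aic_value(base_fit$minus2loglik, base_fit$df),
      augmented = aic_value(augmented_fit$minus2loglik, augmented_fit$df)
    ),
    minus2loglik = c(
      base = base_fit$minus2loglik,
      augmented = augmented_fit$minus2loglik
    ),
    df = c(base = base_fit$df, augmented = augmented_fit$df),
    lr = lr, lr_df = lr_df,
    p_value = if (lr_df == 0) 1 else {
      stats::pchisq(max(lr, 0), df = lr_df, lower.tail = FALSE)
    }
  )
}

#' Variance inflation factors for added covariates
#'
#' For each added column, the VIF is `1 / (1 - R^2)` from regressing that
#' column on all other design columns (with intercept); the tolerance is
#' `1 - R^2`.
#'
#' @param design Numeric matrix/data frame holding all model covariates,
#'   including the added ones.
#' @param added Names (or indices) of the added columns to diagnose.
#' @return Data frame `term`, `vif`, `tolerance`.
#' @export
collinearity <- function(design, added) {
  X <- as.matrix(as.data.frame(design))
  if (is.numeric(added)) added <- colnames(X)[added]
  stopifnot(all(added %in% colnames(X)))
  X <- X[stats::complete.cases(X), , drop = FALSE]
  out <- lapply(added, function(cn) {
    y <- X[, cn]
    Z <- cbind(1, X[, setdiff(colnames(X), cn), drop = FALSE])
    fit <- stats::lm.fit(Z, y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    if (r2 >= 1 - 1e-12) stop("perfect collinearity at '", cn, "'", call. = FALSE)
    data.frame(term = cn, vif = 1 / (1 - r2), tolerance = 1 - r2)
  })
  do.call(rbind, out)
}
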