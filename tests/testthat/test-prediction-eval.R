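# Risk-prediction evaluation: absolute risks, concordance, optimism
# correction, reclassification, calibration and model comparison.

test_that("absolute risk matches the hand-computed baseline hazard", {
  tt <- c(1, 2, 3, 4, 5)
  ss <- c(1, 0, 1, 1, 0)
  x <- c(0.5, -0.5, 1, 0, -1)
  f <- fit_cox(tt, ss, cbind(x = x))
  b <- exp(f$coef[["x"]] * x)
  H0_4 <- 1 / sum(b) + 1 / sum(b[3:5]) + 1 / sum(b[4:5])
  r <- absolute_risk(f, horizon = 4)
  expect_equal(unname(r), 1 - exp(-H0_4 * b),
    tolerance = 1e-10, ignore_attr = TRUE
  )
  expect_false(attr(r, "extrapolated"))

  # risk at t = 0 is 0; beyond follow-up uses the last value and is flagged
  expect_equal(unname(absolute_risk(f, horizon = 0)), rep(0, 5),
    ignore_attr = TRUE
  )
  r9 <- absolute_risk(f, horizon = 9)
  expect_true(attr(r9, "extrapolated"))

  # monotone in the linear predictor
  expect_equal(order(f$lp), order(unname(r)))
})

test_that("uniform linear predictor gives the plain baseline risk", {
  tt <- c(2, 3, 5, 7, 8, 9)
  ss <- c(1, 0, 1, 1, 0, 1)
  f <- fit_cox(tt, ss, cbind(z = rep(0, 6)))
  r <- absolute_risk(f, horizon = 6)
  H0 <- breslow_baseline(f)
  expect_equal(unname(r), rep(1 - exp(-H0$cumhaz[2]), 6),
    ignore_attr = TRUE
  )
})

test_that("Harrell's C equals exhaustive pair enumeration", {
  set.seed(22)
  for (k in 1:3) {
    n <- c(20, 35, 50)[k]
    tt <- sample(1:15, n, replace = TRUE)
    ss <- rbinom(n, 1, 0.6)
    rr <- round(rnorm(n), 1) # induces risk ties
    if (sum(ss) == 0) ss[1] <- 1
    hc <- harrell_c(tt, ss, rr)
    expect_equal(hc$c, oracle_concordance(tt, ss, rr))
    expect_true(hc$lower <= hc$c && hc$c <= hc$upper)
  }
  # perfectly ordered, no censoring
  tt <- 1:10
  expect_equal(harrell_c(tt, rep(1, 10), 10:1)$c, 1)
  # constant risk score
  expect_equal(harrell_c(tt, rep(1, 10), rep(2, 10))$c, 0.5)
  expect_error(harrell_c(c(1, 2), c(0, 1), c(1, 2)), "no usable pairs")
})

test_that("risk categories use lower-closed boundaries", {
  expect_equal(categorize_risk(c(0.05, 0.0501, 0.25)), c(1L, 2L, 4L))
  expect_equal(categorize_risk(c(0.01, 0.07, 0.15, 0.30)), 1:4)
  expect_equal(categorize_risk(c(0, 0.10, 0.20)), c(1L, 2L, 3L))
  expect_error(categorize_risk(c(-0.1)), "\\[0, 1\\]")
  expect_error(categorize_risk(0.5, boundaries = c(0.2, 0.1)), "increasing")
})

test_that("NRI reproduces the printed formula on direct arithmetic", {
  # cases 10 up / 5 down of 50; controls 20 up / 40 down of 200 -> 20.0%
  old_cat <- c(rep(2, 50), rep(2, 200))
  new_cat <- c(
    rep(3, 10), rep(1, 5), rep(2, 35),
    rep(3, 20), rep(1, 40), rep(2, 140)
  )
  case <- c(rep(TRUE, 50), rep(FALSE, 200))
  out <- nri(old_cat, new_cat, case)
  expect_equal(out$nri_pct, 20.0, tolerance = 1e-12)
  expect_equal(out$cases$up, 10)
  expect_equal(out$controls$down, 40)
  expect_equal(sum(out$table_cases), 50)

  # no movement -> 0
  out0 <- nri(old_cat, old_cat, case)
  expect_equal(out0$nri_pct, 0)
  expect_error(nri(old_cat, new_cat, rep(FALSE, 250)), "cases and controls")
})

test_that("IDI matches hand arithmetic and is zero for identical models", {
  old_p <- c(0.20, 0.30, 0.10, 0.20, 0.15, 0.25)
  new_p <- c(0.35, 0.40, 0.05, 0.15, 0.20, 0.30)
  case <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  # d = (.15, .10, -.05, -.05, .05, .05): cases mean .125, controls mean 0
  out <- idi(old_p, new_p, case)
  expect_equal(out$idi_pct, 12.5, tolerance = 1e-12)
  expect_equal(idi(old_p, old_p, case)$idi_pct, 0)
})

test_that("calibration test is exact on a constructed observed-equals-expected toy", {
  tt <- rep(1, 6)
  ss <- c(1, 1, 1, 0, 0, 0)
  x <- c(1, -1, 0, 1, -1, 0)
  f <- fit_cox(tt, ss, cbind(x = x))
  expect_equal(unname(f$coef), 0, tolerance = 1e-10)
  cal <- calibration_gb(f, group = c(1, 2, 3, 1, 2, 3))
  expect_equal(cal$table$observed, cal$table$expected, tolerance = 1e-10)
  expect_equal(cal$statistic, 0, tolerance = 1e-8)
  expect_equal(cal$p_value, 1)
  expect_true(all(cal$table$p_value == 1))
})

test_that("calibration quintile grouping runs on cohort-like data", {
  d <- cohort_frame(quick_cohort(n = 600, seed = 23))
  f <- fit_cox(d$time, d$event, build_design(d, c("age", "sex")))
  cal <- calibration_gb(f)
  expect_equal(nrow(cal$table), 5)
  expect_equal(sum(cal$table$observed), f$nevent)
  expect_equal(sum(cal$table$expected), f$nevent, tolerance = 1e-6)
  expect_true(cal$p_value >= 0 && cal$p_value <= 1)
  expect_error(calibration_gb(f, groups = 1000), "too few")
})

test_that("model comparison applies the AIC and LR identities", {
  d <- cohort_frame(quick_cohort(n = 500, seed = 24))
  Xb <- build_design(d, c("age", "sex"))
  Xa <- cbind(Xb, cg = d$cg05575921)
  fb <- fit_cox(d$time, d$event, Xb)
  fa <- fit_cox(d$time, d$event, Xa)
  cmp <- model_compare(fb, fa)
  expect_equal(cmp$aic[["base"]], fb$minus2loglik + 2 * 2)
  expect_equal(cmp$aic[["augmented"]], fa$minus2loglik + 2 * 3)
  expect_equal(cmp$lr, fb$minus2loglik - fa$minus2loglik)
  expect_equal(cmp$lr_df, 1)
  expect_gte(cmp$lr, 0)

  # a model against itself: zero likelihood ratio on zero df
  cmp0 <- model_compare(fb, fb)
  expect_equal(cmp0$lr, 0)
  expect_equal(cmp0$p_value, 1)

  expect_error(model_compare(fa, fb), "not nested")
  f_sub <- fit_cox(d$time[1:300], d$event[1:300], Xb[1:300, ])
  expect_error(model_compare(f_sub, fa), "different rows")
})

test_that("VIF follows the closed form and flags perfect collinearity", {
  set.seed(25)
  n <- 400
  # construct two columns with empirical correlation exactly 0.7
  a <- as.vector(scale(rnorm(n)))
  z2 <- as.vector(scale(resid(lm(rnorm(n) ~ a))))
  b <- 0.7 * a + sqrt(1 - 0.49) * z2
  out <- collinearity(cbind(a = a, b = b), c("a", "b"))
  expect_equal(out$vif, rep(1 / (1 - 0.49), 2), tolerance = 1e-10)
  expect_equal(out$tolerance, 1 / out$vif, tolerance = 1e-12)

  # orthogonal columns
  out2 <- collinearity(cbind(a = a, b = z2), "b")
  expect_equal(out2$vif, 1, tolerance = 1e-10)
  expect_error(collinearity(cbind(a = a, b = a), "b"), "perfect collinearity")
})

test_that("adding the two CpGs to the risk model yields modest collinearity", {
  # with smoking effects switched off, the collinearity between the two
  # score CpGs reflects only their residual correlation (0.56)
  prof <- default_cpg_profiles()
  prof$current_offset[] <- 0
  prof$former_offset[] <- 0
  d <- cohort_frame(generate_cohort(
    sim_config(n_participants = 1000, seed = 4, cpg_profiles = prof)
  ))
  d$current_smoker <- as.numeric(d$smoking_status == "current")
  X <- cbind(
    build_design(d, c(
      "age", "sex", "systolic_bp", "current_smoker",
      "total_cholesterol", "batch"
    )),
    as.matrix(d[, methrisk_score_cpgs])
  )
  v <- collinearity(X, methrisk_score_cpgs)
  expect_true(all(v$vif > 1.16 & v$vif < 1.76))
})

test_that("a forced identity resample makes the corrected C equal the apparent C", {
  d <- cohort_frame(quick_cohort(n = 250, seed = 26))
  X <- build_design(d, c("age", "sex"))
  o <- optimism_corrected_c(d$time, d$event, X,
    B = 1, seed = 1,
    resamples = list(seq_len(nrow(d)))
  )
  expect_equal(o$c_corrected, o$c_apparent, tolerance = 1e-12)
  expect_equal(o$optimism, 0, tolerance = 1e-12)
})

test_that("the optimism correction shrinks an overfit model's concordance", {
  set.seed(27)
  n <- 150
  X <- matrix(rnorm(n * 8), n, 8) # pure noise predictors
  colnames(X) <- paste0("z", 1:8)
  sim <- sim_surv(n, rep(0, 8), X, seed = 27)
  o <- optimism_corrected_c(sim$time, sim$status, X, B = 60, seed = 2)
  expect_lt(o$c_corrected, o$c_apparent)
  expect_lt(abs(o$c_corrected - 0.5), abs(o$c_apparent - 0.5))
})

test_that("the corrected C sits below the apparent C by a plausible margin on cohort data", {
  d <- cohort_frame(quick_cohort(n = 1000, seed = 15))
  d$current_smoker <- as.numeric(d$smoking_status == "current")
  ev <- as.integer(d$event == 1 & !is.na(d$cause) & d$cause == "cvd")
  X <- cbind(
    build_design(d, c(
      "age", "sex", "systolic_bp", "current_smoker",
      "total_cholesterol", "batch"
    )),
    as.matrix(d[, methrisk_score_cpgs])
  )
  ok <- complete.cases(X)
  o <- optimism_corrected_c(d$time[ok], ev[ok], X[ok, ], B = 100, seed = 5)
  expect_gt(o$optimism, 0.005)
  expect_lt(o$optimism, 0.08)
})
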