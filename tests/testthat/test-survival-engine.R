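# Kaplan-Meier, log-rank and the Cox partial-likelihood engine.

test_that("Kaplan-Meier matches the hand product-limit computation", {
  # events at 1, 3, 5, 6; censorings at 2, 4
  tt <- c(1, 2, 3, 4, 5, 6)
  ss <- c(1, 0, 1, 0, 1, 1)
  km <- kaplan_meier(tt, ss)
  expect_equal(km$survival[km$time == 1], 5 / 6)
  expect_equal(km$survival[km$time == 3], 5 / 6 * 3 / 4)
  expect_equal(km$survival[km$time == 5], 5 / 6 * 3 / 4 * 1 / 2)
  expect_equal(km$survival[km$time == 6], 0)
  # survival only changes at event times, starts below 1 only after an event
  expect_equal(km$survival[km$time == 2], km$survival[km$time == 1])
  expect_true(all(diff(km$survival) <= 0))
  # Greenwood variance at t = 1: S^2 * d/(n(n-d))
  expect_equal(
    km$std_err[km$time == 1], (5 / 6) * sqrt(1 / (6 * 5))
  )
})

test_that("Kaplan-Meier reduces to 1 - ECDF without censoring and to 1 without events", {
  tt <- c(3, 1, 4, 2, 5)
  km <- kaplan_meier(tt, rep(1, 5))
  ec <- 1 - ecdf(tt)(km$time)
  expect_equal(km$survival, ec)
  km0 <- kaplan_meier(tt, rep(0, 5))
  expect_true(all(km0$survival == 1))
})

test_that("log-rank statistic matches the hypergeometric hand computation", {
  # two-group 10-subject toy
  tt <- c(1, 2, 3, 4, 5, 1.5, 2.5, 3.5, 4.5, 5.5)
  ss <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0)
  gg <- rep(c("a", "b"), each = 5)
  lr <- logrank(tt, ss, gg)
  # independent implementation from the O-E / V definition
  ut <- sort(unique(tt[ss == 1]))
  o <- e <- v <- 0
  for (t in ut) {
    n1 <- sum(tt >= t & gg == "a")
    n <- sum(tt >= t)
    d <- sum(tt == t & ss == 1)
    d1 <- sum(tt == t & ss == 1 & gg == "a")
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(lr$statistic, (o - e)^2 / v, tolerance = 1e-10)
  expect_equal(lr$df, 1)

  # identical groups -> statistic 0
  lr0 <- logrank(c(tt, tt), c(ss, ss), rep(c("a", "b"), each = 10))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)
  expect_error(logrank(tt, rep(0, 10), gg), "no events")
})

test_that("log-rank asymptotic p is close to the permutation p on a small toy", {
  set.seed(8)
  tt <- c(2, 4, 5, 7, 8, 10, 3, 6, 9, 11, 12, 14)
  ss <- c(1, 1, 0, 1, 1, 0, 1, 0, 1, 1, 0, 1)
  gg <- rep(c("a", "b"), each = 6)
  lr <- logrank(tt, ss, gg)
  perm <- replicate(4000, logrank(tt, ss, sample(gg))$statistic)
  p_perm <- mean(perm >= lr$statistic - 1e-12)
  expect_lt(abs(lr$p_value - p_perm), 0.04)
})

test_that("Cox coefficient matches grid-search maximization of the partial likelihood", {
  tt <- c(2, 4, 5, 7, 9, 11, 12, 14)
  ss <- c(1, 1, 0, 1, 0, 1, 1, 1)
  x <- c(1, 0, 1, 0, 1, 0, 1, 0)
  fit <- fit_cox(tt, ss, cbind(x = x))
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, function(b) oracle_cox_loglik_1d(tt, ss, x, b), numeric(1))
  expect_equal(unname(fit$coef), grid[which.max(ll)], tolerance = 1e-4)
  expect_lte(fit$minus2loglik, -2 * fit$loglik[["null"]])
})

test_that("all-zero design yields zero coefficients and the null deviance", {
  tt <- c(2, 4, 5, 7, 9, 11)
  ss <- c(1, 1, 0, 1, 0, 1)
  fit <- fit_cox(tt, ss, cbind(z = rep(0, 6)))
  expect_equal(unname(fit$coef), 0)
  expect_equal(fit$minus2loglik, -2 * fit$loglik[["null"]])
})

test_that("Cox engine agrees with the survival package on random data", {
  skip_if_not_installed("survival")
  set.seed(14)
  n <- 250
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4), c = runif(n))
  tt <- rexp(n, exp(0.4 * X[, 1] - 0.6 * X[, 2]))
  ss <- as.integer(tt < 1.5)
  tt <- pmin(tt, 1.5)
  for (m in c("breslow", "efron")) {
    f <- fit_cox(tt, ss, X, ties = m)
    cf <- survival::coxph(survival::Surv(tt, ss) ~ X, ties = m)
    expect_equal(unname(f$coef), unname(coef(cf)), tolerance = 1e-7)
    expect_equal(unname(f$var), unname(vcov(cf)), tolerance = 1e-7)
    expect_equal(f$minus2loglik, -2 * cf$loglik[2], tolerance = 1e-7)
  }
  # heavy ties
  t2 <- ceiling(tt * 4)
  for (m in c("breslow", "efron")) {
    f <- fit_cox(t2, ss, X, ties = m)
    cf <- survival::coxph(survival::Surv(t2, ss) ~ X, ties = m)
    expect_equal(unname(f$coef), unname(coef(cf)), tolerance = 1e-7)
  }
})

test_that("Breslow and Efron agree exactly without ties", {
  set.seed(15)
  n <- 120
  X <- cbind(a = rnorm(n))
  tt <- rexp(n, exp(0.5 * X[, 1]))
  ss <- rbinom(n, 1, 0.7)
  fb <- fit_cox(tt, ss, X, ties = "breslow")
  fe <- fit_cox(tt, ss, X, ties = "efron")
  expect_equal(fb$coef, fe$coef, tolerance = 1e-10)
  expect_equal(fb$minus2loglik, fe$minus2loglik, tolerance = 1e-10)
})

test_that("duplicating the cohort leaves the coefficient unchanged and halves the variance", {
  set.seed(16)
  n <- 100
  X <- cbind(a = rnorm(n))
  tt <- rexp(n, exp(0.5 * X[, 1]))
  ss <- rbinom(n, 1, 0.8)
  f1 <- fit_cox(tt, ss, X, ties = "breslow")
  f2 <- fit_cox(c(tt, tt), c(ss, ss), rbind(X, X), ties = "breslow")
  expect_equal(f1$coef, f2$coef, tolerance = 1e-6)
  expect_equal(unname(f2$var * 2), unname(f1$var), tolerance = 1e-6)
})

test_that("Cox fit recovers a known log hazard ratio", {
  set.seed(17)
  n <- 10000
  X <- cbind(x = rnorm(n))
  sim <- sim_surv(n, 0.7, X, seed = 17)
  f <- fit_cox(sim$time, sim$status, X)
  expect_equal(unname(f$coef), 0.7, tolerance = 0.05)
})

test_that("monotone likelihood is flagged as non-convergence", {
  # perfect separation: the covariate orders the events perfectly
  tt <- c(1, 2, 3, 4, 10, 11, 12, 13)
  ss <- rep(1, 8)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_warning(f <- fit_cox(tt, ss, cbind(x = x)), "monotone")
  expect_false(f$converged)
})

test_that("Breslow baseline matches the hand computation and Nelson-Aalen", {
  # 5-subject toy with a covariate
  tt <- c(1, 2, 3, 4, 5)
  ss <- c(1, 0, 1, 1, 0)
  x <- c(0.5, -0.5, 1, 0, -1)
  f <- fit_cox(tt, ss, cbind(x = x))
  b <- exp(f$coef[["x"]] * x)
  h1 <- 1 / sum(b)
  h3 <- 1 / sum(b[3:5])
  h4 <- 1 / sum(b[4:5])
  bl <- breslow_baseline(f)
  expect_equal(bl$cumhaz, cumsum(c(h1, h3, h4)), tolerance = 1e-10)

  # with all coefficients zero the baseline is the Nelson-Aalen estimator
  f0 <- fit_cox(tt, ss, cbind(z = rep(0, 5)))
  na_est <- cumsum(c(1 / 5, 1 / 3, 1 / 2))
  expect_equal(breslow_baseline(f0)$cumhaz, na_est, tolerance = 1e-12)
})

test_that("per-SD hazard ratios are scale invariant", {
  set.seed(18)
  n <- 400
  X <- cbind(m = rnorm(n, 0.7, 0.1), a = rnorm(n))
  sim <- sim_surv(n, c(-3, 0.3), X, seed = 18)
  f1 <- fit_cox(sim$time, sim$status, X)
  h1 <- per_sd_hr(f1, "m")
  X2 <- X
  X2[, "m"] <- X2[, "m"] * 2
  f2 <- fit_cox(sim$time, sim$status, X2)
  h2 <- per_sd_hr(f2, "m")
  expect_equal(h1$hr, h2$hr, tolerance = 1e-6)
  expect_equal(h1$hr, exp(-f1$coef[["m"]] * sd(X[, "m"])))
  expect_true(h1$lower <= h1$hr && h1$hr <= h1$upper)
  Xc <- X
  Xc[, "a"] <- 1 # constant -> rank deficient with implicit intercept-free Cox
  expect_error(per_sd_hr(f1, "absent"), "not in the fitted design")
})

test_that("martingale residuals sum to zero", {
  d <- cohort_frame(quick_cohort(n = 500, seed = 20))
  X <- build_design(d, c("age", "sex"))
  f <- fit_cox(d$time, d$event, X)
  expect_lt(abs(sum(martingale_residuals(f))), 1e-8)
})
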