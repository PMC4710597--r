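# Independent oracles and small fixtures shared across tests.  Oracles are
# deliberately written from the definitions, not by calling package code.

# Restricted cubic spline: direct evaluation of the truncated-power formula.
oracle_rcs <- function(x, knots) {
  k <- length(knots)
  tk <- knots[k]
  tk1 <- knots[k - 1]
  t1 <- knots[1]
  cube <- function(u) ifelse(u > 0, u^3, 0)
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  for (j in 1:(k - 2)) {
    out[, j + 1] <- (cube(x - knots[j]) -
      cube(x - tk1) * (tk - knots[j]) / (tk - tk1) +
      cube(x - tk) * (tk1 - knots[j]) / (tk - tk1)) / (tk - t1)^2
  }
  out
}

# Harrell's C by exhaustive pair enumeration.
oracle_concordance <- function(time, status, risk) {
  n <- length(time)
  conc <- usable <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ok <- (time[i] < time[j] && status[i] == 1) ||
        (time[i] == time[j] && status[i] == 1 && status[j] == 0)
      if (ok) {
        usable <- usable + 1
        conc <- conc + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
      }
    }
  }
  conc / usable
}

# Cox log partial likelihood (Breslow, from the definition) for a single
# covariate, usable for grid-search maximization.
oracle_cox_loglik_1d <- function(time, status, x, beta) {
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Small Weibull proportional-hazards survival simulator (independent of the
# cohort generator) for recovery and null checks.
sim_surv <- function(n, beta, X, shape = 1.3, scale = 3, cens = 4, seed = 1) {
  set.seed(seed)
  lp <- drop(X %*% beta)
  tt <- scale * (-log(runif(n)) * exp(-lp))^(1 / shape)
  cc <- runif(n, cens / 2, cens)
  list(time = pmin(tt, cc), status = as.integer(tt <= cc))
}

# default cohort scaled for quick tests
quick_cohort <- function(n = 800, seed = 1, ...) {
  generate_cohort(sim_config(n_participants = n, seed = seed, ...))
}

# merged analysis frame
cohort_frame <- function(cc) {
  d <- merge(merge(cc$cohort, cc$methylation, by = "participant_id"),
    cc$survival,
    by = "participant_id"
  )
  d[order(d$participant_id), ]
}
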