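# Product-limit survival estimation and the log-rank test.

#' Kaplan-Meier product-limit survival curves
#'
#' Computes the Kaplan-Meier estimate of the survivor function, with the
#' Greenwood variance, for the whole sample or separately per group.
#'
#' @param time Follow-up times (positive).
#' @param status Event indicators (0/1).
#' @param group Optional grouping vector (factor or character).
#' @return A data frame of class `methrisk_km` with one row per distinct
#'   event or censoring time per group: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, `std_err` (Greenwood SE of the survival
#'   estimate).  The estimate starts at 1 and changes only at event times.
#' @export
kaplan_meier <- function(time, status, group = NULL) {
  if (is.null(group)) group <- rep("all", length(time))
  keep <- !is.na(time) & !is.na(status) & !is.na(group)
  time <- time[keep]
  status <- as.integer(status[keep])
  group <- as.character(group[keep])
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  out <- lapply(sort(unique(group)), function(g) {
    tg <- time[group == g]
    dg <- status[group == g]
    if (length(tg) == 0L) stop("empty group '", g, "'", call. = FALSE)
    ut <- sort(unique(tg))
    n_risk <- vapply(ut, function(t) sum(tg >= t), numeric(1))
    n_event <- vapply(ut, function(t) sum(tg == t & dg == 1), numeric(1))
    n_censor <- vapply(ut, function(t) sum(tg == t & dg == 0), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    gw <- cumsum(ifelse(n_event > 0, n_event / (n_risk * (n_risk - n_event)), 0))
    data.frame(
      group = g, time = ut, n_risk = n_risk, n_event = n_event,
      n_censor = n_censor, survival = surv,
      std_err = surv * sqrt(gw)
    )
  })
  structure(do.call(rbind, out), class = c("methrisk_km", "data.frame"))
}

#' Log-rank test for equality of survival curves
#'
#' The standard (unweighted) log-rank test: at every distinct event time the
#' observed events per group are compared with their hypergeometric
#' expectation, and the summed differences are combined through the
#' hypergeometric covariance matrix into a chi-square statistic with
#' (groups - 1) degrees of freedom.
#'
#' @inheritParams kaplan_meier
#' @return A list with `statistic`, `df`, `p_value`, and the per-group
#'   `observed` and `expected` event counts.
#' @export
logrank <- function(time, status, group) {
  keep <- !is.na(time) & !is.na(status) & !is.na(group)
  time <- time[keep]
  status <- as.integer(status[keep])
  group <- factor(group[keep])
  g <- nlevels(group)
  if (g < 2L) stop("log-rank test needs at least two groups", call. = FALSE)
  if (sum(status) == 0L) stop("no events", call. = FALSE)
  ut <- sort(unique(time[status == 1]))
  O <- E <- numeric(g)
  V <- matrix(0, g, g)
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    nj <- vapply(levels(group), function(l) sum(at_risk & group == l), numeric(1))
    dj <- vapply(levels(group), function(l) {
      sum(time == t & status == 1 & group == l)
    }, numeric(1))
    d <- sum(dj)
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      f <- d * (n - d) / (n - 1)
      V <- V + f * (diag(nj / n, g) - tcrossprod(nj / n))
    }
  }
  u <- (O - E)[-g]
  Vm <- V[-g, -g, drop = FALSE]
  stat <- drop(t(u) %*% psolve(Vm, u))
  names(O) <- names(E) <- levels(group)
  list(
    statistic = stat, df = g - 1L,
    p_value = stats::pchisq(stat, df = g - 1L, lower.tail = FALSE),
    observed = O, expected = E
  )
}
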