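# Proportional-hazards diagnostics based on martingale residuals.
#
# The primary check follows the cumulative score-process approach: for each
# covariate the observed process is the cumulative sum of its Schoenfeld
# residuals over event times (which by construction returns to zero at the
# last event, since the score vanishes at the MLE).  Its null distribution is
# approximated by multiplier resampling of the per-event residual increments
# with the correction term that accounts for estimation of the coefficients,
# and the test compares supremum statistics.  A cheap alternative correlates
# scaled Schoenfeld residuals with event-time rank.

#' Proportional-hazards check from martingale-based residual processes
#'
#' For every covariate in a fitted Cox model, tests the proportional-hazards
#' assumption.  `method = "supremum"` computes the observed cumulative
#' Schoenfeld-residual (score) process over follow-up time and a supremum
#' statistic, with the p-value obtained by simulating the process under the
#' null via standard-normal multipliers on the per-event increments
#' (including the correction for the estimated coefficients).
#' `method = "schoenfeld"` instead correlates scaled Schoenfeld residuals
#' with the rank of event time (a t-test), which is fast but only sensitive
#' to monotone trends.
#'
#' @param fit A converged `methrisk_cox` object.
#' @param nsim Number of simulated score processes for the supremum test.
#' @param seed Integer seed for the multiplier draws.
#' @param method `"supremum"` (default) or `"schoenfeld"`.
#' @return A data frame with one row per covariate: `term`, `statistic`,
#'   `p_value`, `method`.
#' @export
martingale_ph_check <- function(fit, nsim = 1000, seed = 1,
                                method = c("supremum", "schoenfeld")) {
  stopifnot(inherits(fit, "methrisk_cox"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  method <- match.arg(method)
  time <- fit$time
  status <- fit$status
  X <- fit$design
  p <- ncol(X)

  ord <- order(time)
  tt <- time[ord]
  dd <- status[ord]
  Xs <- X[ord, , drop = FALSE]
  eta <- drop(Xs %*% fit$coef)
  w <- exp(eta - max(eta))
  cs0 <- rev(cumsum(rev(w)))
  wX <- Xs * w
  cs1 <- matrix(apply(wX, 2, function(col) rev(cumsum(rev(col)))), nrow = length(tt))
  newblk <- !duplicated(tt)
  blk <- cumsum(newblk)
  first <- which(newblk)

  ev <- which(dd == 1)
  ne <- length(ev)
  # individual Schoenfeld residuals at each event (Breslow risk-set mean)
  i1 <- first[blk[ev]]
  xbar <- cs1[i1, , drop = FALSE] / cs0[i1]
  s <- Xs[ev, , drop = FALSE] - xbar # ne x p, ordered by event time

  if (method == "schoenfeld") {
    V <- fit$info / ne
    sstar <- s %*% psolve(V) / ne # scaled residual variation
    tr <- rank(tt[ev], ties.method = "average")
    out <- lapply(seq_len(p), function(j) {
      r <- suppressWarnings(stats::cor(sstar[, j], tr))
      if (!is.finite(r)) r <- 0
      stat <- r * sqrt((ne - 2) / max(1 - r^2, 1e-12))
      data.frame(
        term = colnames(X)[j], statistic = stat,
        p_value = 2 * stats::pt(-abs(stat), df = ne - 2),
        method = "schoenfeld"
      )
    })
    return(do.call(rbind, out))
  }

  # observed process and cumulative information over event times
  U <- apply(s, 2, cumsum)
  U <- matrix(U, nrow = ne)
  # per-event information increments (Breslow)
  cumV <- array(0, dim = c(p, p, ne))
  acc <- matrix(0, p, p)
  iu <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  wXX <- wX[, iu[, 1], drop = FALSE] * Xs[, iu[, 2], drop = FALSE]
  cs2 <- matrix(apply(wXX, 2, function(col) rev(cumsum(rev(col)))), nrow = length(tt))
  for (k in seq_len(ne)) {
    v2 <- cs2[i1[k], ] / cs0[i1[k]]
    Vk <- matrix(0, p, p)
    Vk[cbind(iu[, 1], iu[, 2])] <- v2
    Vk[cbind(iu[, 2], iu[, 1])] <- v2
    acc <- acc + (Vk - tcrossprod(xbar[k, ]))
    cumV[, , k] <- acc
  }
  Itau <- cumV[, , ne]
  Iinv <- psolve(Itau)

  obs_sup <- apply(abs(U), 2, max)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  G <- matrix(stats::rnorm(nsim * ne), nsim, ne)
  Tg <- G %*% s # nsim x p, total resampled score
  exceed <- numeric(p)
  # A[k, ] = row j of cumV[,,k] %*% Iinv, per covariate
  for (j in seq_len(p)) {
    cum_j <- t(apply(G * rep(s[, j], each = nsim), 1, cumsum)) # nsim x ne
    if (ne == 1L) cum_j <- t(cum_j)
    vap <- vapply(
      seq_len(ne),
      function(k) drop(cumV[j, , k] %*% Iinv), numeric(p)
    )
    Aj <- if (p == 1L) matrix(vap, ne, 1L) else t(vap) # ne x p
    corr <- Aj %*% t(Tg) # ne x nsim
    Wstar <- t(cum_j) - corr
    sup_star <- apply(abs(Wstar), 2, max)
    exceed[j] <- sum(sup_star >= obs_sup[j])
  }
  data.frame(
    term = colnames(X), statistic = obs_sup,
    p_value = (1 + exceed) / (nsim + 1),
    method = "supremum"
  )
}
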