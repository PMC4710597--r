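# Cox proportional-hazards machinery: partial-likelihood derivatives,
# Newton-Raphson fitting with Breslow or Efron handling of tied event times,
# the Breslow baseline cumulative hazard, per-SD hazard ratios and martingale
# residuals.  Everything is computed from first principles; the `survival`
# package is used only as an independent oracle in the test suite.

# Log partial likelihood and its derivatives at a given coefficient vector.
#
# Rows are sorted by follow-up time internally; risk-set sums are suffix
# cumulative sums, so the cost is O(n log n + n p^2).  `what` selects how much
# is computed: "loglik" (cheapest), "eta" (adds per-subject gradient/curvature
# with respect to the linear predictor, used by the penalized fitter) or
# "all" (score vector and observed information).
#' @keywords internal
cox_derivs <- function(time, status, X, beta, ties = "breslow", what = "all") {
  n <- length(time)
  p <- ncol(X)
  ord <- order(time)
  tt <- time[ord]
  dd <- status[ord]
  Xs <- X[ord, , drop = FALSE]
  eta <- drop(Xs %*% beta)
  emax <- max(eta)
  w <- exp(eta - emax) # the shift cancels in the partial likelihood

  cs0 <- rev(cumsum(rev(w)))
  newblk <- !duplicated(tt)
  blk <- cumsum(newblk)
  first <- which(newblk)
  ev <- which(dd == 1)
  if (length(ev) == 0L) stop("no events in the data", call. = FALSE)
  eblk <- blk[ev]
  ub <- sort(unique(eblk))
  dk <- as.vector(rowsum(rep(1, length(ev)), eblk))
  sum_eta_ev <- as.vector(rowsum(eta[ev] - emax, eblk))
  i1 <- first[ub]
  S0 <- cs0[i1]
  m <- length(ub)

  out <- list(n = n, nevent = length(ev))

  if (identical(ties, "breslow")) {
    out$loglik <- sum(sum_eta_ev) - sum(dk * log(S0))
  } else {
    s0e <- as.vector(rowsum(w[ev], eblk))
    ll <- sum(sum_eta_ev)
    for (k in seq_len(m)) {
      l <- seq_len(dk[k]) - 1
      ll <- ll - sum(log(S0[k] - (l / dk[k]) * s0e[k]))
    }
    out$loglik <- ll
  }

  # Breslow baseline hazard increments at the distinct event times
  # (unshifted scale).
  out$basehaz <- list(
    time = tt[i1], nevent = dk,
    hazard = dk / (S0 * exp(emax))
  )

  if (identical(what, "loglik")) return(out)

  if (identical(what, "eta")) {
    # Gradient (= martingale residual) and diagonal curvature w.r.t. eta,
    # Breslow ties.  Used by the coordinate-descent penalized fitter.
    inc1 <- numeric(max(blk))
    inc2 <- numeric(max(blk))
    inc1[ub] <- dk / S0
    inc2[ub] <- dk / S0^2
    B1 <- cumsum(inc1)[blk]
    B2 <- cumsum(inc2)[blk]
    g <- dd - w * B1
    h <- w * B1 - w^2 * B2
    out$grad_eta <- g[order(ord)]
    out$hess_eta <- pmax(h, 1e-10)[order(ord)]
    return(out)
  }

  wX <- Xs * w
  cs1 <- apply(wX, 2, function(col) rev(cumsum(rev(col))))
  cs1 <- matrix(cs1, nrow = n)
  iu <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  wXX <- wX[, iu[, 1], drop = FALSE] * Xs[, iu[, 2], drop = FALSE]
  cs2 <- apply(wXX, 2, function(col) rev(cumsum(rev(col))))
  cs2 <- matrix(cs2, nrow = n)

  S1 <- cs1[i1, , drop = FALSE]
  S2 <- cs2[i1, , drop = FALSE]
  sXk <- rowsum(Xs[ev, , drop = FALSE], eblk)

  expand_sym <- function(v) {
    M <- matrix(0, p, p)
    M[cbind(iu[, 1], iu[, 2])] <- v
    M[cbind(iu[, 2], iu[, 1])] <- v
    M
  }

  U <- numeric(p)
  I <- matrix(0, p, p)
  if (identical(ties, "breslow")) {
    xbar <- S1 / S0
    U <- colSums(sXk) - colSums(dk * xbar)
    I <- expand_sym(colSums(dk * S2 / S0)) -
      crossprod(sqrt(dk) * xbar)
  } else {
    s0e <- as.vector(rowsum(w[ev], eblk))
    s1e <- rowsum(wX[ev, , drop = FALSE], eblk)
    s2e <- rowsum(wXX[ev, , drop = FALSE], eblk)
    for (k in seq_len(m)) {
      U <- U + sXk[k, ]
      for (l in seq_len(dk[k]) - 1) {
        fr <- l / dk[k]
        den <- S0[k] - fr * s0e[k]
        mvec <- (S1[k, ] - fr * s1e[k, ]) / den
        U <- U - mvec
        I <- I + expand_sym((S2[k, ] - fr * s2e[k, ]) / den) -
          tcrossprod(mvec)
      }
    }
  }
  out$score <- U
  out$info <- I
  out
}

#' Log partial likelihood of a Cox model at given coefficients
#'
#' Evaluates the Cox log partial likelihood for an arbitrary coefficient
#' vector, with Breslow or Efron handling of tied event times.  Useful for
#' likelihood cross-validation and for independent verification of fitted
#' models.
#'
#' @param time Follow-up times (positive).
#' @param status Event indicators (0 = censored, 1 = event).
#' @param design Numeric matrix of covariates (one column per coefficient).
#' @param beta Coefficient vector, one value per design column.
#' @param ties `"breslow"` or `"efron"`.
#' @return The log partial likelihood (a scalar).
#' @export
cox_loglik <- function(time, status, design, beta, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  design <- as.matrix(design)
  cox_derivs(time, status, design, beta, ties = ties, what = "loglik")$loglik
}

#' Fit a Cox proportional-hazards model by Newton-Raphson
#'
#' Maximizes the Cox log partial likelihood with a damped Newton-Raphson
#' iteration.  Tied event times are handled by the Breslow (default) or Efron
#' approximation.  Rows with missing values in `time`, `status` or any design
#' column are dropped (complete-case analysis) and counted.
#'
#' Convergence is declared when the largest absolute score component falls
#' below `tol_score` or the relative change in log partial likelihood falls
#' below `tol_loglik`.  A likelihood that keeps improving while a coefficient
#' diverges (monotone likelihood, e.g. perfect separation) is flagged via
#' `converged = FALSE` with a warning.
#'
#' @param time Follow-up times in years (positive).
#' @param status Event indicators (0 = censored, 1 = event).
#' @param design Numeric matrix or data frame of covariates; factors must be
#'   dummy-encoded by the caller (see [build_design()]).
#' @param ties Tie-handling method, `"breslow"` (default) or `"efron"`.
#' @param max_iter Maximum Newton-Raphson iterations.
#' @param tol_score Convergence tolerance on the score vector.
#' @param tol_loglik Relative convergence tolerance on the log likelihood.
#' @return An object of class `methrisk_cox` with elements `coef`, `var`
#'   (inverse observed information), `loglik` (null and fitted),
#'   `minus2loglik`, `df`, `baseline` (Breslow cumulative-hazard step
#'   function as a data frame), `lp` (linear predictor), `n`, `nevent`,
#'   `n_dropped`, `iter`, `converged` and the retained `time`, `status`,
#'   `design`.
#' @examples
#' d <- data.frame(t = c(2, 4, 5, 7, 9, 11), s = c(1, 1, 0, 1, 0, 1),
#'                 x = c(1, 0, 1, 0, 1, 0))
#' fit <- fit_cox(d$t, d$s, design = d["x"])
#' exp(fit$coef) # hazard ratio for x
#' @export
fit_cox <- function(time, status, design, ties = c("breslow", "efron"),
                    max_iter = 30, tol_score = 1e-8, tol_loglik = 1e-10) {
  ties <- match.arg(ties)
  design <- as.matrix(as.data.frame(design))
  storage.mode(design) <- "double"
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  keep <- stats::complete.cases(design) & !is.na(time) & !is.na(status)
  n_dropped <- sum(!keep)
  time <- time[keep]
  status <- as.integer(status[keep])
  X <- design[keep, , drop = FALSE]
  if (any(time <= 0)) stop("all follow-up times must be positive", call. = FALSE)
  if (!all(status %in% c(0L, 1L))) stop("status must be 0/1", call. = FALSE)
  if (sum(status) < 1L) stop("at least one event is required", call. = FALSE)
  p <- ncol(X)

  all_zero <- all(X == 0)
  if (!all_zero && qr(X)$rank < p) {
    stop("design matrix is rank deficient", call. = FALSE)
  }

  beta <- numeric(p)
  d0 <- cox_derivs(time, status, X, beta, ties = ties, what = "all")
  loglik_null <- d0$loglik
  cur <- d0
  converged <- FALSE
  iter <- 0L
  if (all_zero) {
    converged <- TRUE
  } else {
    for (iter in seq_len(max_iter)) {
      step <- tryCatch(solve(cur$info, cur$score),
        error = function(e) drop(psolve(cur$info, cur$score))
      )
      halve <- 0L
      repeat {
        cand <- beta + step
        new <- cox_derivs(time, status, X, cand, ties = ties, what = "all")
        if (new$loglik >= cur$loglik - 1e-12 || halve >= 20L) break
        step <- step / 2
        halve <- halve + 1L
      }
      delta_ll <- abs(new$loglik - cur$loglik)
      beta <- cand
      cur <- new
      if (max(abs(cur$score)) < tol_score ||
        delta_ll < tol_loglik * (abs(cur$loglik) + 1)) {
        converged <- TRUE
        break
      }
    }
    if (!converged || any(abs(beta) > 20)) {
      if (any(abs(beta) > 20)) converged <- FALSE
      if (!converged) {
        warning("Cox fit did not converge (possible monotone likelihood)",
          call. = FALSE
        )
      }
    }
  }

  V <- tryCatch(solve(cur$info), error = function(e) psolve(cur$info))
  V <- (V + t(V)) / 2
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  bh <- cur$basehaz
  baseline <- data.frame(
    time = bh$time, nevent = bh$nevent,
    hazard = bh$hazard, cumhaz = cumsum(bh$hazard)
  )
  lp <- drop(X %*% beta)
  cumhaz_i <- stats::stepfun(baseline$time, c(0, baseline$cumhaz))(time)
  res <- status - cumhaz_i * exp(lp)

  structure(list(
    coef = beta, var = V,
    loglik = c(null = loglik_null, fitted = cur$loglik),
    minus2loglik = -2 * cur$loglik,
    df = p, score = cur$score, info = cur$info,
    baseline = baseline, lp = lp, residuals = res,
    n = length(time), nevent = sum(status), n_dropped = n_dropped,
    ties = ties, iter = iter, converged = converged,
    time = time, status = status, design = X
  ), class = "methrisk_cox")
}

#' @export
print.methrisk_cox <- function(x, digits = 4, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties), n = ", x$n,
    ", events = ", x$nevent, "\n",
    sep = ""
  )
  se <- sqrt(diag(x$var))
  z <- x$coef / se
  tab <- data.frame(
    coef = x$coef, HR = exp(x$coef), se = se,
    lower = exp(x$coef - 1.96 * se), upper = exp(x$coef + 1.96 * se),
    p = 2 * stats::pnorm(-abs(z))
  )
  print(round(tab, digits))
  cat("-2 log partial likelihood:", format(x$minus2loglik, digits = 8), "\n")
  invisible(x)
}

#' Breslow estimate of the baseline cumulative hazard
#'
#' Returns the baseline cumulative hazard of a fitted Cox model as a step
#' function over the distinct event times,
#' \eqn{H_0(t) = \sum_{t_k \le t} d_k / \sum_{i \in R(t_k)} e^{\eta_i}}.
#' With all coefficients zero this reduces exactly to the Nelson-Aalen
#' estimator.  The linear predictor is used on its raw (uncentred) scale, and
#' absolute risks must use the same convention (see [absolute_risk()]).
#'
#' @param fit A `methrisk_cox` object.
#' @return A data frame of class `methrisk_basehaz` with columns `time`,
#'   `nevent`, `hazard` (increments) and `cumhaz`.
#' @export
breslow_baseline <- function(fit) {
  stopifnot(inherits(fit, "methrisk_cox"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  structure(fit$baseline, class = c("methrisk_basehaz", "data.frame"))
}

# Evaluate a cumulative-hazard step function; flags extrapolation beyond the
# last observed event time.
#' @keywords internal
cumhaz_at <- function(baseline, t) {
  f <- stats::stepfun(baseline$time, c(0, baseline$cumhaz))
  out <- f(t)
  attr(out, "extrapolated") <- any(t > max(baseline$time))
  out
}

#' Hazard ratio per one standard-deviation decrease of a covariate
#'
#' Re-expresses a fitted Cox coefficient as the hazard ratio associated with
#' a decrease of the covariate by one cohort standard deviation,
#' \eqn{HR = e^{-\beta \cdot SD}}, with the Wald 95% interval transformed on
#' the same scale.  The result is invariant to the units in which the
#' covariate was stored.
#'
#' @param fit A `methrisk_cox` object.
#' @param column Name of the design column.
#' @param sd Standard deviation used for scaling; defaults to the SD of the
#'   column in the analysis data.
#' @return A one-row data frame with `term`, `hr`, `lower`, `upper`, `p`,
#'   `coef`, `se`, `sd`.
#' @export
per_sd_hr <- function(fit, column, sd = NULL) {
  stopifnot(inherits(fit, "methrisk_cox"))
  if (!column %in% names(fit$coef)) {
    stop("column '", column, "' not in the fitted design", call. = FALSE)
  }
  if (is.null(sd)) sd <- stats::sd(fit$design[, column])
  if (!is.finite(sd) || sd <= 0) stop("covariate has zero SD", call. = FALSE)
  b <- fit$coef[[column]]
  se <- sqrt(fit$var[column, column])
  ci <- sort(exp(-sd * c(b - 1.96 * se, b + 1.96 * se)))
  data.frame(
    term = column, hr = exp(-b * sd), lower = ci[1], upper = ci[2],
    p = 2 * stats::pnorm(-abs(b / se)), coef = b, se = se, sd = sd,
    row.names = NULL
  )
}

#' Martingale residuals of a Cox fit
#'
#' \eqn{M_i = \delta_i - \hat H_0(t_i) e^{\hat\eta_i}} on the analysis rows
#' (complete cases, in input order).  Under the Breslow baseline the
#' residuals sum to zero.
#'
#' @param fit A `methrisk_cox` object.
#' @return Numeric vector of residuals.
#' @export
martingale_residuals <- function(fit) {
  stopifnot(inherits(fit, "methrisk_cox"))
  fit$residuals
}
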