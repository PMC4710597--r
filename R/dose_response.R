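# Restricted cubic splines and adjusted dose-response regression.

#' Restricted cubic spline basis
#'
#' Truncated-power restricted (natural) cubic spline basis: for knots
#' \eqn{t_1 < \dots < t_k} the basis holds the linear term \eqn{x} plus
#' \eqn{k-2} nonlinear columns
#' \deqn{B_j(x) = \frac{(x-t_j)_+^3 -
#'   (x-t_{k-1})_+^3 \, (t_k-t_j)/(t_k-t_{k-1}) +
#'   (x-t_k)_+^3 \, (t_{k-1}-t_j)/(t_k-t_{k-1})}{(t_k-t_1)^2},}
#' which is linear beyond the boundary knots and exactly \eqn{(x, 0, \dots,
#' 0)} for \eqn{x \le t_1}.
#'
#' @param x Exposure values (may lie outside the knot range).
#' @param knots Strictly increasing knot locations, at least 3.
#' @return A matrix with columns `x, s1, ..., s(k-2)` and attribute
#'   `knots`.
#' @export
rcs_basis <- function(x, knots) {
  knots <- sort(knots)
  k <- length(knots)
  if (k < 3) stop("need at least 3 knots", call. = FALSE)
  if (any(diff(knots) == 0)) stop("duplicate knots", call. = FALSE)
  tk <- knots[k]
  tk1 <- knots[k - 1]
  t1 <- knots[1]
  pos3 <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(x), k - 1)
  B[, 1] <- x
  for (j in seq_len(k - 2)) {
    B[, j + 1] <- (pos3(x - knots[j]) -
      pos3(x - tk1) * (tk - knots[j]) / (tk - tk1) +
      pos3(x - tk) * (tk1 - knots[j]) / (tk - tk1)) / (tk - t1)^2
  }
  colnames(B) <- c("x", paste0("s", seq_len(k - 2)))
  attr(B, "knots") <- knots
  B
}

#' Default knot locations for a restricted cubic spline
#'
#' Standard percentile-based placement: for `k = 4` knots (the default) the
#' 5th/35th/65th/95th percentiles of the exposure, computed on the exposed
#' participants the caller passes in.
#'
#' @param x Exposure values among exposed participants.
#' @param k Number of knots (3, 4 or 5).
#' @return Numeric vector of knots.
#' @export
rcs_knots <- function(x, k = 4) {
  probs <- switch(as.character(k),
    "3" = c(0.10, 0.50, 0.90),
    "4" = c(0.05, 0.35, 0.65, 0.95),
    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
    stop("k must be 3, 4 or 5", call. = FALSE)
  )
  kn <- stats::quantile(x[!is.na(x)], probs, type = 7, names = FALSE)
  if (any(diff(kn) == 0)) kn <- unique(kn)
  if (length(kn) < 3) stop("exposure too discrete for spline knots", call. = FALSE)
  kn
}

#' Adjusted linear regression of methylation on exposures
#'
#' Ordinary least squares of a beta-value outcome on an exposure design plus
#' covariates, with classical standard errors.  Rows with any missing value
#' are dropped (complete cases) and counted.  Confidence intervals use the
#' 1.96 normal multiplier; p-values are two-sided from the t distribution.
#'
#' @param outcome Numeric outcome vector (beta-values).
#' @param design Data frame of exposures and covariates.  Character/factor
#'   columns are dummy-encoded with their first level as reference.
#' @return A list of class `methrisk_ols`: `coefficients` (data frame
#'   `term`, `estimate`, `se`, `lower`, `upper`, `p_value`), `n`,
#'   `n_dropped`, `sigma`, `r_squared`, `vcov`, and the underlying `lm`
#'   fit.
#' @export
fit_adjusted_ols <- function(outcome, design) {
  df <- as.data.frame(design)
  df$.y <- outcome
  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  if (stats::df.residual(fit) <= 0) {
    stop("zero residual degrees of freedom", call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  coefs <- data.frame(
    term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
    lower = ct[, 1] - 1.96 * ct[, 2], upper = ct[, 1] + 1.96 * ct[, 2],
    p_value = ct[, 4], row.names = NULL
  )
  structure(list(
    coefficients = coefs, n = nrow(df), n_dropped = n_dropped,
    sigma = sm$sigma, r_squared = sm$r.squared,
    vcov = stats::vcov(fit), fit = fit
  ), class = "methrisk_ols")
}

#' Adjusted restricted-cubic-spline dose-response curve
#'
#' Fits methylation on a restricted cubic spline in the exposure plus
#' covariates, with members of the reference group entered at exposure 0
#' (all spline columns zero).  Returns the fitted methylation difference
#' versus the reference across a grid of exposures with pointwise Wald 95%
#' confidence limits from the coefficient covariance.  The curve passes
#' through 0 (with zero-width limits) at the reference exposure.
#'
#' @param outcome Beta-value outcome.
#' @param exposure Nonnegative exposure (cigarettes/day, pack-years, or
#'   years since cessation).
#' @param reference Logical vector: `TRUE` for participants in the reference
#'   group (their exposure is treated as 0).
#' @param covariates Optional data frame of adjustment covariates.
#' @param knots Knot vector; default [rcs_knots()] with 4 knots on the
#'   exposed (non-reference) participants.
#' @param grid Exposure grid for the curve; default 101 points from 0 to the
#'   maximum observed exposure.
#' @return A data frame of class `methrisk_curve`: `exposure`, `estimate`,
#'   `lower`, `upper`, with attributes `knots`, `n`, `n_dropped`.
#' @export
dose_response_curve <- function(outcome, exposure, reference,
                                covariates = NULL, knots = NULL,
                                grid = NULL) {
  stopifnot(length(outcome) == length(exposure), length(reference) == length(outcome))
  if (!any(reference, na.rm = TRUE)) stop("reference group is empty", call. = FALSE)
  if (any(exposure < 0, na.rm = TRUE)) stop("exposure must be nonnegative", call. = FALSE)
  x_eff <- ifelse(reference, 0, exposure)
  if (is.null(knots)) {
    knots <- rcs_knots(exposure[!reference & !is.na(exposure)], k = 4)
  }
  B <- rcs_basis(x_eff, knots)
  colnames(B) <- paste0("rcs_", colnames(B))
  design <- as.data.frame(B)
  if (!is.null(covariates)) design <- cbind(design, as.data.frame(covariates))
  ols <- fit_adjusted_ols(outcome, design)
  if (is.null(grid)) {
    grid <- seq(0, max(exposure, na.rm = TRUE), length.out = 101)
  }
  Bg <- rcs_basis(grid, knots)
  terms <- paste0("rcs_", colnames(Bg))
  cf <- ols$coefficients
  idx <- match(terms, cf$term)
  beta_s <- cf$estimate[idx]
  V <- ols$vcov[cf$term[idx], cf$term[idx], drop = FALSE]
  est <- drop(Bg %*% beta_s)
  se <- sqrt(pmax(rowSums((Bg %*% V) * Bg), 0))
  out <- data.frame(
    exposure = grid, estimate = est,
    lower = est - 1.96 * se, upper = est + 1.96 * se
  )
  attr(out, "knots") <- knots
  attr(out, "n") <- ols$n
  attr(out, "n_dropped") <- ols$n_dropped
  class(out) <- c("methrisk_curve", "data.frame")
  out
}
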