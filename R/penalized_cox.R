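# L1-penalized Cox regression for variable selection among correlated CpGs.
#
# Fitting uses the usual quadratic approximation of the log partial
# likelihood around the current linear predictor (Breslow ties), followed by
# coordinate descent with soft-thresholding of the penalized coefficients;
# unpenalized covariates (age, sex, ...) are never thresholded.  The penalty
# parameter is chosen by k-fold cross-validated partial likelihood
# (Verweij-van Houwelingen): cvl_k = l(full; beta_{-k}) - l(train_{-k};
# beta_{-k}).

# One penalized fit at fixed lambda on a standardized design: proximal
# Newton.  Each outer step builds the exact quadratic model of the negative
# log partial likelihood (score U and observed information I at the current
# beta), solves the lasso-penalized quadratic subproblem by coordinate
# descent in the small coefficient space, and applies step halving on the
# penalized objective.
#' @keywords internal
pencox_fit_std <- function(time, status, Xs, penalized, lambda, beta0,
                           maxit = 50, tol = 1e-8) {
  p <- ncol(Xs)
  beta <- beta0
  pen_obj <- function(b, ll = NULL) {
    if (is.null(ll)) {
      ll <- cox_derivs(time, status, Xs, b,
        ties = "breslow", what = "loglik"
      )$loglik
    }
    -ll + lambda * sum(abs(b[penalized]))
  }
  obj <- pen_obj(beta)
  for (it in seq_len(maxit)) {
    dv <- cox_derivs(time, status, Xs, beta, ties = "breslow", what = "all")
    U <- dv$score
    I <- dv$info
    dI <- pmax(diag(I), 1e-10)
    # solve: min_b -U'(b - beta) + 0.5 (b-beta)' I (b-beta) + lambda|b_pen|
    b <- beta
    target <- drop(I %*% beta) + U
    for (sweep in 1:200) {
      maxdel <- 0
      for (j in seq_len(p)) {
        cj <- target[j] - sum(I[j, ] * b) + I[j, j] * b[j]
        bnew <- if (penalized[j]) soft_threshold(cj, lambda) / dI[j] else cj / dI[j]
        if (bnew != b[j]) {
          maxdel <- max(maxdel, abs(bnew - b[j]))
          b[j] <- bnew
        }
      }
      if (maxdel < 1e-11 * max(1, max(abs(b)))) break
    }
    # step halving on the penalized objective
    step <- b - beta
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      obj_new <- pen_obj(cand)
      if (obj_new <= obj + 1e-12 || alpha < 1e-4) break
      alpha <- alpha / 2
    }
    delta <- max(abs(alpha * step))
    beta <- cand
    obj <- obj_new
    if (delta < tol * max(1, max(abs(beta)))) {
      return(list(beta = beta, converged = TRUE, iter = it))
    }
  }
  list(beta = beta, converged = FALSE, iter = maxit)
}

#' L1-penalized Cox model with cross-validated penalty selection
#'
#' Fits a lasso-penalized Cox model over a decreasing grid of penalty values
#' with warm starts.  Columns named in `penalized` carry an L1 penalty
#' (internally the design is centred and scaled to unit SD so the penalty
#' acts on comparable scales; returned coefficients are on the original
#' scale); all other columns are unpenalized and fitted freely.  The penalty
#' is selected by `cv_folds`-fold cross-validated log partial likelihood, and
#' the selected variable set is the set of penalized columns with nonzero
#' coefficients at the chosen penalty.
#'
#' @param time Follow-up times (positive).
#' @param status Event indicators (0/1).
#' @param design Numeric matrix/data frame of covariates.
#' @param penalized Logical vector (one per column) or column names marking
#'   penalized covariates.  Default: all columns penalized.
#' @param lambda Optional decreasing vector of penalty values (on the
#'   standardized-design scale).  Default: a log-spaced grid of `nlambda`
#'   values from the smallest penalty that zeroes all penalized coefficients
#'   down to `lambda_min_ratio` times that value.
#' @param nlambda,lambda_min_ratio Grid controls when `lambda` is `NULL`.
#' @param cv_folds Number of cross-validation folds (events are stratified
#'   across folds).
#' @param seed Seed for the fold assignment.
#' @return An object of class `methrisk_pencox`: `lambda`, `beta` (columns =
#'   grid points, original scale), `cvl` (cross-validated partial
#'   log-likelihood per lambda), `lambda_opt`, `selected` (names of nonzero
#'   penalized coefficients at `lambda_opt`), `converged` (per lambda).
#' @export
fit_penalized_cox <- function(time, status, design, penalized = NULL,
                              lambda = NULL, nlambda = 20,
                              lambda_min_ratio = 0.01,
                              cv_folds = 5, seed = 1) {
  X <- as.matrix(as.data.frame(design))
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- stats::complete.cases(X) & !is.na(time) & !is.na(status)
  X <- X[keep, , drop = FALSE]
  time <- time[keep]
  status <- as.integer(status[keep])
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(penalized)) penalized <- rep(TRUE, p)
  if (is.character(penalized)) penalized <- colnames(X) %in% penalized
  stopifnot(length(penalized) == p)

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) stop("constant design column", call. = FALSE)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  if (is.null(lambda)) {
    # gradient at beta = 0 (unpenalized block still 0: grid top is approximate
    # but conventional)
    g0 <- cox_derivs(time, status, Xs, numeric(p),
      ties = "breslow", what = "eta"
    )$grad_eta
    lmax <- max(abs(crossprod(Xs[, penalized, drop = FALSE], g0)))
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
      length.out = nlambda
    ))
  }
  if (is.unsorted(rev(lambda))) stop("lambda grid must be decreasing", call. = FALSE)

  path_fit <- function(tt, ss, XX) {
    betas <- matrix(0, p, length(lambda))
    conv <- logical(length(lambda))
    b <- numeric(p)
    for (i in seq_along(lambda)) {
      f <- pencox_fit_std(tt, ss, XX, penalized, lambda[i], b)
      b <- f$beta
      betas[, i] <- b
      conv[i] <- f$converged
    }
    list(beta = betas, converged = conv)
  }

  full <- path_fit(time, status, Xs)
  if (!any(full$converged)) {
    stop("no lambda value achieved convergence", call. = FALSE)
  }

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fold <- integer(n)
  fold[status == 1] <- sample(rep_len(seq_len(cv_folds), sum(status == 1)))
  fold[status == 0] <- sample(rep_len(seq_len(cv_folds), sum(status == 0)))

  cvl <- numeric(length(lambda))
  for (k in seq_len(cv_folds)) {
    tr <- fold != k
    fit_k <- path_fit(time[tr], status[tr], Xs[tr, , drop = FALSE])
    for (i in seq_along(lambda)) {
      b <- fit_k$beta[, i]
      l_full <- cox_derivs(time, status, Xs, b,
        ties = "breslow", what = "loglik"
      )$loglik
      l_tr <- cox_derivs(time[tr], status[tr], Xs[tr, , drop = FALSE], b,
        ties = "breslow", what = "loglik"
      )$loglik
      cvl[i] <- cvl[i] + (l_full - l_tr)
    }
  }
  ok <- which(full$converged)
  iopt <- ok[which.max(cvl[ok])]
  beta_orig <- full$beta / scl
  rownames(beta_orig) <- colnames(X)
  sel <- colnames(X)[penalized & abs(full$beta[, iopt]) > 0]
  structure(list(
    lambda = lambda, beta = beta_orig, cvl = cvl,
    lambda_opt = lambda[iopt], beta_opt = beta_orig[, iopt],
    selected = sel, penalized = colnames(X)[penalized],
    converged = full$converged, n = n, nevent = sum(status)
  ), class = "methrisk_pencox")
}

#' @export
print.methrisk_pencox <- function(x, ...) {
  cat(
    "L1-penalized Cox path:", length(x$lambda), "lambda values, n =", x$n,
    ", events =", x$nevent, "\n"
  )
  cat(
    "lambda_opt =", format(x$lambda_opt, digits = 4), "; selected:",
    if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)", "\n"
  )
  invisible(x)
}
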