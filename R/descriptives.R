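# Stratified descriptive summaries, group tests, inter-CpG correlations and
# person-year incidence rates.

#' Stratified medians and quartiles of a methylation variable
#'
#' Per-stratum summary of beta-values: counts, share of non-missing strata,
#' median and quartiles (type-7 linear-interpolation quantiles, the
#' convention used package-wide), plus the Kruskal-Wallis p-value for the
#' difference across strata (when there are at least two strata).  Missing
#' values are excluded from the summaries and counted.
#'
#' @param values Numeric vector (e.g. beta-values at one CpG).
#' @param strata Stratum labels (factor or character); `NA` labels are
#'   excluded and counted.
#' @return A data frame of class `methrisk_strat`: `stratum`, `n`,
#'   `percent`, `n_missing_value`, `median`, `q1`, `q3`, `p_value`, with
#'   attribute `n_missing_stratum`.
#' @export
stratified_medians <- function(values, strata) {
  stopifnot(length(values) == length(strata))
  n_missing_stratum <- sum(is.na(strata))
  keep <- !is.na(strata)
  values <- values[keep]
  strata <- factor(strata[keep], levels = unique(strata[keep]))
  if (nlevels(strata) == 0L) stop("no non-missing strata", call. = FALSE)
  ntot <- length(strata)
  rows <- lapply(levels(strata), function(l) {
    v <- values[strata == l]
    ok <- !is.na(v)
    if (!any(ok)) stop("stratum '", l, "' has no non-missing values", call. = FALSE)
    q <- stats::quantile(v[ok], c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(
      stratum = l, n = length(v), percent = 100 * length(v) / ntot,
      n_missing_value = sum(!ok),
      median = q[2], q1 = q[1], q3 = q[3]
    )
  })
  out <- do.call(rbind, rows)
  out$p_value <- if (nlevels(strata) >= 2L) {
    kruskal_wallis(values, strata)$p_value
  } else {
    NA_real_
  }
  attr(out, "n_missing_stratum") <- n_missing_stratum
  class(out) <- c("methrisk_strat", "data.frame")
  out
}

#' Kruskal-Wallis rank test across strata
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation on
#' (groups - 1) degrees of freedom, as implemented by
#' [stats::kruskal.test()].
#'
#' @param values Numeric vector.
#' @param strata Group labels; at least two non-empty groups required.
#' @return A list with `statistic` (H), `df` and `p_value`.
#' @export
kruskal_wallis <- function(values, strata) {
  keep <- !is.na(values) & !is.na(strata)
  strata <- factor(strata[keep])
  strata <- droplevels(strata)
  if (nlevels(strata) < 2L) stop("need at least two groups", call. = FALSE)
  kt <- stats::kruskal.test(values[keep], strata)
  list(
    statistic = unname(kt$statistic), df = unname(kt$parameter),
    p_value = kt$p.value
  )
}

#' Spearman rank correlation matrix of the CpG beta-values
#'
#' Pairwise-complete Spearman correlations among the CpG columns.
#'
#' @param methylation Data frame or matrix of beta-values; a
#'   `participant_id` column, if present, is dropped.
#' @param min_pairs Minimum pairwise-complete observations required for every
#'   pair.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(methylation, min_pairs = 3) {
  m <- as.data.frame(methylation)
  m$participant_id <- NULL
  m <- as.matrix(m)
  if (any(colSums(!is.na(m)) == 0)) {
    stop("a CpG column has all values missing", call. = FALSE)
  }
  ok <- !is.na(m)
  npair <- crossprod(ok)
  if (any(npair < min_pairs)) {
    stop("fewer than ", min_pairs, " pairwise-complete observations", call. = FALSE)
  }
  stats::cor(m, method = "spearman", use = "pairwise.complete.obs")
}

#' Incidence rate per 100 person-years
#'
#' @param cases Number of events (nonnegative, vectorized).
#' @param person_years Person-years at risk (positive, vectorized).
#' @return A data frame with `cases`, `person_years`, `rate` (exact
#'   `100 * cases / person_years`); round to 2 decimals for table display.
#' @examples
#' incidence_rate(52, 1546.03) # 3.36 per 100 person-years
#' @export
incidence_rate <- function(cases, person_years) {
  if (any(person_years <= 0)) stop("person_years must be positive", call. = FALSE)
  if (any(cases < 0)) stop("cases must be nonnegative", call. = FALSE)
  data.frame(
    cases = cases, person_years = person_years,
    rate = 100 * cases / person_years
  )
}
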