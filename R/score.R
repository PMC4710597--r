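# Quartile assignment and the two-CpG 0/1/2 methylation score.

#' Assign per-CpG quartiles
#'
#' Computes quartile cutoffs (type-7 quantiles of all non-missing values,
#' the package-wide convention) for every CpG column and assigns each
#' participant a quartile index 1-4.  Lowest-quartile membership uses the
#' closed-boundary rule: a participant is in the lowest quartile iff
#' `beta <= Q1` (and generally in quartile `q` iff the value does not exceed
#' the q-th cutoff).  Columns whose cutoffs coincide (massive ties) are
#' flagged as degenerate.
#'
#' @param methylation Data frame or matrix of beta-values; a
#'   `participant_id` column, if present, is carried through.
#' @return A list of class `methrisk_quartiles`: `quartile` (data frame of
#'   indices, `NA` where the value is missing), `cutoffs` (3 x CpG matrix of
#'   Q1/Q2/Q3), `degenerate` (named logical).
#' @examples
#' qa <- assign_quartiles(data.frame(cg = 1:8))
#' qa$cutoffs # Q1 = 2.75 under type-7 quantiles
#' @export
assign_quartiles <- function(methylation) {
  m <- as.data.frame(methylation)
  ids <- m$participant_id
  m$participant_id <- NULL
  cut_m <- sapply(m, function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 4) stop("need at least 4 non-missing values per CpG", call. = FALSE)
    stats::quantile(v[ok], c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  })
  cut_m <- matrix(cut_m, nrow = 3, dimnames = list(c("q1", "q2", "q3"), names(m)))
  qidx <- as.data.frame(lapply(names(m), function(cn) {
    v <- m[[cn]]
    1L + (v > cut_m[1, cn]) + (v > cut_m[2, cn]) + (v > cut_m[3, cn])
  }), col.names = names(m))
  degenerate <- apply(cut_m, 2, function(q) any(diff(q) == 0))
  if (!is.null(ids)) qidx <- cbind(participant_id = ids, qidx)
  structure(list(quartile = qidx, cutoffs = cut_m, degenerate = degenerate),
    class = "methrisk_quartiles"
  )
}

#' Two-CpG methylation score
#'
#' The unweighted 0/1/2 score: the number of score CpGs (by default
#' cg05575921 and cg06126421) at which the participant's beta-value lies in
#' the lowest quartile.  Participants missing either CpG get a missing
#' score.
#'
#' @param quartiles A `methrisk_quartiles` object.
#' @param cpgs The two score CpGs.
#' @return Integer vector of scores with attribute `distribution` (counts of
#'   0/1/2).
#' @export
build_score <- function(quartiles, cpgs = methrisk_score_cpgs) {
  stopifnot(inherits(quartiles, "methrisk_quartiles"))
  q <- quartiles$quartile
  if (!all(cpgs %in% names(q))) {
    stop("quartiles missing for score CpGs", call. = FALSE)
  }
  flags <- sapply(cpgs, function(cn) q[[cn]] == 1L)
  flags <- matrix(flags, ncol = length(cpgs))
  score <- as.integer(rowSums(flags))
  score[rowSums(is.na(flags)) > 0] <- NA_integer_
  attr(score, "distribution") <- table(factor(score, levels = 0:2))
  score
}

#' Joint sex-by-score classification
#'
#' Cross-classifies participants by sex and methylation score into the six
#' classes "female-0" ... "male-2", usable directly as a Cox covariate.
#'
#' @param score Integer 0/1/2 vector from [build_score()].
#' @param sex Character/factor vector of `"male"` / `"female"`.
#' @return Factor with levels `female-0, female-1, female-2, male-0,
#'   male-1, male-2`; `NA` where either input is missing.
#' @export
joint_sex_score_classes <- function(score, sex) {
  stopifnot(length(score) == length(sex))
  lv <- as.vector(outer(c("female", "male"), 0:2, paste, sep = "-"))
  lv <- sort(lv)
  out <- ifelse(is.na(score) | is.na(sex), NA_character_,
    paste(as.character(sex), score, sep = "-")
  )
  factor(out, levels = lv)
}
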