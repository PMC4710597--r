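# Lossless CSV round-trip of the three cohort tables.  Doubles are written
# with 17 significant digits so that read-back reproduces them bit for bit;
# missing values are empty fields.

#' Write a cohort to CSV files
#'
#' Writes `cohort.csv`, `methylation.csv` and `survival.csv` into a
#' directory.  Numeric fields are serialized with full double precision so
#' that [read_cohort()] round-trips exactly; missing values become empty
#' fields.
#'
#' @param x A `methrisk_cohort` object (or plain list with the three data
#'   frames).
#' @param path Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(x, path) {
  stopifnot(all(c("cohort", "methylation", "survival") %in% names(x)))
  ids <- lapply(x[c("cohort", "methylation", "survival")], `[[`, "participant_id")
  if (!all(vapply(ids, identical, logical(1), y = ids[[1]]))) {
    stop("participant_id keys differ across tables", call. = FALSE)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(path, c("cohort.csv", "methylation.csv", "survival.csv"))
  tabs <- x[c("cohort", "methylation", "survival")]
  for (i in seq_along(tabs)) {
    df <- tabs[[i]]
    out <- df
    char_cols <- which(vapply(out, is.character, logical(1)))
    for (cn in names(out)) {
      if (is.double(out[[cn]])) out[[cn]] <- fmt_double(out[[cn]])
    }
    # quote only genuinely-character fields so numeric columns parse under
    # strict colClasses on read
    utils::write.csv(out, files[i],
      row.names = FALSE, na = "",
      quote = if (length(char_cols)) unname(char_cols) else FALSE
    )
  }
  invisible(files)
}

#' @keywords internal
cohort_col_classes <- function(table, cpgs) {
  switch(table,
    cohort = c(
      participant_id = "integer", sex = "character", age = "numeric",
      smoking_status = "character", cigarettes_per_day = "numeric",
      pack_years = "numeric", years_since_cessation = "numeric",
      bmi_category = "character", physical_activity = "character",
      systolic_bp = "numeric", total_cholesterol = "numeric",
      prevalent_cvd = "logical", prevalent_diabetes = "logical",
      prevalent_cancer = "logical", batch = "character"
    ),
    methylation = c(
      participant_id = "integer",
      stats::setNames(rep("numeric", length(cpgs)), cpgs)
    ),
    survival = c(
      participant_id = "integer", time = "numeric", event = "integer",
      cause = "character", cause_known = "logical"
    )
  )
}

#' Read a cohort from CSV files
#'
#' Reads the three tables written by [write_cohort()] and validates them:
#' matching `participant_id` keys, beta-values within \[0, 1\], positive
#' follow-up times, and `cause = "none"` for censored records.
#'
#' @param path Directory containing `cohort.csv`, `methylation.csv`,
#'   `survival.csv`.
#' @return A `methrisk_cohort` list.
#' @export
read_cohort <- function(path) {
  files <- file.path(path, c("cohort.csv", "methylation.csv", "survival.csv"))
  if (!all(file.exists(files))) {
    stop("missing cohort CSV files in '", path, "'", call. = FALSE)
  }
  hdr <- names(utils::read.csv(files[2], nrows = 1, check.names = FALSE))
  cpgs <- setdiff(hdr, "participant_id")
  if (length(cpgs) == 0L) cpgs <- methrisk_cpgs
  rd <- function(f, table) {
    cls <- cohort_col_classes(table, cpgs)
    df <- utils::read.csv(f,
      colClasses = cls, na.strings = "",
      check.names = FALSE, stringsAsFactors = FALSE
    )
    df
  }
  cohort <- rd(files[1], "cohort")
  methylation <- rd(files[2], "methylation")
  surv <- rd(files[3], "survival")

  ids <- list(cohort$participant_id, methylation$participant_id, surv$participant_id)
  if (!all(vapply(ids, identical, logical(1), y = ids[[1]]))) {
    stop("participant_id keys differ across tables", call. = FALSE)
  }
  bmat <- as.matrix(methylation[, cpgs, drop = FALSE])
  if (any(bmat < 0 | bmat > 1, na.rm = TRUE)) {
    stop("beta-values outside [0, 1]", call. = FALSE)
  }
  if (nrow(surv) > 0) {
    if (any(surv$time <= 0, na.rm = TRUE)) {
      stop("non-positive follow-up time", call. = FALSE)
    }
    bad <- surv$event == 0 & !is.na(surv$cause) & surv$cause != "none"
    if (any(bad, na.rm = TRUE)) {
      stop("censored records must have cause 'none'", call. = FALSE)
    }
  }
  structure(list(cohort = cohort, methylation = methylation, survival = surv),
    class = "methrisk_cohort"
  )
}
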