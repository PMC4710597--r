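# Dummy-encoded design matrices for survival models.

#' Build a numeric design matrix from cohort columns
#'
#' Numeric columns pass through, logicals become 0/1, and character/factor
#' columns are dummy-encoded against their reference level (the first level,
#' or the level named in `references`).  Rows are kept aligned with the
#' input; missing values propagate so that model fitters can apply
#' complete-case handling and report the number dropped.
#'
#' @param data Data frame.
#' @param vars Column names to include.
#' @param references Optional named character vector of reference levels,
#'   e.g. `c(smoking_status = "never")`.
#' @return Numeric matrix with columns named `var` or `var=level`.
#' @export
build_design <- function(data, vars, references = NULL) {
  stopifnot(all(vars %in% names(data)))
  cols <- list()
  for (v in vars) {
    x <- data[[v]]
    if (is.numeric(x)) {
      cols[[v]] <- as.numeric(x)
    } else if (is.logical(x)) {
      cols[[v]] <- as.numeric(x)
    } else {
      x <- as.character(x)
      lv <- sort(unique(x[!is.na(x)]))
      ref <- if (!is.null(references) && v %in% names(references)) {
        references[[v]]
      } else {
        lv[1]
      }
      if (!ref %in% lv) stop("reference level '", ref, "' absent in ", v, call. = FALSE)
      for (l in setdiff(lv, ref)) {
        nm <- paste0(v, "=", l)
        cols[[nm]] <- ifelse(is.na(x), NA_real_, as.numeric(x == l))
      }
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- NULL
  out
}
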