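#' Construct a cohort dataset
#'
#' Joins an expression matrix (genes x samples) with a clinical table; the
#' two must describe exactly the same samples (strict set equality on
#' sample ids). Columns of the expression matrix are reordered to the
#' clinical table's sample order.
#'
#' @param cohort_id Cohort label (also used as batch label downstream).
#' @param expression Numeric matrix, genes x samples, finite values, with
#'   row and column names.
#' @param clinical Data frame with columns `sample_id`, `time`, `event`,
#'   `sex`, `age`, `cytogenetics`, `runx1_mutation`, `fusion_t8_21`.
#' @param platform Free-text platform tag.
#' @return A `cohort_dataset`.
#' @export
cohort_dataset <- function(cohort_id, expression, clinical,
                           platform = "unknown") {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    stopf("expression matrix needs gene row names and sample column names")
  }
  if (!all(is.finite(expression))) stopf("expression values must all be finite")
  required <- c("sample_id", "time", "event", "sex", "age", "cytogenetics",
                "runx1_mutation", "fusion_t8_21")
  missing <- setdiff(required, names(clinical))
  if (length(missing) > 0) {
    stopf("clinical table lacks columns: %s", paste(missing, collapse = ", "))
  }
  if (!setequal(colnames(expression), clinical$sample_id)) {
    bad <- union(setdiff(colnames(expression), clinical$sample_id),
                 setdiff(clinical$sample_id, colnames(expression)))
    stopf("expression and clinical sample ids differ (e.g. %s)",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  expression <- expression[, clinical$sample_id, drop = FALSE]
  structure(list(cohort_id = cohort_id, expression = expression,
                 clinical = clinical, platform = platform),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("Cohort '%s' (%s): %d genes x %d samples, %d events\n",
              x$cohort_id, x$platform, nrow(x$expression),
              ncol(x$expression), sum(x$clinical$event)))
  invisible(x)
}

# Subset a cohort dataset to a sample index vector.
subset_cohort <- function(cohort, idx) {
  structure(list(cohort_id = cohort$cohort_id,
                 expression = cohort$expression[, idx, drop = FALSE],
                 clinical = cohort$clinical[idx, , drop = FALSE],
                 platform = cohort$platform),
            class = "cohort_dataset")
}
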