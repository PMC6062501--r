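COMPARISON_NAMES <- c("fusion_vs_no_fusion", "mutation_vs_no_mutation",
                      "fusion_only_vs_mutation_only")

#' Define one exposure contrast of the screen
#'
#' The three contrasts mirror the screening design: (1) fusion-positive vs
#' fusion-negative, (2) mutation-positive vs mutation-negative, (3)
#' fusion-only vs mutation-only patients. Each comparison names the cohort
#' used for pre-selection (possibly several cohort ids, which are then
#' ComBat-concatenated) and the distinct cohort used for validation.
#'
#' @param name One of `"fusion_vs_no_fusion"`, `"mutation_vs_no_mutation"`,
#'   `"fusion_only_vs_mutation_only"`.
#' @param preselection_cohort Cohort id, or a vector of ids to harmonize and
#'   concatenate for the pre-selection stage.
#' @param validation_cohort Single cohort id, distinct from all
#'   pre-selection ids.
#' @return A `comparison_spec`.
#' @export
comparison_spec <- function(name, preselection_cohort, validation_cohort) {
  name <- match.arg(name, COMPARISON_NAMES)
  if (validation_cohort %in% preselection_cohort) {
    stopf("validation cohort must be distinct from the pre-selection cohort(s)")
  }
  structure(list(name = name, preselection_cohort = preselection_cohort,
                 validation_cohort = validation_cohort),
            class = "comparison_spec")
}

# Exposure status under a comparison: 1 = exposed, 0 = unexposed, NA =
# excluded (Venn logic: samples missing a required flag, or -- for the
# fusion-only vs mutation-only contrast -- samples with neither or both
# alterations, are excluded).
exposure_status <- function(clinical, name) {
  mut <- as.character(clinical$runx1_mutation)
  fus <- as.character(clinical$fusion_t8_21)
  if (name == "fusion_vs_no_fusion") {
    ifelse(fus == "present", 1, ifelse(fus == "absent", 0, NA))
  } else if (name == "mutation_vs_no_mutation") {
    ifelse(mut == "present", 1, ifelse(mut == "absent", 0, NA))
  } else if (name == "fusion_only_vs_mutation_only") {
    ifelse(fus == "missing" | mut == "missing", NA,
           ifelse(fus == "present" & mut == "absent", 1,
                  ifelse(mut == "present" & fus == "absent", 0, NA)))
  } else {
    stopf("unknown comparison '%s'", name)
  }
}

# Restrict one cohort to the samples analyzable under a comparison and
# attach the exposure vector. Errors (naming the arm) if an arm is empty.
comparison_subset <- function(cohort, comparison) {
  name <- if (inherits(comparison, "comparison_spec")) comparison$name
          else match.arg(comparison, COMPARISON_NAMES)
  e <- exposure_status(cohort$clinical, name)
  keep <- !is.na(e)
  if (sum(e[keep] == 1) == 0) {
    stopf("comparison '%s' infeasible on cohort '%s': exposed arm is empty",
          name, cohort$cohort_id)
  }
  if (sum(e[keep] == 0) == 0) {
    stopf("comparison '%s' infeasible on cohort '%s': unexposed arm is empty",
          name, cohort$cohort_id)
  }
  sub <- subset_cohort(cohort, which(keep))
  list(expression = sub$expression, clinical = sub$clinical,
       exposure = e[keep], cohort_id = cohort$cohort_id, name = name)
}

#' Build the analysis subsets for one comparison
#'
#' Resolves the comparison's cohorts, applies the exposure rule (dropping
#' samples with missing required alteration flags, and for the fusion-only
#' vs mutation-only contrast all samples with neither alteration), and -- if
#' several pre-selection cohorts are named -- harmonizes and concatenates
#' them with [combat_harmonize()], protecting the exposure as a covariate so
#' batch removal cannot absorb the exposure-to-expression signal.
#'
#' @param cohorts Named list of `cohort_dataset` objects.
#' @param spec A [comparison_spec()].
#' @return List with `preselection` and `validation`, each a list holding
#'   `expression`, `clinical`, `exposure`.
#' @export
build_comparison <- function(cohorts, spec) {
  if (!inherits(spec, "comparison_spec")) stopf("spec must be a comparison_spec")
  missing_ids <- setdiff(c(spec$preselection_cohort, spec$validation_cohort),
                         names(cohorts))
  if (length(missing_ids) > 0) {
    stopf("unknown cohort id(s): %s", paste(missing_ids, collapse = ", "))
  }
  pre_ids <- spec$preselection_cohort
  if (length(pre_ids) == 1) {
    pre <- comparison_subset(cohorts[[pre_ids]], spec$name)
  } else {
    subs <- lapply(pre_ids, function(id) comparison_subset(cohorts[[id]], spec$name))
    shared <- Reduce(intersect, lapply(subs, function(s) rownames(s$expression)))
    if (length(shared) == 0) stopf("pre-selection cohorts share no genes")
    expr <- do.call(cbind, lapply(subs, function(s) s$expression[shared, , drop = FALSE]))
    clin <- do.call(rbind, lapply(subs, function(s) s$clinical))
    exposure <- unlist(lapply(subs, function(s) s$exposure))
    batch <- rep(pre_ids, vapply(subs, function(s) ncol(s$expression), integer(1)))
    expr <- combat_harmonize(expr, batch, mode = "eb",
                             covariates = cbind(exposure = exposure))
    pre <- list(expression = expr, clinical = clin, exposure = unname(exposure),
                cohort_id = paste(pre_ids, collapse = "+"), name = spec$name)
  }
  val <- comparison_subset(cohorts[[spec$validation_cohort]], spec$name)
  list(preselection = pre, validation = val)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1, returned in the
#' input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Pre-select promising genes
#'
#' Keeps genes whose indirect effect supports the total effect and whose
#' unadjusted mediation p-value is strictly below `alpha`, ordered by
#' ascending p-value. The direction filter runs before thresholding.
#'
#' @param results Per-gene mediation table from [mediation_test_all()].
#' @param alpha Pre-selection level (strict `<`).
#' @return Character vector of pre-selected gene ids; attributes
#'   `n_p_below` (count below alpha before the direction filter) and
#'   `n_supporting` record both conventions.
#' @export
preselect_genes <- function(results, alpha = 0.05) {
  if (is.null(results) || nrow(results) == 0) {
    warnf("empty mediation result list: nothing to pre-select")
    return(character(0))
  }
  keep <- results$direction == "supporting" & results$p < alpha
  out <- results$gene[keep][order(results$p[keep])]
  attr(out, "n_p_below") <- sum(results$p < alpha)
  attr(out, "n_supporting") <- sum(results$direction == "supporting")
  out
}

#' Validate pre-selected genes on an independent cohort
#'
#' Re-runs the mediation test on the validation cohort for the pre-selected
#' genes only. Genes absent from the validation cohort are recorded as
#' untested and excluded from the multiplicity family. Benjamini-Hochberg
#' adjustment runs over the genes that were tested and pass the
#' supporting-direction filter on the validation cohort (the direction
#' filter is applied before each stage's thresholding); a gene is validated
#' when its adjusted p-value is strictly below `alpha`.
#'
#' @param cohort Validation `cohort_dataset`.
#' @param preselected Character vector of pre-selected gene ids.
#' @param spec A [comparison_spec()] (or comparison name).
#' @param alpha Validation level (strict `<`, applied to adjusted p-values).
#' @param confounders Clinical confounders to adjust for.
#' @return Data frame with the mediation statistics plus `p_adj` (NA outside
#'   the BH family) and `significant`; attributes `untested` and
#'   `bh_family_size`.
#' @export
validate_genes <- function(cohort, preselected, spec, alpha = 0.05,
                           confounders = c("sex", "age", "cytogenetics")) {
  if (length(preselected) == 0) {
    out <- data.frame(gene = character(0), p = numeric(0), p_adj = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    attr(out, "untested") <- character(0)
    attr(out, "bh_family_size") <- 0L
    return(out)
  }
  present <- intersect(preselected, rownames(cohort$expression))
  untested <- setdiff(preselected, present)
  if (length(present) == 0) {
    warnf("none of the pre-selected genes are measured on the validation cohort")
    out <- data.frame(gene = character(0), p = numeric(0), p_adj = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    attr(out, "untested") <- untested
    attr(out, "bh_family_size") <- 0L
    return(out)
  }
  res <- mediation_test_all(cohort, spec, confounders, genes = present)
  fam <- res$direction == "supporting"
  res$p_adj <- NA_real_
  if (any(fam)) res$p_adj[fam] <- bh_adjust(res$p[fam])
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  attr(res, "untested") <- untested
  attr(res, "bh_family_size") <- sum(fam)
  res
}

#' Genes validated in two comparisons
#'
#' Set intersection of the significant genes of two validated tables,
#' annotated with both comparisons' statistics.
#'
#' @param tableA,tableB Validated tables from [validate_genes()].
#' @return Data frame of shared genes with suffixed statistics columns.
#' @export
intersect_candidates <- function(tableA, tableB) {
  sigA <- tableA[tableA$significant, , drop = FALSE]
  sigB <- tableB[tableB$significant, , drop = FALSE]
  common <- intersect(sigA$gene, sigB$gene)
  merge(sigA[sigA$gene %in% common, c("gene", "nie", "p", "p_adj")],
        sigB[sigB$gene %in% common, c("gene", "nie", "p", "p_adj")],
        by = "gene", suffixes = c("_A", "_B"))
}

#' Mediation screen restricted to a candidate gene panel
#'
#' Runs the mediation test for a small a-priori panel (such as a published
#' prognostic signature) so the multiplicity burden is only the panel size.
#' Panel members absent from the cohort are logged and skipped.
#'
#' @param cohort A `cohort_dataset`.
#' @param panel Character vector of panel gene ids.
#' @param spec A [comparison_spec()] or comparison name.
#' @param alpha Significance level on BH-adjusted p-values (strict `<`).
#' @param confounders Clinical confounders.
#' @return As [validate_genes()].
#' @export
panel_screen <- function(cohort, panel, spec, alpha = 0.05,
                         confounders = c("sex", "age", "cytogenetics")) {
  present <- intersect(panel, rownames(cohort$expression))
  if (length(present) == 0) stopf("no panel gene is present in the cohort")
  validate_genes(cohort, panel, spec, alpha, confounders)
}

#' Run the full two-stage mediation screen
#'
#' For each comparison: build the analysis subsets (harmonizing
#' concatenated pre-selection cohorts), run genome-wide mediation tests on
#' the pre-selection cohort, pre-select supporting genes at unadjusted
#' p < `alpha_pre`, re-test them on the validation cohort with BH
#' adjustment, and finally intersect the validated lists of every pair of
#' comparisons. A failing comparison is recorded in the per-comparison
#' status and does not abort the others.
#'
#' @param cohorts Named list of `cohort_dataset` objects.
#' @param specs List of [comparison_spec()] objects.
#' @param alpha_pre Pre-selection level.
#' @param alpha_val Validation level (on BH-adjusted p-values).
#' @param confounders Clinical confounders.
#' @return A `screening_result`: per-comparison stage tables and logs,
#'   pairwise intersections, and a status summary.
#' @export
run_screen <- function(cohorts, specs, alpha_pre = 0.05, alpha_val = 0.05,
                       confounders = c("sex", "age", "cytogenetics")) {
  comparisons <- list()
  for (spec in specs) {
    nm <- spec$name
    comparisons[[nm]] <- tryCatch({
      built <- build_comparison(cohorts, spec)
      pre_cohort <- cohort_dataset(built$preselection$cohort_id %||% "pre",
                                   built$preselection$expression,
                                   built$preselection$clinical)
      # exposure may differ from raw flags only via exclusion, which the
      # subset already applied; re-derive per contract
      pre_res <- mediation_test_all(pre_cohort, spec, confounders)
      preselected <- preselect_genes(pre_res, alpha_pre)
      val_tab <- validate_genes(cohorts[[spec$validation_cohort]],
                                preselected, spec, alpha_val, confounders)
      list(status = "ok",
           preselection_table = pre_res,
           preselected = as.character(preselected),
           validation_table = val_tab,
           log = list(n_genes_tested = nrow(pre_res),
                      n_p_below_alpha = attr(preselected, "n_p_below"),
                      n_supporting_direction = attr(preselected, "n_supporting"),
                      n_preselected = length(preselected),
                      n_untested_on_validation = length(attr(val_tab, "untested")),
                      bh_family_size = attr(val_tab, "bh_family_size"),
                      n_validated = sum(val_tab$significant)))
    }, error = function(e) {
      list(status = paste("failed:", conditionMessage(e)),
           preselection_table = NULL, preselected = character(0),
           validation_table = NULL, log = list())
    })
  }
  nms <- names(comparisons)
  intersections <- list()
  if (length(nms) >= 2) {
    for (i in seq_along(nms)) for (j in seq_along(nms)) {
      if (i < j && comparisons[[i]]$status == "ok" &&
          comparisons[[j]]$status == "ok") {
        key <- paste(nms[i], nms[j], sep = " & ")
        intersections[[key]] <- intersect_candidates(
          comparisons[[i]]$validation_table, comparisons[[j]]$validation_table)
      }
    }
  }
  structure(list(comparisons = comparisons, intersections = intersections,
                 alpha_pre = alpha_pre, alpha_val = alpha_val),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Two-stage mediation screen\n")
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    if (cmp$status == "ok") {
      cat(sprintf("  %s: %d tested, %d pre-selected, %d validated\n", nm,
                  cmp$log$n_genes_tested, cmp$log$n_preselected,
                  cmp$log$n_validated))
    } else {
      cat(sprintf("  %s: %s\n", nm, cmp$status))
    }
  }
  for (key in names(x$intersections)) {
    cat(sprintf("  intersection [%s]: %d gene(s)\n", key,
                nrow(x$intersections[[key]])))
  }
  invisible(x)
}
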