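#!/usr/bin/env Rscript
# Stage 4: descriptive characterization of the validated genes.
#
# For each validated gene: univariate Cox per SD of expression with
# Harrell's concordance, a Kaplan-Meier median-split comparison with the
# log-rank test, and Wilcoxon comparisons of expression between altered and
# unaltered patients. Across the validated set: partial correlations and
# the agreement between hierarchical and k-means clusterings (adjusted
# Rand index), computed on the standardized expression of the unaltered
# patients as in the screening design.

suppressMessages(library(survmedscreen))

data_dir <- file.path("results", "data")
screen_dir <- file.path("results", "screen")
out <- file.path("results", "descriptives")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- cohort_dataset(
  "cohort_1",
  read_expression_tsv(file.path(data_dir, "cohort_1_expression.tsv")),
  read_clinical_tsv(file.path(data_dir, "cohort_1_clinical.tsv")))
validated <- read.delim(file.path(screen_dir, "validation.tsv"),
                        stringsAsFactors = FALSE)
genes <- validated$gene[validated$significant]
if (length(genes) == 0) {
  message("no validated genes; falling back to the 3 smallest validation p-values")
  genes <- head(validated$gene[order(validated$p)], 3)
}
message("characterizing: ", paste(genes, collapse = ", "))

clin <- cohort$clinical
exposed <- clin$runx1_mutation == "present"

## per-gene survival descriptives ---------------------------------------
cox_rows <- list(); km_rows <- list(); wil_rows <- list()
for (g in genes) {
  expr <- cohort$expression[g, ]
  cx <- cox_univariate_standardized(expr, clin$time, clin$event)
  cox_rows[[g]] <- data.frame(gene = g, hr_per_sd = cx$hr,
                              ci_lower = cx$ci_lower, ci_upper = cx$ci_upper,
                              concordance = cx$concordance, p = cx$p)
  split <- median_dichotomize(expr)
  km <- km_logrank(clin$time, clin$event, split)
  km_rows[[g]] <- cbind(gene = g, km$curves,
                        logrank_chisq = km$chisq, logrank_p = km$p)
  wil_rows[[g]] <- data.frame(gene = g,
                              p_mut_vs_none = wilcoxon_compare(expr[exposed],
                                                               expr[!exposed]))
}
write.table(do.call(rbind, cox_rows), file.path(out, "cox_univariate.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, km_rows), file.path(out, "km_curves.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, wil_rows), file.path(out, "wilcoxon.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## joint structure of the gene set (unaltered patients only) ------------
panel <- unique(c(genes, head(validated$gene[order(validated$p)], 10)))
sub <- standardize_genes(cohort$expression[panel, !exposed, drop = FALSE])
if (length(panel) >= 3) {
  pc <- partial_correlation_matrix(sub, threshold = 0.2)
  write.table(pc$edges, file.path(out, "partial_correlation_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- cluster_and_compare(sub, k = 2, seed = 1)
  message(sprintf("hierarchical vs k-means agreement (ARI): %.2f", cl$agreement))
  write.table(data.frame(gene = rownames(sub), hierarchical = cl$hierarchical,
                         kmeans = cl$kmeans),
              file.path(out, "clusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

write_run_manifest(file.path(out, "manifest.json"), "describe",
                   config = list(genes = genes, k = 2), seeds = 1,
                   counts = list(n_genes_described = length(genes)))
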