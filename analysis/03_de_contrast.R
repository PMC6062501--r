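#!/usr/bin/env Rscript
# Stage 3: why differential expression is not mediation.
#
# Moderated-t differential expression on the pre-selection cohort picks the
# exposure-responsive genes; each DE gene is then put into two Cox models,
# (a) gene alone and (b) gene + exposure. Genes whose apparent survival
# relevance evaporates in (b) were riding on the exposure's own effect.

suppressMessages(library(survmedscreen))

data_dir <- file.path("results", "data")
out <- file.path("results", "contrast")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- cohort_dataset(
  "cohort_1",
  read_expression_tsv(file.path(data_dir, "cohort_1_expression.tsv")),
  read_clinical_tsv(file.path(data_dir, "cohort_1_clinical.tsv")))

ctr <- de_mediation_contrast(cohort, "mutation_vs_no_mutation",
                             de_alpha = 0.01, alpha = 0.05)
message(sprintf(paste0("%d genes differentially expressed (BH p < 0.01); ",
                       "%d survival-associated alone (a), %d after adjusting ",
                       "for the exposure (b)"),
                ctr$counts["n_de"], ctr$counts["n_sig_a"],
                ctr$counts["n_sig_b"]))

write.table(ctr$de_table, file.path(out, "de_moderated_t.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
if (!is.null(ctr$cox_table)) {
  write.table(ctr$cox_table, file.path(out, "cox_pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

write_run_manifest(file.path(out, "manifest.json"), "contrast",
                   config = list(de_alpha = 0.01, alpha = 0.05),
                   seeds = NA, counts = as.list(ctr$counts))
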