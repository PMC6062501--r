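#!/usr/bin/env Rscript
# Stage 1: simulate a two-cohort AML-like study with planted mediation
# structure and write it out as plain TSV/GMT files under results/data/.
#
# The world: 1000 genes of which 5 are supporting mediators (exposure
# shifts expression by 0.8 SD, expression shifts the hazard by 0.5 per SD),
# a handful of opposing/prognostic genes, 50 purely differentially
# expressed genes, and a RUNX1-mutation-like exposure carried by 20% of
# 800 patients per cohort. The baseline hazard (5 events per time unit)
# sits about 3 SD above the covariate hazard spread so the additive model
# stays positive.

suppressMessages(library(survmedscreen))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 5L
out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

config <- sim_config(
  n_genes = 1000, n_samples_per_cohort = 800, n_cohorts = 2,
  class_fractions = c(supporting_mediator = 0.005, opposing_mediator = 0.002,
                      de_only = 0.05, prognostic_only = 0.002, null = 0.941),
  alteration_probs = c(none = 0.8, mutation = 0.2, fusion = 0),
  a_effect = 0.8, b_effect = 0.5, baseline_hazard = 5, direct_effect = 1,
  seed = seed)

study <- generate_study(config)

for (co in study$cohorts) {
  write_expression_tsv(co$expression,
                       file.path(out, paste0(co$cohort_id, "_expression.tsv")))
  write_clinical_tsv(co$clinical,
                     file.path(out, paste0(co$cohort_id, "_clinical.tsv")))
  message(sprintf("wrote cohort %s: %d genes x %d samples, %d events",
                  co$cohort_id, nrow(co$expression), ncol(co$expression),
                  sum(co$clinical$event)))
}
write.table(study$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

genesets <- generate_genesets(study$truth, n_sets = 10, set_size = 25,
                              enrichment = 0.6, seed = seed)
write_gmt(genesets, file.path(out, "genesets.gmt"))

write_run_manifest(file.path(out, "manifest.json"), "simulate",
                   config = unclass(config), seeds = seed,
                   counts = list(n_genes = config$n_genes,
                                 n_cohorts = config$n_cohorts,
                                 n_samples = config$n_samples_per_cohort))
message("simulation written to ", out)
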