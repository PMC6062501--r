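#!/usr/bin/env Rscript
# Stage 5: over-representation analysis of the mediation candidates.
#
# Candidates are genes with supporting direction and unadjusted validation
# p < 0.10 (a deliberately lenient exploratory cut); the universe is the
# set of genes tested on the validation cohort; gene sets come from the
# simulated GMT file, which contains one set enriched for the planted
# mediators.

suppressMessages(library(survmedscreen))

data_dir <- file.path("results", "data")
screen_dir <- file.path("results", "screen")
out <- file.path("results", "ora")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

validated <- read.delim(file.path(screen_dir, "validation.tsv"),
                        stringsAsFactors = FALSE)
preselection <- read.delim(file.path(screen_dir, "preselection.tsv"),
                           stringsAsFactors = FALSE)
genesets <- read_gmt(file.path(data_dir, "genesets.gmt"),
                     universe = preselection$gene)

candidates <- select_ora_candidates(validated, alpha = 0.10)
message(sprintf("%d ORA candidates at validation p < 0.10", length(candidates)))
if (length(candidates) == 0) {
  message("no candidates; writing an empty enrichment table")
  enr <- data.frame(set = character(0), set_size = integer(0),
                    overlap = integer(0), p = numeric(0), p_adj = numeric(0))
} else {
  enr <- ora_hypergeometric(candidates, preselection$gene, genesets)
  print(head(enr, 3))
}
write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

write_run_manifest(file.path(out, "manifest.json"), "ora",
                   config = list(alpha = 0.10), seeds = NA,
                   counts = list(n_candidates = length(candidates),
                                 n_sets = length(genesets$sets)))
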