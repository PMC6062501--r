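#' Univariate Cox regression on a standardized gene
#'
#' Hazard ratio per one SD of log2 expression (the gene is standardized
#' before fitting so ratios are comparable across genes) with a 95%
#' confidence interval and Harrell's concordance index of the fitted risk
#' score. Higher expression associated with higher hazard gives HR > 1.
#'
#' @param gene Numeric vector of per-sample expression.
#' @param time,event Survival outcome.
#' @return List `hr`, `ci_lower`, `ci_upper`, `concordance`, `p`.
#' @export
cox_univariate_standardized <- function(gene, time, event) {
  g <- standardize_genes(as.numeric(gene))
  fit <- survival::coxph(survival::Surv(time, event) ~ g)
  s <- summary(fit)
  co <- s$coefficients
  list(hr = unname(exp(co[1, "coef"])),
       ci_lower = unname(s$conf.int[1, "lower .95"]),
       ci_upper = unname(s$conf.int[1, "upper .95"]),
       concordance = unname(s$concordance[1]),
       p = unname(co[1, "Pr(>|z|)"]))
}

#' Split samples at the median
#'
#' `high` for values strictly above the median; ties at the median go to
#' `low`. Degenerate all-equal input yields all `low` with a warning.
#'
#' @param values Numeric vector (length >= 2).
#' @return Character vector of `"high"`/`"low"` labels.
#' @export
median_dichotomize <- function(values) {
  if (length(values) < 2) stopf("need at least 2 samples")
  med <- stats::median(values)
  if (all(values == values[1])) {
    warnf("all values equal: every sample labeled 'low'")
  }
  ifelse(values > med, "high", "low")
}

#' Kaplan-Meier curves and log-rank test for two groups
#'
#' Product-limit survival curves per group plus the standard log-rank
#' chi-square statistic and p-value.
#'
#' @param time,event Survival outcome.
#' @param groups Group label per sample (exactly 2 non-empty groups).
#' @return List `curves` (data frame `group`, `time`, `n_risk`, `n_event`,
#'   `survival`), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(time, event, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stopf("exactly two groups are required")
  if (any(table(groups) == 0)) stopf("both groups must be non-empty")
  sf <- survival::survfit(survival::Surv(time, event) ~ groups)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(group = sub("^groups=", "", strata), time = sf$time,
                       n_risk = sf$n.risk, n_event = sf$n.event,
                       survival = sf$surv, stringsAsFactors = FALSE)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ groups)
  chisq <- sd_$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  list(curves = curves, chisq = chisq, df = 1, p = p)
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Exact for small samples without ties; normal approximation with tie
#' correction otherwise (the standard rank-sum conventions).
#'
#' @param groupA,groupB Numeric vectors.
#' @return Two-sided p-value.
#' @export
wilcoxon_compare <- function(groupA, groupB) {
  if (length(groupA) == 0 || length(groupB) == 0) {
    stopf("both groups must be non-empty")
  }
  suppressWarnings(stats::wilcox.test(groupA, groupB)$p.value)
}

#' Partial correlations among a small set of genes
#'
#' Partial correlation of each gene pair given all remaining genes, from the
#' inverse correlation matrix:
#' \eqn{\rho_{ij \cdot rest} = -\Omega_{ij} / \sqrt{\Omega_{ii}\Omega_{jj}}}.
#' The edge list keeps pairs whose partial correlation is strictly larger
#' than the display threshold.
#'
#' @param mat Expression submatrix, genes x samples, with more samples than
#'   genes.
#' @param threshold Display threshold (strict `>`), default 0.2.
#' @return A `partial_correlation_graph`: list `matrix` (symmetric, unit
#'   diagonal), `edges` (data frame `gene1`, `gene2`, `partial_cor`),
#'   `threshold`.
#' @export
partial_correlation_matrix <- function(mat, threshold = 0.2) {
  mat <- as.matrix(mat)
  if (ncol(mat) <= nrow(mat)) {
    stopf("need more samples than genes for partial correlations")
  }
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  R <- stats::cor(t(mat))
  if (rcond(R) < 1e-12) stopf("correlation matrix is singular")
  Om <- solve(R)
  d <- sqrt(diag(Om))
  P <- -Om / tcrossprod(d)
  diag(P) <- 1
  dimnames(P) <- dimnames(R)
  idx <- which(upper.tri(P), arr.ind = TRUE)
  vals <- P[idx]
  keep <- vals > threshold
  edges <- data.frame(gene1 = rownames(P)[idx[keep, 1]],
                      gene2 = rownames(P)[idx[keep, 2]],
                      partial_cor = vals[keep], stringsAsFactors = FALSE)
  structure(list(matrix = P, edges = edges, threshold = threshold),
            class = "partial_correlation_graph")
}

#' Compare hierarchical and k-means clusterings of genes
#'
#' Complete-linkage hierarchical clustering with Euclidean distance, cut at
#' `k`, against k-means with the same `k` (seeded for reproducibility, 10
#' random starts), with agreement measured by the adjusted Rand index.
#'
#' @param mat Matrix whose rows (genes) are clustered.
#' @param k Number of clusters.
#' @param seed RNG seed for k-means.
#' @return List `hierarchical`, `kmeans` (integer label vectors) and
#'   `agreement` (ARI).
#' @export
cluster_and_compare <- function(mat, k = 2, seed = 1) {
  mat <- as.matrix(mat)
  if (k > nrow(mat)) stopf("k exceeds the number of genes")
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "complete")
  part_h <- stats::cutree(hc, k = k)
  part_k <- with_seed(seed, stats::kmeans(mat, centers = k, nstart = 10)$cluster)
  list(hierarchical = part_h, kmeans = part_k,
       agreement = adjusted_rand_index(part_h, part_k))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement:
#' \eqn{ARI = (Index - E[Index]) / (Max - E[Index])} over the contingency
#' table of the two label vectors. 1 for identical partitions (up to label
#' permutation), about 0 at chance level.
#'
#' @param partitionA,partitionB Label vectors over the same items.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(partitionA, partitionB) {
  if (length(partitionA) != length(partitionB)) {
    stopf("partitions must label the same items")
  }
  tab <- table(partitionA, partitionB)
  choose2 <- function(x) x * (x - 1) / 2
  index <- sum(choose2(tab))
  a <- sum(choose2(rowSums(tab)))
  b <- sum(choose2(colSums(tab)))
  expected <- a * b / choose2(length(partitionA))
  maxi <- (a + b) / 2
  if (maxi == expected) return(1)       # degenerate: identical trivial partitions
  (index - expected) / (maxi - expected)
}

#' Candidate genes for over-representation analysis
#'
#' Genes with supporting direction and unadjusted validation p-value
#' strictly below `alpha` (a deliberately lenient exploratory cut, before
#' any multiplicity adjustment).
#'
#' @param validation_table A [validate_genes()] table.
#' @param alpha Raw p-value threshold (strict `<`), default 0.10.
#' @return Character vector of gene ids.
#' @export
select_ora_candidates <- function(validation_table, alpha = 0.10) {
  if (is.null(validation_table) || nrow(validation_table) == 0) return(character(0))
  validation_table$gene[validation_table$direction == "supporting" &
                          validation_table$p < alpha]
}

#' Gene-set collection
#'
#' Named gene sets over a universe; every set is clipped to the universe and
#' empty sets are rejected.
#'
#' @param sets Named list of character vectors.
#' @param universe Character vector of all gene ids.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stopf("every gene set needs a name")
  }
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  if (any(lengths(sets) == 0)) {
    stopf("empty gene set(s): %s",
          paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p-value of the candidate list's overlap with
#' each gene set (probability of an overlap at least as large under uniform
#' sampling of the candidates from the universe), BH-adjusted across sets.
#'
#' @param candidates Character vector of candidate gene ids (must lie in the
#'   universe).
#' @param universe Character vector defining the tested family (typically
#'   the genes surviving preprocessing in the validation cohort).
#' @param genesets A [gene_set_collection()] (its sets are clipped to
#'   `universe`).
#' @return Data frame `set`, `set_size`, `overlap`, `p`, `p_adj`, ordered by
#'   ascending p.
#' @export
ora_hypergeometric <- function(candidates, universe, genesets) {
  candidates <- unique(candidates)
  bad <- setdiff(candidates, universe)
  if (length(bad) > 0) {
    stopf("candidate gene(s) outside the universe: %s",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  sets <- lapply(genesets$sets, intersect, universe)
  N <- length(universe)
  n <- length(candidates)
  res <- data.frame(set = names(sets),
                    set_size = lengths(sets),
                    overlap = vapply(sets, function(s)
                      length(intersect(s, candidates)), integer(1)),
                    stringsAsFactors = FALSE)
  res$p <- stats::phyper(res$overlap - 1, res$set_size, N - res$set_size, n,
                         lower.tail = FALSE)
  res$p_adj <- bh_adjust(res$p)
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Gene sets enriched in both comparisons
#'
#' Sets significant (BH-adjusted p strictly below `alpha`) in two
#' enrichment results over the same collection.
#'
#' @param resultsA,resultsB [ora_hypergeometric()] tables.
#' @param alpha Significance level on adjusted p-values.
#' @return Character vector of set names.
#' @export
common_enriched <- function(resultsA, resultsB, alpha = 0.05) {
  intersect(resultsA$set[resultsA$p_adj < alpha],
            resultsB$set[resultsB$p_adj < alpha])
}
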