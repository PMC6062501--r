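# Invert the trigamma function by Newton iteration (needed for the
# moment-matching estimate of the variance prior's degrees of freedom).
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Moderated t-tests for differential expression
#'
#' Per-gene linear model of expression on a two-group contrast plus optional
#' covariates, with residual variances shrunk toward a common prior by
#' empirical Bayes. The prior degrees of freedom \eqn{d_0} and prior
#' variance \eqn{s_0^2} are estimated across genes by moment matching on the
#' log residual variances (scaled F-distribution moments, inverting the
#' trigamma function). The moderated statistic is the group coefficient over
#' its standard error with posterior variance
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)} and is referred
#' to a t-distribution with \eqn{d_0 + d_g} degrees of freedom.
#'
#' @param mat Expression matrix, genes x samples (log scale).
#' @param groups Binary 0/1 group indicator (1 = exposed/altered group).
#' @param covariates Optional numeric covariate matrix (samples x q).
#' @param prior_df Optional forced prior df: `0` reproduces the ordinary
#'   t-test exactly, `Inf` replaces every gene's variance by \eqn{s_0^2}.
#' @return Data frame `gene`, `coef`, `t`, `p`, `s2`, `s2_post`, `df_total`;
#'   attributes `prior_df` and `prior_var`.
#' @export
moderated_t_test <- function(mat, groups, covariates = NULL, prior_df = NULL) {
  mat <- as.matrix(mat)
  groups <- as.numeric(groups)
  if (!all(groups %in% c(0, 1))) stopf("groups must be binary 0/1")
  if (sum(groups == 0) < 2 || sum(groups == 1) < 2) {
    stopf("need at least 2 samples per group")
  }
  X <- cbind(1, group = groups)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) stopf("rank-deficient design")
  n <- ncol(mat)
  H <- solve(crossprod(X))
  beta <- H %*% crossprod(X, t(mat))
  resid <- t(mat) - X %*% beta
  df <- n - ncol(X)
  s2 <- colSums(resid^2) / df
  coef <- beta[2, ]
  v <- H[2, 2]

  pos <- s2 > 0
  z <- log(s2[pos])
  evar <- stats::var(z) - trigamma(df / 2)
  if (is.null(prior_df)) {
    if (is.na(evar) || evar <= 0) {
      d0 <- Inf
    } else {
      d0 <- 2 * trigamma_inverse(evar)
    }
  } else {
    d0 <- prior_df
  }
  if (is.infinite(d0)) {
    s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2))
  } else if (d0 == 0) {
    s02 <- NA_real_                      # unused: no shrinkage
  } else {
    s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  }
  if (d0 == 0) {
    s2_post <- s2
  } else if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
  } else {
    s2_post <- (d0 * s02 + df * s2) / (d0 + df)
  }
  tstat <- coef / sqrt(s2_post * v)
  df_total <- d0 + df
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(gene = rownames(mat), coef = coef, t = tstat, p = p,
                    s2 = s2, s2_post = s2_post, df_total = df_total,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  out
}

#' Paired per-gene Cox regressions with and without the exposure
#'
#' For each gene, two proportional-hazards models: (a) the gene as the only
#' covariate, (b) the gene plus the exposure. The Wald p-value of the
#' gene's coefficient is recorded for each, and the two p-value families are
#' BH-adjusted separately. Genes whose fit fails or is degenerate
#' (constant expression, collinearity with the exposure, non-convergence)
#' are flagged and excluded from both families.
#'
#' @param mat Expression matrix, genes x samples.
#' @param time,event Survival outcome.
#' @param exposure Binary exposure vector.
#' @return Data frame `gene`, `p_a`, `p_b`, `p_a_adj`, `p_b_adj`, `flagged`.
#' @export
cox_gene_regressions <- function(mat, time, event, exposure) {
  mat <- as.matrix(mat)
  if (sum(event) < 1) stopf("at least one event is required")
  surv <- survival::Surv(time, event)
  exposure <- as.numeric(exposure)
  G <- nrow(mat)
  p_a <- rep(NA_real_, G); p_b <- rep(NA_real_, G); flagged <- logical(G)
  for (g in seq_len(G)) {
    gene <- mat[g, ]
    if (stats::sd(gene) == 0) { flagged[g] <- TRUE; next }
    pa <- tryCatch({
      fit <- survival::coxph(surv ~ gene)
      s <- summary(fit)$coefficients
      if (anyNA(s["gene", c("coef", "Pr(>|z|)")])) NA_real_ else s["gene", "Pr(>|z|)"]
    }, error = function(e) NA_real_, warning = function(w) NA_real_)
    pb <- tryCatch({
      fit <- survival::coxph(surv ~ gene + exposure)
      s <- summary(fit)$coefficients
      # an aliased term anywhere (gene collinear with exposure) voids model (b)
      if (nrow(s) < 2 || anyNA(fit$coefficients) ||
          anyNA(s["gene", c("coef", "Pr(>|z|)")])) NA_real_
      else s["gene", "Pr(>|z|)"]
    }, error = function(e) NA_real_, warning = function(w) NA_real_)
    if (is.na(pa) || is.na(pb)) { flagged[g] <- TRUE; next }
    p_a[g] <- pa; p_b[g] <- pb
  }
  out <- data.frame(gene = rownames(mat), p_a = p_a, p_b = p_b,
                    p_a_adj = NA_real_, p_b_adj = NA_real_,
                    flagged = flagged, stringsAsFactors = FALSE)
  ok <- !flagged
  if (any(ok)) {
    out$p_a_adj[ok] <- bh_adjust(p_a[ok])
    out$p_b_adj[ok] <- bh_adjust(p_b[ok])
  }
  rownames(out) <- NULL
  out
}

#' Contrast differential expression with mediation-style survival relevance
#'
#' Selects differentially expressed genes at BH-adjusted p < `de_alpha`
#' (moderated t), then runs the paired Cox regressions on exactly those
#' genes and reports how many stay survival-associated with and without
#' adjustment for the exposure. The expected picture on data where the
#' exposure drives both expression and survival: far fewer genes remain
#' significant once the exposure is adjusted for -- differential expression
#' alone does not establish mediation.
#'
#' @param cohort A `cohort_dataset`.
#' @param comparison A [comparison_spec()] or comparison name.
#' @param de_alpha DE significance level on adjusted p-values (strict `<`).
#' @param alpha Cox significance level on adjusted p-values (strict `<`).
#' @param confounders Clinical confounders for the DE linear model.
#' @return List with `de_table`, `cox_table` (DE genes only), and `counts`
#'   (`n_de`, `n_sig_a`, `n_sig_b`).
#' @export
de_mediation_contrast <- function(cohort, comparison, de_alpha = 0.01,
                                  alpha = 0.05,
                                  confounders = c("sex", "age", "cytogenetics")) {
  sub <- comparison_subset(cohort, comparison)
  C <- confounder_matrix(sub$clinical, confounders)
  de <- moderated_t_test(sub$expression, sub$exposure, C)
  de$p_adj <- bh_adjust(de$p)
  de_genes <- de$gene[de$p_adj < de_alpha]
  if (length(de_genes) == 0) {
    warnf("no differentially expressed genes at adjusted p < %g", de_alpha)
    return(list(de_table = de, cox_table = NULL,
                counts = c(n_de = 0, n_sig_a = 0, n_sig_b = 0)))
  }
  cox <- cox_gene_regressions(sub$expression[de_genes, , drop = FALSE],
                              sub$clinical$time, sub$clinical$event,
                              sub$exposure)
  counts <- c(n_de = length(de_genes),
              n_sig_a = sum(cox$p_a_adj < alpha, na.rm = TRUE),
              n_sig_b = sum(cox$p_b_adj < alpha, na.rm = TRUE))
  list(de_table = de, cox_table = cox, counts = counts)
}
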