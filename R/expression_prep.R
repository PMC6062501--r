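#' Drop genes that are unexpressed in most samples
#'
#' A gene is removed when its fraction of zero-count samples is strictly
#' greater than `max_unexpressed_fraction` (so a gene at exactly the
#' threshold is kept).
#'
#' @param counts Nonnegative count matrix, genes x samples.
#' @param max_unexpressed_fraction Maximum tolerated zero fraction.
#' @return The filtered matrix; attribute `dropped` lists removed genes.
#' @export
filter_low_expression <- function(counts, max_unexpressed_fraction = 0.90) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be nonnegative")
  zero_frac <- rowMeans(counts == 0)
  drop <- zero_frac > max_unexpressed_fraction
  out <- counts[!drop, , drop = FALSE]
  attr(out, "dropped") <- rownames(counts)[drop]
  out
}

#' Log-stabilize a count matrix
#'
#' Elementwise `log2(x + 1)`; a plain variance-stabilizing stand-in for
#' platform-specific preprocessing of raw counts.
#'
#' @param counts Nonnegative matrix.
#' @return Matrix on the log2 scale.
#' @export
log_stabilize <- function(counts) {
  if (any(counts < 0)) stopf("counts must be nonnegative")
  log2(counts + 1)
}

#' Center and scale each gene
#'
#' Per-gene standardization to mean zero, variance one (denominator n - 1),
#' so hazard ratios and hazard increments are per SD of log2 expression and
#' comparable across genes.
#'
#' @param x Matrix (genes x samples) or a single gene's numeric vector.
#' @return Standardized matrix or vector.
#' @export
standardize_genes <- function(x) {
  if (is.null(dim(x))) {
    s <- stats::sd(x)
    if (s == 0) stopf("zero-variance gene cannot be standardized")
    return((x - mean(x)) / s)
  }
  x <- as.matrix(x)
  m <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  if (any(s == 0)) {
    stopf("zero-variance gene(s): %s",
          paste(utils::head(rownames(x)[s == 0], 5), collapse = ", "))
  }
  (x - m) / s
}

# Method-of-moments hyperparameters for the inverse-gamma scale prior
# (the standard empirical-Bayes batch-adjustment choice).
ig_aprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2 }
ig_bprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2 }

# Iterative joint solution of the empirical-Bayes batch location/scale
# posteriors for one batch (location gamma* and scale delta2* depend on
# each other, so they are iterated to convergence).
eb_batch_solve <- function(Zb, g_hat, d_hat, g_bar, t2, a_pr, b_pr,
                           tol = 1e-8, max_iter = 500) {
  nb <- ncol(Zb)
  g_new <- g_hat
  d_new <- d_hat
  for (it in seq_len(max_iter)) {
    g_old <- g_new; d_old <- d_new
    g_new <- (nb * t2 * g_hat + d_new * g_bar) / (nb * t2 + d_new)
    sum2 <- rowSums((Zb - g_new)^2)
    d_new <- (0.5 * sum2 + b_pr) / (nb / 2 + a_pr - 1)
    change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                  abs(d_new - d_old) / (abs(d_old) + 1e-12))
    if (change < tol) break
  }
  list(gamma_star = g_new, delta2_star = d_new)
}

#' Location/scale batch harmonization (ComBat-style)
#'
#' Removes per-gene, per-batch location shifts and scale factors from an
#' expression matrix so cohorts measured on different platforms can be
#' concatenated. Each gene is standardized under a pooled model (batch
#' means plus optional protected covariates, pooled residual variance with
#' residual degrees of freedom); per-batch location/scale parameters are
#' estimated on the standardized data and, in `"eb"` mode, shrunk toward
#' across-gene priors (normal prior for locations, inverse-gamma for
#' scales, method-of-moments hyperparameters, iterated jointly). Covariate
#' effects are estimated and re-added, so biological signal passed in
#' `covariates` (e.g. the exposure) is not absorbed by the batch
#' adjustment. `"plain"` mode applies the unshrunk estimates and is exactly
#' hand-checkable.
#'
#' @param mat Expression matrix, genes x samples.
#' @param batch Batch label per sample (at least 2 batches of >= 2 samples;
#'   a single batch returns the input unchanged with a warning).
#' @param mode `"eb"` (empirical Bayes, default) or `"plain"`.
#' @param covariates Optional numeric matrix of covariates to protect.
#' @return The adjusted matrix (same dimensions); attribute `batch_params`
#'   carries the applied location/scale per gene and batch.
#' @export
combat_harmonize <- function(mat, batch, mode = c("eb", "plain"),
                             covariates = NULL) {
  mode <- match.arg(mode)
  mat <- as.matrix(mat)
  batch <- factor(batch)
  if (length(batch) != ncol(mat)) stopf("one batch label per sample required")
  if (nlevels(batch) == 1) {
    warnf("single batch: harmonization is the identity")
    return(mat)
  }
  tab <- table(batch)
  if (any(tab < 2)) {
    stopf("every batch needs at least 2 samples (got: %s)",
          paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  n <- ncol(mat)
  B <- stats::model.matrix(~ 0 + batch)
  X <- B
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    X <- cbind(B, covariates)
  }
  if (qr(X)$rank < ncol(X)) {
    stopf("covariates are confounded with batch (rank-deficient design)")
  }
  beta <- solve(crossprod(X), crossprod(X, t(mat)))     # (nb+q) x genes
  nb_levels <- nlevels(batch)
  grand <- drop(crossprod(beta[seq_len(nb_levels), , drop = FALSE],
                          as.numeric(tab) / n))          # weighted grand mean
  stand_mean <- matrix(grand, nrow = nrow(mat), ncol = n)
  if (!is.null(covariates)) {
    cov_part <- t(covariates %*% beta[-seq_len(nb_levels), , drop = FALSE])
    stand_mean <- stand_mean + cov_part
  }
  resid <- mat - t(X %*% beta)
  df <- n - ncol(X)
  s2 <- rowSums(resid^2) / df                            # residual-df pooled
  if (any(s2 == 0)) stopf("zero residual variance for some gene(s)")
  s <- sqrt(s2)
  Z <- (mat - stand_mean) / s

  out <- Z
  params <- list()
  for (b in levels(batch)) {
    idx <- which(batch == b)
    Zb <- Z[, idx, drop = FALSE]
    g_hat <- rowMeans(Zb)
    d_hat <- apply(Zb, 1, stats::var)
    if (mode == "plain") {
      g_star <- g_hat; d_star <- d_hat
    } else {
      g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
      a_pr <- ig_aprior(d_hat); b_pr <- ig_bprior(d_hat)
      sol <- eb_batch_solve(Zb, g_hat, d_hat, g_bar, t2, a_pr, b_pr)
      g_star <- sol$gamma_star; d_star <- sol$delta2_star
    }
    out[, idx] <- (Zb - g_star) / sqrt(d_star)
    params[[b]] <- list(location = g_star, scale2 = d_star)
  }
  out <- out * s + stand_mean
  dimnames(out) <- dimnames(mat)
  attr(out, "batch_params") <- params
  out
}
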