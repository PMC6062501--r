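#' Fit the linear mediator model for one gene
#'
#' Ordinary least squares of per-sample expression on a binary exposure and
#' optional confounders. The exposure coefficient \eqn{\hat\alpha_E} is the
#' adjusted exposure-to-expression effect; with no confounders it equals the
#' difference of group means.
#'
#' @param expression Numeric vector of per-sample expression values.
#' @param exposure Binary 0/1 exposure vector.
#' @param confounders Optional numeric matrix of confounder encodings
#'   (samples x variables).
#' @return An object of class `mediator_model_fit` with `coefficients`,
#'   `se`, `sigma` (residual SD) and `df_residual`.
#' @export
fit_mediator_model <- function(expression, exposure, confounders = NULL) {
  expression <- as.numeric(expression)
  exposure <- as.numeric(exposure)
  n <- length(expression)
  if (length(exposure) != n) stopf("expression and exposure lengths differ")
  if (!all(exposure %in% c(0, 1))) stopf("exposure must be binary 0/1")
  if (sum(exposure == 1) < 2 || sum(exposure == 0) < 2) {
    stopf("insufficient data: need at least 2 samples per exposure group")
  }
  if (stats::sd(expression) == 0) {
    stopf("degenerate gene: expression is constant across samples")
  }
  X <- cbind(intercept = 1, exposure = exposure)
  if (!is.null(confounders) && NCOL(confounders) > 0) {
    confounders <- as.matrix(confounders)
    if (is.null(colnames(confounders))) {
      colnames(confounders) <- paste0("c", seq_len(ncol(confounders)))
    }
    X <- cbind(X, confounders)
  }
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12) stopf("mediator-model design is rank deficient")
  H <- solve(XtX)
  beta <- drop(H %*% crossprod(X, expression))
  names(beta) <- colnames(X)
  resid <- expression - drop(X %*% beta)
  df <- n - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * diag(H))
  names(se) <- colnames(X)
  structure(list(coefficients = beta, se = se, sigma = sqrt(sigma2),
                 df_residual = df),
            class = "mediator_model_fit")
}

#' Natural indirect effect with Sobel-type delta-method inference
#'
#' The natural indirect effect on the additive-hazards scale is the product
#' of the exposure-to-expression coefficient \eqn{a = \hat\alpha_E} and the
#' expression-to-hazard coefficient \eqn{b = \hat\gamma_M}:
#' \deqn{\widehat{NIE} = a b, \quad
#'       se = \sqrt{b^2 Var(a) + a^2 Var(b)},}
#' with a two-sided normal p-value. The covariance cross-term between the
#' two fits is omitted (Sobel convention; conservative in simulations). An
#' exact-zero product with zero standard error yields p = 1 rather than NaN.
#'
#' @param mfit A [fit_mediator_model()] fit containing the exposure arm.
#' @param hfit An [fit_additive_hazards()] fit containing a coefficient named
#'   by `mediator`.
#' @param mediator Name of the mediator term in `hfit`.
#' @return List with `nie`, `se_nie`, `z`, `p`, `a`, `se_a`, `b`, `se_b`.
#' @export
indirect_effect <- function(mfit, hfit, mediator = "mediator") {
  if (!inherits(mfit, "mediator_model_fit")) stopf("mfit must be a mediator_model_fit")
  if (!inherits(hfit, "additive_hazard_fit")) stopf("hfit must be an additive_hazard_fit")
  if (!mediator %in% names(hfit$coefficients)) {
    stopf("hazard fit has no mediator term '%s'", mediator)
  }
  a <- unname(mfit$coefficients["exposure"])
  se_a <- unname(mfit$se["exposure"])
  b <- unname(hfit$coefficients[mediator])
  se_b <- unname(hfit$se[mediator])
  sobel_product(a, se_a, b, se_b)
}

# Shared Sobel product computation (also used by the vectorized screen).
sobel_product <- function(a, se_a, b, se_b) {
  nie <- a * b
  se_nie <- sqrt(b^2 * se_a^2 + a^2 * se_b^2)
  z <- ifelse(se_nie > 0, nie / se_nie, 0)
  p <- ifelse(se_nie > 0, 2 * stats::pnorm(-abs(z)), ifelse(nie == 0, 1, 0))
  list(nie = nie, se_nie = se_nie, z = z, p = p,
       a = a, se_a = se_a, b = b, se_b = se_b)
}

#' Classify an indirect effect as supporting or opposing the total effect
#'
#' A mediator supports the exposure's observed influence on survival when
#' the sign of its indirect effect matches the sign of the exposure's total
#' effect on the hazard (e.g. a gene up-regulated by a harmful alteration
#' and itself hazard-increasing). An indirect effect of exactly zero is
#' degenerate.
#'
#' @param nie_sign Sign of the indirect effect (or the effect itself).
#' @param total_sign Total-effect sign, `+1` or `-1`.
#' @return `"supporting"`, `"opposing"` or `"degenerate"`.
#' @export
classify_direction <- function(nie_sign, total_sign) {
  if (!total_sign %in% c(-1, 1)) stopf("total_sign must be +1 or -1")
  s <- sign(nie_sign)
  if (s == 0) return("degenerate")
  if (s == total_sign) "supporting" else "opposing"
}

#' Mediation test for a single gene
#'
#' Composes the mediator regression, the additive-hazards outcome model
#' (exposure + gene + confounders), the delta-method indirect effect and the
#' direction classification against the exposure's total-effect sign
#' (estimated on the same samples from the mediator-free hazard model).
#' Degenerate genes (constant expression, collinear designs) are returned
#' flagged with p = 1 rather than raising, so a genome-wide screen survives
#' pathological genes.
#'
#' @param gene Gene identifier present in the cohort's expression matrix.
#' @param cohort A `cohort_dataset`.
#' @param comparison A [comparison_spec()] or comparison name.
#' @param confounders Clinical confounders to adjust for in both models.
#' @return A one-row data frame: `gene`, `a`, `se_a`, `b`, `se_b`, `nie`,
#'   `se_nie`, `z`, `p`, `direction`, `total_sign`.
#' @export
mediation_test_gene <- function(gene, cohort, comparison,
                                confounders = c("sex", "age", "cytogenetics")) {
  sub <- comparison_subset(cohort, comparison)
  if (!gene %in% rownames(sub$expression)) stopf("gene '%s' not in cohort", gene)
  C <- confounder_matrix(sub$clinical, confounders)
  ts <- total_effect_sign(cohort, comparison, confounders)
  res <- tryCatch({
    mfit <- fit_mediator_model(sub$expression[gene, ], sub$exposure, C)
    Z <- cbind(exposure = sub$exposure, C, mediator = sub$expression[gene, ])
    hfit <- fit_additive_hazards(surv_design(Z, sub$clinical$time, sub$clinical$event))
    ie <- indirect_effect(mfit, hfit)
    data.frame(gene = gene, a = ie$a, se_a = ie$se_a, b = ie$b, se_b = ie$se_b,
               nie = ie$nie, se_nie = ie$se_nie, z = ie$z, p = ie$p,
               direction = classify_direction(ie$nie, ts),
               total_sign = ts, stringsAsFactors = FALSE)
  }, error = function(e) {
    data.frame(gene = gene, a = NA_real_, se_a = NA_real_, b = NA_real_,
               se_b = NA_real_, nie = 0, se_nie = 0, z = 0, p = 1,
               direction = "degenerate", total_sign = ts,
               stringsAsFactors = FALSE)
  })
  rownames(res) <- NULL
  res
}

#' Genome-wide mediation tests for one comparison on one cohort
#'
#' Numerically identical to calling [mediation_test_gene()] per gene, but
#' computed with the shared covariate block factored out: the
#' exposure/confounder parts of the Lin-Ying matrices are built once and the
#' gene-specific row/column is filled in for all genes via matrix products,
#' so a 1000-gene screen costs a few matrix multiplications plus one small
#' solve per gene.
#'
#' @param cohort A `cohort_dataset`.
#' @param comparison A [comparison_spec()] or comparison name.
#' @param confounders Clinical confounders to adjust for.
#' @param genes Optional subset of gene ids to test (default: all genes).
#' @return Data frame with one row per gene, columns as in
#'   [mediation_test_gene()], ordered as requested.
#' @export
mediation_test_all <- function(cohort, comparison,
                               confounders = c("sex", "age", "cytogenetics"),
                               genes = NULL) {
  sub <- comparison_subset(cohort, comparison)
  M <- sub$expression
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(M))
    if (length(missing) > 0) {
      stopf("genes not in cohort: %s", paste(missing, collapse = ", "))
    }
    M <- M[genes, , drop = FALSE]
  }
  C <- confounder_matrix(sub$clinical, confounders)
  e <- sub$exposure
  time <- sub$clinical$time
  event <- sub$clinical$event
  n <- length(e)
  G <- nrow(M)

  W <- cbind(exposure = e, C)
  p0 <- ncol(W)
  wfit <- fit_additive_hazards(surv_design(W, time, event))
  ts <- unname(ifelse(wfit$coefficients["exposure"] >= 0, 1, -1))

  ## --- mediator model, all genes at once -------------------------------
  X <- cbind(1, W)                       # same design as fit_mediator_model
  H <- solve(crossprod(X))
  beta <- H %*% crossprod(X, t(M))       # (p0+1) x G
  fitted <- X %*% beta
  rss <- colSums((t(M) - fitted)^2)
  df <- n - ncol(X)
  sigma2 <- rss / df
  a <- beta[2, ]                         # exposure row
  se_a <- sqrt(sigma2 * H[2, 2])
  gene_sd <- apply(M, 1, stats::sd)

  ## --- additive-hazards fits, shared block + per-gene border -----------
  core <- ah_core(W, time, event)
  ord <- core$ord
  x <- core$x
  w <- core$delta / core$nk
  Ws <- W[ord, , drop = FALSE]
  Ms <- M[, ord, drop = FALSE]
  SM <- rev_cumsum_cols(Ms)
  A_WW <- core$A
  A_Wm <- Ms %*% (Ws * x) - SM %*% (core$S * w)          # G x p0
  A_mm <- drop((Ms^2) %*% x) - drop((SM^2) %*% w)        # length G
  ev <- core$ev
  fe <- core$fe
  rn <- core$rn
  Wc <- Ws[ev, , drop = FALSE] - core$S[fe, , drop = FALSE] / rn
  MC <- Ms[, ev, drop = FALSE] - sweep(SM[, fe, drop = FALSE], 2, rn, "/")
  b_W <- core$b
  b_m <- rowSums(MC)
  B_WW <- core$B
  B_Wm <- MC %*% Wc                                       # G x p0
  B_mm <- rowSums(MC^2)

  out_b <- numeric(G); out_se_b <- numeric(G); ok <- logical(G)
  p1 <- p0 + 1
  A_g <- matrix(0, p1, p1); B_g <- matrix(0, p1, p1)
  A_g[1:p0, 1:p0] <- A_WW
  B_g[1:p0, 1:p0] <- B_WW
  for (g in seq_len(G)) {
    if (gene_sd[g] == 0) next
    A_g[p1, 1:p0] <- A_Wm[g, ]; A_g[1:p0, p1] <- A_Wm[g, ]; A_g[p1, p1] <- A_mm[g]
    B_g[p1, 1:p0] <- B_Wm[g, ]; B_g[1:p0, p1] <- B_Wm[g, ]; B_g[p1, p1] <- B_mm[g]
    Ainv <- tryCatch(solve(A_g), error = function(e) NULL)
    if (is.null(Ainv) || !all(is.finite(Ainv)) || rcond(A_g) < 1e-12) next
    gam <- Ainv %*% c(b_W, b_m[g])
    V <- Ainv %*% B_g %*% Ainv
    out_b[g] <- gam[p1]
    out_se_b[g] <- sqrt(max(V[p1, p1], 0))
    ok[g] <- TRUE
  }

  degen <- !ok | gene_sd == 0 |
    sum(e == 1) < 2 | sum(e == 0) < 2
  sp <- sobel_product(a, se_a, out_b, out_se_b)
  res <- data.frame(gene = rownames(M), a = sp$a, se_a = sp$se_a,
                    b = sp$b, se_b = sp$se_b, nie = sp$nie,
                    se_nie = sp$se_nie, z = sp$z, p = sp$p,
                    direction = ifelse(sp$nie == 0, "degenerate",
                                       ifelse(sign(sp$nie) == ts,
                                              "supporting", "opposing")),
                    total_sign = ts, stringsAsFactors = FALSE)
  if (any(degen)) {
    res$a[degen] <- NA_real_; res$se_a[degen] <- NA_real_
    res$b[degen] <- NA_real_; res$se_b[degen] <- NA_real_
    res$nie[degen] <- 0; res$se_nie[degen] <- 0; res$z[degen] <- 0
    res$p[degen] <- 1; res$direction[degen] <- "degenerate"
  }
  rownames(res) <- NULL
  res
}
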