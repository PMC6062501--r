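# Independent oracles, written before the main implementations and kept
# deliberately naive (explicit loops, finite-difference Newton) so they
# share no code path with the package.

# Brute-force evaluation of the additive-hazards estimating equation
#   U(beta) = sum_i int (Z_i - Zbar(t)) [dN_i(t) - Y_i(t) beta' Z_i dt]
# with explicit risk-set recomputation on every inter-event interval.
bf_ah_U <- function(beta, Z, time, event) {
  n <- nrow(Z)
  U <- rep(0, ncol(Z))
  # event terms
  for (i in seq_len(n)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      zbar <- colMeans(Z[risk, , drop = FALSE])
      U <- U + (Z[i, ] - zbar)
    }
  }
  # integral terms over intervals between consecutive distinct times
  cuts <- sort(unique(c(0, time)))
  for (k in seq_len(length(cuts) - 1)) {
    t0 <- cuts[k]; t1 <- cuts[k + 1]
    risk <- which(time >= t1)
    if (length(risk) == 0) next
    zbar <- colMeans(Z[risk, , drop = FALSE])
    for (i in risk) {
      U <- U - (Z[i, ] - zbar) * sum(Z[i, ] * beta) * (t1 - t0)
    }
  }
  U
}

# Solve U(beta) = 0 by Newton iteration with a finite-difference Jacobian.
bf_ah_solve <- function(Z, time, event, tol = 1e-12, max_iter = 50) {
  p <- ncol(Z)
  beta <- rep(0, p)
  h <- 1e-6
  for (it in seq_len(max_iter)) {
    U <- bf_ah_U(beta, Z, time, event)
    if (max(abs(U)) < tol) break
    J <- matrix(0, p, p)
    for (j in seq_len(p)) {
      bp <- beta; bp[j] <- bp[j] + h
      J[, j] <- (bf_ah_U(bp, Z, time, event) - U) / h
    }
    beta <- beta - solve(J, U)
  }
  beta
}

# A fixed 20-sample survival fixture (hand-written numbers, includes ties).
ah_fixture <- function() {
  list(
    time = c(2.3, 1.1, 4.5, 0.8, 3.2, 1.1, 5.0, 2.3, 0.5, 6.1,
             1.9, 2.8, 3.7, 0.9, 4.1, 2.2, 1.5, 3.0, 5.5, 2.6),
    event = c(1, 1, 0, 1, 1, 0, 1, 1, 1, 0,
              1, 0, 1, 1, 0, 1, 1, 0, 1, 1),
    z = c(1, 0, 1, 0, 1, 1, 0, 0, 1, 0,
          1, 0, 1, 0, 1, 0, 1, 0, 1, 0),
    z2 = c(0.3, -1.2, 0.5, 0.1, -0.4, 1.7, -0.8, 0.9, -1.5, 0.2,
           1.1, -0.3, 0.7, -0.9, 0.4, 1.3, -0.6, 0.8, -1.1, 0.6))
}

# Small deterministic cohort for interface-level tests: a handful of genes
# with known structure, survival drawn from a seeded additive hazard.
toy_cohort <- function(n = 120, seed = 11, n_genes = 6) {
  set.seed(seed)
  mutation <- rbinom(n, 1, 0.3)
  fusion <- ifelse(mutation == 1, 0, rbinom(n, 1, 0.2))
  sex <- rbinom(n, 1, 0.5)
  age <- rnorm(n, 55, 8)
  cyto <- sample(c("favorable", "intermediate", "adverse"), n, TRUE,
                 prob = c(0.2, 0.6, 0.2))
  genes <- sprintf("G%02d", seq_len(n_genes))
  expr <- matrix(rnorm(n_genes * n, mean = 7), nrow = n_genes,
                 dimnames = list(genes, sprintf("S%03d", seq_len(n))))
  expr["G01", ] <- expr["G01", ] + 1.0 * mutation     # planted mediator gene
  lam <- 1 + 0.5 * mutation + 0.3 * (expr["G01", ] - mean(expr["G01", ]))
  lam[lam <= 0] <- 1e-6
  tt <- rexp(n, lam)
  cens <- pmin(rexp(n, 0.5), 3)
  clinical <- data.frame(
    sample_id = colnames(expr), time = pmax(pmin(tt, cens), 1e-8),
    event = as.numeric(tt <= cens), sex = sex, age = age,
    cytogenetics = cyto,
    runx1_mutation = ifelse(mutation == 1, "present", "absent"),
    fusion_t8_21 = ifelse(fusion == 1, "present", "absent"),
    stringsAsFactors = FALSE)
  cohort_dataset("toy", expr, clinical, platform = "toy")
}
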