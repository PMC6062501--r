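#' Survival design for the additive-hazards model
#'
#' Bundles a covariate matrix with right-censored survival outcomes and
#' validates the contract required by [fit_additive_hazards()]: no missing
#' values, strictly positive follow-up times, 0/1 event indicators, at least
#' one observed event, and a covariate matrix of full column rank (including
#' against the implicit baseline, so a constant column is rejected as
#' collinear).
#'
#' @param covariates Numeric matrix (samples x covariates) with column names.
#' @param time Positive follow-up times.
#' @param event Event indicators, 1 = event observed, 0 = censored.
#' @return An object of class `surv_design`.
#' @export
surv_design <- function(covariates, time, event) {
  covariates <- as.matrix(covariates)
  if (is.null(colnames(covariates))) {
    colnames(covariates) <- paste0("z", seq_len(ncol(covariates)))
  }
  storage.mode(covariates) <- "double"
  time <- as.numeric(time)
  event <- as.numeric(event)
  n <- length(time)
  if (nrow(covariates) != n || length(event) != n) {
    stopf("covariates, time and event must describe the same samples")
  }
  if (anyNA(covariates) || anyNA(time) || anyNA(event)) {
    stopf("missing values are not allowed in a survival design")
  }
  if (any(time <= 0)) stopf("all follow-up times must be > 0")
  if (!all(event %in% c(0, 1))) stopf("event indicators must be 0 or 1")
  if (sum(event) < 1) stopf("no events observed: the design carries no information")
  aug <- cbind(1, covariates)
  if (qr(aug)$rank < ncol(aug)) {
    stopf("covariate matrix is rank deficient (constant or collinear columns)")
  }
  structure(list(covariates = covariates, time = time, event = event),
            class = "surv_design")
}

# Closed-form Lin-Ying estimator for the time-constant additive-hazards
# model lambda(t | Z) = lambda0(t) + gamma' Z.
#
# With samples sorted by follow-up time x_1 <= ... <= x_n, the estimating
# equation U(gamma) = b - A gamma has
#   A = sum_i x_i Z_i Z_i'  -  sum_k (Delta_k / n_k) s_k s_k'
#   b = sum_{events} (Z_i - Zbar(x_i))
# where Delta_k = x_k - x_{k-1}, n_k = n - k + 1 is the size of the risk set
# on (x_{k-1}, x_k], s_k = sum_{j >= k} Z_j, and Zbar(x_i) averages Z over
# the risk set at x_i (ties handled in one Breslow-style block). The
# sandwich meat is B = sum_{events} (Z_i - Zbar)(Z_i - Zbar)'.
ah_core <- function(Z, time, event) {
  n <- nrow(Z)
  ord <- order(time)
  x <- time[ord]
  d <- event[ord]
  Zs <- Z[ord, , drop = FALSE]
  delta <- diff(c(0, x))
  nk <- n - seq_len(n) + 1
  w <- delta / nk
  S <- rev_cumsum_rows(Zs)
  A <- crossprod(Zs * sqrt(x)) - crossprod(S * sqrt(w))
  first <- match(x, x)                       # first index of each tied block
  ev <- which(d == 1)
  fe <- first[ev]
  rn <- nk[fe]                               # at-risk count at each event time
  Zc <- Zs[ev, , drop = FALSE] - S[fe, , drop = FALSE] / rn
  b <- colSums(Zc)
  B <- crossprod(Zc)
  list(A = A, b = b, B = B, ord = ord, x = x, d = d, delta = delta, nk = nk,
       S = S, first = first, ev = ev, fe = fe, rn = rn)
}

#' Fit the time-constant additive-hazards (Lin-Ying) model
#'
#' Estimates hazard-increment coefficients for
#' \eqn{\lambda(t \mid Z) = \lambda_0(t) + \gamma' Z} by the closed-form
#' solution \eqn{\hat\gamma = A^{-1} b} of the Lin-Ying estimating equation,
#' with a sandwich covariance \eqn{A^{-1} B A^{-1}} and the cumulative
#' baseline hazard evaluated at the distinct event times. Tied event times
#' are processed in a single risk-set update; the integration horizon is the
#' largest observed time.
#'
#' @param design A [surv_design()] object.
#' @return An object of class `additive_hazard_fit` with elements
#'   `coefficients`, `vcov`, `se`, `baseline` (data frame `time`, `cumhaz`),
#'   `n`, `n_events`.
#' @export
fit_additive_hazards <- function(design) {
  if (!inherits(design, "surv_design")) stopf("design must be a surv_design object")
  Z <- design$covariates
  core <- ah_core(Z, design$time, design$event)
  Ainv <- tryCatch(solve(core$A), error = function(e) NULL)
  if (is.null(Ainv) || !all(is.finite(Ainv)) || rcond(core$A) < 1e-12) {
    stopf("additive-hazards information matrix is singular (collinear covariates)")
  }
  coef <- drop(Ainv %*% core$b)
  names(coef) <- colnames(Z)
  V <- Ainv %*% core$B %*% Ainv
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(Z), colnames(Z))
  baseline <- ah_baseline(core, coef)
  structure(list(coefficients = coef, vcov = V, se = sqrt(pmax(diag(V), 0)),
                 baseline = baseline, n = nrow(Z), n_events = sum(design$event)),
            class = "additive_hazard_fit")
}

# Cumulative baseline hazard at the distinct event times:
#   Lambda0(t) = sum_{event times s <= t} dNbar(s)/Y(s) - gamma' int_0^t Zbar(s) ds
ah_baseline <- function(core, coef) {
  if (length(core$ev) == 0) {
    return(data.frame(time = numeric(0), cumhaz = numeric(0)))
  }
  # integral of the at-risk covariate average, accumulated over intervals
  Zbar_int <- apply(core$S / core$nk * core$delta, 2, cumsum)
  Zbar_int <- matrix(Zbar_int, nrow = length(core$x))
  etimes <- unique(core$x[core$ev])
  pos <- match(etimes, core$x)
  jumps <- vapply(pos, function(k) {
    sum(core$d[core$first == k]) / core$nk[k]
  }, numeric(1))
  na_part <- cumsum(jumps)
  reg_part <- drop(Zbar_int[pos, , drop = FALSE] %*% coef)
  data.frame(time = etimes, cumhaz = na_part - reg_part)
}

#' Cumulative baseline hazard for fixed coefficients
#'
#' Evaluates the additive-hazards cumulative baseline estimator at the
#' distinct event times for a supplied coefficient vector. With all
#' coefficients forced to zero this reduces exactly to the Nelson-Aalen
#' estimator.
#'
#' @param design A [surv_design()] object.
#' @param coefficients Coefficient vector (one per design covariate).
#' @return Data frame with columns `time` and `cumhaz`.
#' @export
cumulative_baseline_hazard <- function(design, coefficients) {
  if (!inherits(design, "surv_design")) stopf("design must be a surv_design object")
  if (length(coefficients) != ncol(design$covariates)) {
    stopf("need one coefficient per covariate")
  }
  core <- ah_core(design$covariates, design$time, design$event)
  ah_baseline(core, as.numeric(coefficients))
}

#' @export
print.additive_hazard_fit <- function(x, ...) {
  cat(sprintf("Additive-hazards fit: %d samples, %d events\n", x$n, x$n_events))
  z <- x$coefficients / x$se
  tab <- data.frame(estimate = x$coefficients, se = x$se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  print(tab, digits = 4)
  invisible(x)
}

#' Direction of the exposure's total effect on the hazard
#'
#' Fits the additive-hazards model with exposure and confounders (no
#' mediator) on the samples selected by a comparison and returns the sign of
#' the exposure coefficient: `+1` means the exposure raises the hazard
#' (harmful, e.g. a RUNX1 point mutation), `-1` that it lowers it
#' (protective, e.g. the RUNX1/RUNX1T1 fusion).
#'
#' @param cohort A `cohort_dataset`.
#' @param comparison A [comparison_spec()] or a comparison name.
#' @param confounders Clinical confounders to adjust for.
#' @return `+1` or `-1`.
#' @export
total_effect_sign <- function(cohort, comparison,
                              confounders = c("sex", "age", "cytogenetics")) {
  sub <- comparison_subset(cohort, comparison)
  W <- cbind(exposure = sub$exposure,
             confounder_matrix(sub$clinical, confounders))
  fit <- fit_additive_hazards(surv_design(W, sub$clinical$time, sub$clinical$event))
  unname(ifelse(fit$coefficients["exposure"] >= 0, 1, -1))
}

# Encode clinical confounders as a numeric design matrix. Cytogenetic risk
# uses reference-level indicator coding with "intermediate" as reference;
# age is centered at 55 years so hazard intercepts stay interpretable.
confounder_matrix <- function(clinical, confounders) {
  if (is.null(confounders) || length(confounders) == 0) {
    return(matrix(numeric(0), nrow = nrow(clinical), ncol = 0))
  }
  cols <- list()
  for (v in confounders) {
    if (v == "sex") {
      cols$sex <- as.numeric(clinical$sex)
    } else if (v == "age") {
      cols$age <- as.numeric(clinical$age) - 55
    } else if (v == "cytogenetics") {
      cyto <- as.character(clinical$cytogenetics)
      cols$cyto_favorable <- as.numeric(cyto == "favorable")
      cols$cyto_adverse <- as.numeric(cyto == "adverse")
    } else {
      if (!v %in% names(clinical)) stopf("unknown confounder '%s'", v)
      cols[[v]] <- as.numeric(clinical[[v]])
    }
  }
  do.call(cbind, cols)
}
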