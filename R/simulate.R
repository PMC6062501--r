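#' Configuration for the synthetic multi-cohort generator
#'
#' Describes a simulated multi-cohort AML-like study with planted mediation
#' structure. Genes fall into five classes: `supporting_mediator` (exposure
#' shifts expression and expression shifts the hazard, with the product
#' concordant with the exposure's direct effect), `opposing_mediator`
#' (discordant product), `de_only` (expression shift, no hazard effect),
#' `prognostic_only` (hazard effect, no expression shift) and `null`.
#' Alterations (RUNX1-like point mutation vs RUNX1/RUNX1T1-like fusion) are
#' strictly mutually exclusive by default; mediator genes respond with
#' opposite signs to the two alterations (a shared-mechanism response, as
#' for genes up-regulated by the harmful mutation and down-regulated by the
#' protective fusion). Survival is drawn from a time-constant additive
#' hazard, which makes event times exponential given covariates.
#'
#' Defaults state a two-cohort screening world of 1000 genes and 400
#' samples per cohort with 15 supporting mediators. `baseline_hazard` and
#' `direct_effect` defaults are chosen once so the additive hazard stays
#' positive (clamping below the 0.5% error budget) and so the net total
#' effect of each alteration keeps its stated direction (mutation harmful,
#' fusion protective) after summing the planted indirect effects; see the
#' methods vignette for the arithmetic.
#'
#' @param n_cohorts Number of cohorts.
#' @param n_samples_per_cohort Samples per cohort.
#' @param n_genes Number of genes.
#' @param class_fractions Named proportions over the five gene classes;
#'   must sum to 1.
#' @param alteration_probs Named proportions over `none`, `mutation`,
#'   `fusion`; must sum to 1.
#' @param a_effect Exposure-to-expression shift for the mutation, in
#'   within-gene SD units (the fusion response is the negated shift).
#' @param b_effect Expression-to-hazard slope magnitude, hazard units per SD.
#' @param baseline_hazard Baseline event rate, events per time unit.
#' @param direct_effect Hazard increment of the mutation not running through
#'   any gene (the fusion's direct increment is its negation).
#' @param confounder_effects List with numeric vectors `expression` and
#'   `hazard`, each with elements `sex`, `age` (per year, age centered at
#'   55), `cyto_favorable`, `cyto_adverse`.
#' @param batch_sd SD of cohort-specific per-gene location shifts.
#' @param batch_scale_sd SD of cohort-specific per-gene log noise-scale
#'   factors.
#' @param censoring_rate Rate of independent exponential censoring.
#' @param admin_censor_time Administrative follow-up horizon.
#' @param cyto_favorable_given_fusion Probability that a fusion sample has
#'   favorable cytogenetics (creates the cytogenetics confounding the test
#'   must adjust away).
#' @param mutation_fusion_overlap Probability that a mutation sample also
#'   carries the fusion; 0 (default) keeps the alterations strictly
#'   exclusive.
#' @param seed Master RNG seed.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_cohorts = 2,
                       n_samples_per_cohort = 400,
                       n_genes = 1000,
                       class_fractions = c(supporting_mediator = 0.015,
                                           opposing_mediator = 0.05,
                                           de_only = 0.05,
                                           prognostic_only = 0.05,
                                           null = 0.835),
                       alteration_probs = c(none = 0.85, mutation = 0.10,
                                            fusion = 0.05),
                       a_effect = 0.8,
                       b_effect = 0.3,
                       baseline_hazard = 12,
                       direct_effect = 10,
                       confounder_effects = list(
                         expression = c(sex = 0.2, age = 0.01,
                                        cyto_favorable = -0.3,
                                        cyto_adverse = 0.3),
                         hazard = c(sex = 0.2, age = 0.02,
                                    cyto_favorable = -0.5,
                                    cyto_adverse = 0.5)),
                       batch_sd = 0.5,
                       batch_scale_sd = 0.1,
                       censoring_rate = 2,
                       admin_censor_time = 2,
                       cyto_favorable_given_fusion = 0.9,
                       mutation_fusion_overlap = 0,
                       seed = 1) {
  classes <- c("supporting_mediator", "opposing_mediator", "de_only",
               "prognostic_only", "null")
  if (!setequal(names(class_fractions), classes)) {
    stopf("class_fractions must be named over: %s", paste(classes, collapse = ", "))
  }
  class_fractions <- class_fractions[classes]
  if (any(class_fractions < 0 | class_fractions > 1) ||
      abs(sum(class_fractions) - 1) > 1e-8) {
    stopf("class_fractions must lie in [0,1] and sum to 1")
  }
  if (!setequal(names(alteration_probs), c("none", "mutation", "fusion"))) {
    stopf("alteration_probs must be named over none, mutation, fusion")
  }
  alteration_probs <- alteration_probs[c("none", "mutation", "fusion")]
  if (any(alteration_probs < 0) || abs(sum(alteration_probs) - 1) > 1e-8) {
    stopf("alteration_probs must be nonnegative and sum to 1")
  }
  if (n_cohorts < 1 || n_samples_per_cohort < 1 || n_genes < 1) {
    stopf("n_cohorts, n_samples_per_cohort and n_genes must be positive")
  }
  if (baseline_hazard <= 0) stopf("baseline_hazard must be > 0")
  if (admin_censor_time <= 0) stopf("admin_censor_time must be > 0")
  if (censoring_rate < 0) stopf("censoring_rate must be >= 0")
  if (mutation_fusion_overlap < 0 || mutation_fusion_overlap > 1) {
    stopf("mutation_fusion_overlap must be in [0,1]")
  }
  structure(list(n_cohorts = as.integer(n_cohorts),
                 n_samples_per_cohort = as.integer(n_samples_per_cohort),
                 n_genes = as.integer(n_genes),
                 class_fractions = class_fractions,
                 alteration_probs = alteration_probs,
                 a_effect = a_effect, b_effect = b_effect,
                 baseline_hazard = baseline_hazard,
                 direct_effect = direct_effect,
                 confounder_effects = confounder_effects,
                 batch_sd = batch_sd, batch_scale_sd = batch_scale_sd,
                 censoring_rate = censoring_rate,
                 admin_censor_time = admin_censor_time,
                 cyto_favorable_given_fusion = cyto_favorable_given_fusion,
                 mutation_fusion_overlap = mutation_fusion_overlap,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate the per-gene truth table
#'
#' Assigns gene classes by largest-remainder rounding of the configured
#' class fractions, draws per-gene effect signs, and records the true
#' exposure-to-expression effects for both alterations (the fusion response
#' is the negated mutation response), the true expression-to-hazard slope,
#' gene baselines, and per-comparison supporting flags. Supporting
#' mediators have \eqn{sign(a b)} concordant with the direct effect's sign
#' for each exposure; opposing mediators are discordant. Null genes have
#' a = b = 0. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return Data frame of class `truth_table`: `gene`, `class`, `baseline`,
#'   `a_mutation`, `a_fusion`, `b`, `supporting_mutation`,
#'   `supporting_fusion`.
#' @export
generate_truth <- function(config) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  G <- config$n_genes
  frac <- config$class_fractions
  raw <- frac * G
  counts <- floor(raw)
  rem <- G - sum(counts)
  if (rem > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(rem)]] <- counts[order_rem[seq_len(rem)]] + 1
  }
  cls <- rep(names(counts), counts)
  with_seed(derive_seed(config$seed, 1), {
    cls <- sample(cls)
    gene <- sprintf("G%04d", seq_len(G))
    baseline <- stats::rnorm(G, mean = 7, sd = 1.5)
    sgn <- sample(c(-1, 1), G, replace = TRUE)
    a_mut <- numeric(G); b <- numeric(G)
    d_sign <- sign(config$direct_effect)
    if (d_sign == 0) d_sign <- 1
    is_sup <- cls == "supporting_mediator"
    is_opp <- cls == "opposing_mediator"
    is_de <- cls == "de_only"
    is_prog <- cls == "prognostic_only"
    a_mut[is_sup | is_opp | is_de] <- config$a_effect * sgn[is_sup | is_opp | is_de]
    # supporting: sign(a*b) = sign(direct); opposing: sign(a*b) = -sign(direct)
    b[is_sup] <- d_sign * config$b_effect * sgn[is_sup]
    b[is_opp] <- -d_sign * config$b_effect * sgn[is_opp]
    b[is_prog] <- config$b_effect * sgn[is_prog]
    truth <- data.frame(gene = gene, class = cls, baseline = baseline,
                        a_mutation = a_mut, a_fusion = -a_mut, b = b,
                        stringsAsFactors = FALSE)
    # Supporting flag per comparison: mutation total direction is
    # +sign(direct), fusion total direction is -sign(direct).
    truth$supporting_mutation <- truth$a_mutation * truth$b * d_sign > 0
    truth$supporting_fusion <- truth$a_fusion * truth$b * (-d_sign) > 0
    class(truth) <- c("truth_table", "data.frame")
    truth
  })
}

# Draw alteration status, confounders and clinical covariates for one cohort.
draw_clinical <- function(config, n, cohort_id) {
  alt <- sample(c("none", "mutation", "fusion"), n, replace = TRUE,
                prob = config$alteration_probs)
  mutation <- ifelse(alt == "mutation", "present", "absent")
  fusion <- ifelse(alt == "fusion", "present", "absent")
  if (config$mutation_fusion_overlap > 0) {
    both <- alt == "mutation" &
      stats::runif(n) < config$mutation_fusion_overlap
    fusion[both] <- "present"
  }
  sex <- stats::rbinom(n, 1, 0.5)
  age <- stats::rnorm(n, mean = 55, sd = 10)
  pf <- config$cyto_favorable_given_fusion
  cyto_probs <- list(
    fusion = c(favorable = pf, intermediate = (1 - pf) * 0.8,
               adverse = (1 - pf) * 0.2),
    mutation = c(favorable = 0.05, intermediate = 0.60, adverse = 0.35),
    none = c(favorable = 0.15, intermediate = 0.65, adverse = 0.20))
  grp <- ifelse(fusion == "present", "fusion",
                ifelse(mutation == "present", "mutation", "none"))
  cyto <- character(n)
  for (g in names(cyto_probs)) {
    idx <- which(grp == g)
    if (length(idx) > 0) {
      cyto[idx] <- sample(names(cyto_probs[[g]]), length(idx), replace = TRUE,
                          prob = cyto_probs[[g]])
    }
  }
  data.frame(sample_id = sprintf("%s_S%04d", cohort_id, seq_len(n)),
             time = NA_real_, event = NA_real_, sex = sex, age = age,
             cytogenetics = cyto, runx1_mutation = mutation,
             fusion_t8_21 = fusion, stringsAsFactors = FALSE)
}

#' Generate one synthetic cohort
#'
#' Expression for gene g, sample i is
#' \deqn{M_{gi} = baseline_g + a_g^{mut} E_i + a_g^{fus} F_i + c' C_i +
#'       shift_{g,cohort} + scale_{g,cohort}\,\varepsilon_{gi}}
#' with standard normal noise, and the additive hazard is
#' \deqn{\lambda_i = \lambda_0 + d\,E_i - d\,F_i +
#'       \sum_g b_g (M_{gi} - baseline_g^{tot}) + c_h' C_i,}
#' where the mediator enters as its deviation from the gene's cohort-level
#' baseline (gene baselines and batch shifts are absorbed into the baseline
#' hazard, not the gene effect). Event times are exponential with rate
#' \eqn{\lambda_i}; censoring is the minimum of an independent exponential
#' and the administrative horizon. Hazards that come out nonpositive are
#' clamped to 1e-6; if more than 0.5% of samples need clamping the
#' generator stops with a simulation error, keeping it honest about
#' model-compatible parameter ranges.
#'
#' @param config A [sim_config()].
#' @param truth A [generate_truth()] table for the same config.
#' @param cohort_index Cohort number, `1..n_cohorts`.
#' @return A `cohort_dataset`: list with `cohort_id`, `expression`
#'   (genes x samples), `clinical`, `platform`.
#' @export
generate_cohort <- function(config, truth, cohort_index) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  if (cohort_index < 1 || cohort_index > config$n_cohorts) {
    stopf("cohort_index must be in 1..n_cohorts")
  }
  n <- config$n_samples_per_cohort
  G <- config$n_genes
  cohort_id <- sprintf("cohort_%d", cohort_index)
  with_seed(derive_seed(config$seed, 100 + cohort_index), {
    clinical <- draw_clinical(config, n, cohort_id)
    E <- as.numeric(clinical$runx1_mutation == "present")
    F_ <- as.numeric(clinical$fusion_t8_21 == "present")
    ce <- config$confounder_effects$expression
    ch <- config$confounder_effects$hazard
    conf_expr <- ce["sex"] * clinical$sex + ce["age"] * (clinical$age - 55) +
      ce["cyto_favorable"] * (clinical$cytogenetics == "favorable") +
      ce["cyto_adverse"] * (clinical$cytogenetics == "adverse")
    conf_haz <- ch["sex"] * clinical$sex + ch["age"] * (clinical$age - 55) +
      ch["cyto_favorable"] * (clinical$cytogenetics == "favorable") +
      ch["cyto_adverse"] * (clinical$cytogenetics == "adverse")

    shift <- stats::rnorm(G, 0, config$batch_sd)
    scale <- exp(stats::rnorm(G, 0, config$batch_scale_sd))
    noise <- matrix(stats::rnorm(G * n), nrow = G) * scale
    mean_part <- truth$baseline + shift +
      outer(truth$a_mutation, E) + outer(truth$a_fusion, F_)
    expr <- mean_part + matrix(conf_expr, nrow = G, ncol = n, byrow = TRUE) + noise
    rownames(expr) <- truth$gene
    colnames(expr) <- clinical$sample_id

    # hazard responds to deviations of expression from the cohort-level
    # gene baseline (baseline + batch shift)
    active <- which(truth$b != 0)
    med_part <- if (length(active) > 0) {
      drop(crossprod(expr[active, , drop = FALSE] -
                       (truth$baseline + shift)[active], truth$b[active]))
    } else rep(0, n)
    lambda <- config$baseline_hazard + config$direct_effect * E -
      config$direct_effect * F_ + med_part + conf_haz
    clamped <- lambda <= 0
    if (mean(clamped) > 0.005) {
      stopf(paste("simulation error: %.1f%% of samples have nonpositive hazard;",
                  "parameters are outside the additive model's range"),
            100 * mean(clamped))
    }
    lambda[clamped] <- 1e-6
    tt <- stats::rexp(n, rate = lambda)
    cens <- if (config$censoring_rate > 0) {
      pmin(stats::rexp(n, rate = config$censoring_rate), config$admin_censor_time)
    } else rep(config$admin_censor_time, n)
    clinical$time <- pmax(pmin(tt, cens), 1e-10)
    clinical$event <- as.numeric(tt <= cens)
    structure(list(cohort_id = cohort_id, expression = expr,
                   clinical = clinical,
                   platform = sprintf("synthetic_platform_%d", cohort_index)),
              class = "cohort_dataset")
  })
}

#' Generate a full multi-cohort study
#'
#' One shared truth table, cohort-specific batch shifts and noise-scale
#' factors, disjoint samples across cohorts. Deterministic given the config
#' seed.
#'
#' @param config A [sim_config()].
#' @return List with elements `cohorts` (named list of `cohort_dataset`) and
#'   `truth`.
#' @export
generate_study <- function(config) {
  truth <- generate_truth(config)
  cohorts <- lapply(seq_len(config$n_cohorts), function(k) {
    generate_cohort(config, truth, k)
  })
  names(cohorts) <- vapply(cohorts, function(co) co$cohort_id, character(1))
  list(cohorts = cohorts, truth = truth)
}

#' Generate synthetic gene sets with one planted enriched set
#'
#' Local stand-in for a pathway annotation database: `n_sets` gene sets over
#' the truth table's gene universe, where the first ("designated") set draws
#' each member from the supporting-mediator genes with probability
#' `enrichment` and uniformly otherwise; the remaining sets are uniform
#' draws.
#'
#' @param truth A [generate_truth()] table.
#' @param n_sets Number of sets.
#' @param set_size Genes per set (must not exceed the universe size).
#' @param enrichment Probability in `[0,1]` that a designated-set member is
#'   sampled from the supporting mediators.
#' @param seed RNG seed.
#' @return A `gene_set_collection` (see [read_gmt()]); the planted set is
#'   named `PLANTED_MEDIATOR_SET`.
#' @export
generate_genesets <- function(truth, n_sets = 10, set_size = 20,
                              enrichment = 0.5, seed = 1) {
  if (enrichment < 0 || enrichment > 1) stopf("enrichment must be in [0,1]")
  if (set_size > nrow(truth)) stopf("set_size exceeds the number of genes")
  universe <- truth$gene
  mediators <- truth$gene[truth$class == "supporting_mediator"]
  others <- setdiff(universe, mediators)
  with_seed(seed, {
    sets <- vector("list", n_sets)
    n_med <- stats::rbinom(1, set_size, enrichment)
    n_med <- min(n_med, length(mediators))
    sets[[1]] <- c(sample(mediators, n_med),
                   sample(others, set_size - n_med))
    for (s in seq_len(n_sets)[-1]) {
      sets[[s]] <- sample(universe, set_size)
    }
    names(sets) <- c("PLANTED_MEDIATOR_SET",
                     sprintf("RANDOM_SET_%02d", seq_len(n_sets)[-1]))
    gene_set_collection(sets, universe)
  })
}

#' Score a screening result against the planted truth
#'
#' Sensitivity is the fraction of planted supporting mediators (for the
#' screened comparison) present in the validated list; the realized
#' false-discovery proportion is the fraction of validated genes that are
#' not planted supporting mediators (0 for an empty list, by convention).
#' Leak counts report validated genes per planted class.
#'
#' @param validated Character vector of validated gene ids (or a
#'   `screening_result` comparison's validation table).
#' @param truth A [generate_truth()] table.
#' @param comparison `"mutation"` or `"fusion"`: which supporting flag
#'   defines the target set.
#' @return List with `sensitivity`, `fdp`, `n_validated`, `leaks` (named
#'   vector of validated counts per class).
#' @export
evaluate_against_truth <- function(validated, truth, comparison = "mutation") {
  if (is.data.frame(validated)) {
    validated <- validated$gene[validated$significant]
  }
  unknown <- setdiff(validated, truth$gene)
  if (length(unknown) > 0) {
    stopf("unknown gene ids: %s", paste(unknown, collapse = ", "))
  }
  flag <- switch(comparison,
                 mutation = truth$supporting_mutation,
                 fusion = truth$supporting_fusion,
                 stopf("comparison must be 'mutation' or 'fusion'"))
  target <- truth$gene[flag]
  hits <- intersect(validated, target)
  sens <- if (length(target) == 0) NA_real_ else length(hits) / length(target)
  fdp <- if (length(validated) == 0) 0 else
    length(setdiff(validated, target)) / length(validated)
  leaks <- table(factor(truth$class[match(validated, truth$gene)],
                        levels = unique(truth$class)))
  list(sensitivity = sens, fdp = fdp, n_validated = length(validated),
       leaks = c(leaks))
}
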