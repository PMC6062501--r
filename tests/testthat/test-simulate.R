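test_that("truth table respects class fractions, rounding and null zeros", {
  cfg <- sim_config(n_genes = 1000, seed = 4)
  truth <- generate_truth(cfg)
  expect_equal(sum(truth$class == "supporting_mediator"), 15)
  expect_equal(sum(truth$class == "opposing_mediator"), 50)
  expect_equal(sum(truth$class == "de_only"), 50)
  expect_equal(sum(truth$class == "prognostic_only"), 50)
  expect_true(all(truth$a_mutation[truth$class == "null"] == 0))
  expect_true(all(truth$b[truth$class == "null"] == 0))
  # supporting flags: sign(a*b) concordant with each exposure's total direction
  sup <- truth$class == "supporting_mediator"
  expect_true(all(truth$a_mutation[sup] * truth$b[sup] > 0))
  expect_true(all(truth$supporting_mutation[sup]))
  expect_true(all(truth$supporting_fusion[sup]))
  opp <- truth$class == "opposing_mediator"
  expect_true(all(truth$a_mutation[opp] * truth$b[opp] < 0))
  expect_false(any(truth$supporting_mutation[opp]))
})

test_that("degenerate all-null mixture yields only null genes", {
  cfg <- sim_config(n_genes = 50,
                    class_fractions = c(supporting_mediator = 0,
                                        opposing_mediator = 0, de_only = 0,
                                        prognostic_only = 0, null = 1))
  truth <- generate_truth(cfg)
  expect_true(all(truth$class == "null"))
  expect_true(all(truth$a_mutation == 0 & truth$b == 0))
})

test_that("generation is deterministic given config + seed", {
  cfg <- sim_config(n_genes = 60, n_samples_per_cohort = 50, seed = 9,
                    baseline_hazard = 6, direct_effect = 2)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
})

test_that("mutation and fusion are strictly exclusive by default", {
  cfg <- sim_config(n_genes = 20, n_samples_per_cohort = 800, seed = 2,
                    baseline_hazard = 6, direct_effect = 2)
  study <- generate_study(cfg)
  for (co in study$cohorts) {
    both <- co$clinical$runx1_mutation == "present" &
      co$clinical$fusion_t8_21 == "present"
    expect_false(any(both))
  }
})

test_that("null effects give no exposure-group expression differences", {
  cfg <- sim_config(n_genes = 200, n_samples_per_cohort = 600, n_cohorts = 1,
                    a_effect = 0, b_effect = 0, batch_sd = 0,
                    baseline_hazard = 2, direct_effect = 0, seed = 31)
  study <- generate_study(cfg)
  co <- study$cohorts[[1]]
  e <- co$clinical$runx1_mutation == "present"
  diff <- rowMeans(co$expression[, e, drop = FALSE]) -
    rowMeans(co$expression[, !e, drop = FALSE])
  mc_se <- sqrt(1 / sum(e) + 1 / sum(!e))
  expect_true(all(abs(diff) < 3.9 * mc_se))   # 200 genes, 3.9 SE ~ genomewide
})

test_that("exposure shift of supporting mediators matches a_effect", {
  cfg <- sim_config(n_genes = 400, n_samples_per_cohort = 2000, n_cohorts = 1,
                    class_fractions = c(supporting_mediator = 0.05,
                                        opposing_mediator = 0, de_only = 0,
                                        prognostic_only = 0, null = 0.95),
                    a_effect = 0.8, b_effect = 0.1, baseline_hazard = 4,
                    direct_effect = 1, batch_sd = 0, seed = 17)
  study <- generate_study(cfg)
  co <- study$cohorts[[1]]
  truth <- study$truth
  e <- co$clinical$runx1_mutation == "present"
  sup <- truth$gene[truth$class == "supporting_mediator"]
  signed <- sign(truth$a_mutation[match(sup, truth$gene)])
  shift <- (rowMeans(co$expression[sup, e, drop = FALSE]) -
              rowMeans(co$expression[sup, !e, drop = FALSE])) * signed
  mc_se <- sqrt(1 / sum(e) + 1 / sum(!e))
  expect_true(all(abs(shift - 0.8) < 3.5 * mc_se))
})

test_that("zero censoring with a huge horizon gives all events", {
  cfg <- sim_config(n_genes = 10, n_samples_per_cohort = 300, n_cohorts = 1,
                    censoring_rate = 0, admin_censor_time = 1e9,
                    baseline_hazard = 3, direct_effect = 1, seed = 5)
  study <- generate_study(cfg)
  expect_true(all(study$cohorts[[1]]$clinical$event == 1))
})

test_that("direct effect is recovered by the additive-hazards fit at n = 2000", {
  cfg <- sim_config(n_genes = 5, n_samples_per_cohort = 2000, n_cohorts = 1,
                    class_fractions = c(supporting_mediator = 0,
                                        opposing_mediator = 0, de_only = 1,
                                        prognostic_only = 0, null = 0),
                    a_effect = 0.5, b_effect = 0, baseline_hazard = 2,
                    direct_effect = 0.8, seed = 77)
  study <- generate_study(cfg)
  co <- study$cohorts[[1]]
  sub <- survmedscreen:::comparison_subset(co, "mutation_vs_no_mutation")
  W <- cbind(exposure = sub$exposure,
             survmedscreen:::confounder_matrix(sub$clinical,
                                               c("sex", "age", "cytogenetics")))
  fit <- fit_additive_hazards(surv_design(W, sub$clinical$time, sub$clinical$event))
  expect_lt(abs(fit$coefficients["exposure"] - 0.8), 2 * fit$se["exposure"])
})

test_that("batch shifts inflate between-cohort gene means as configured", {
  base <- list(n_genes = 150, n_samples_per_cohort = 400, n_cohorts = 3,
               baseline_hazard = 6, direct_effect = 2, seed = 13)
  cfg0 <- do.call(sim_config, c(base, list(batch_sd = 0, batch_scale_sd = 0)))
  cfg1 <- do.call(sim_config, c(base, list(batch_sd = 1.0)))
  s0 <- generate_study(cfg0)
  s1 <- generate_study(cfg1)
  between_var <- function(study) {
    means <- sapply(study$cohorts, function(co) rowMeans(co$expression))
    mean(apply(means, 1, var))
  }
  expect_lt(between_var(s0), 0.05)          # Monte-Carlo noise only
  expect_gt(between_var(s1), 0.5)           # exceeds batch_sd^2 / 2
})

test_that("incompatible hazard parameters raise a simulation error", {
  cfg <- sim_config(n_genes = 100, n_samples_per_cohort = 300, n_cohorts = 1,
                    class_fractions = c(supporting_mediator = 0.5,
                                        opposing_mediator = 0, de_only = 0,
                                        prognostic_only = 0, null = 0.5),
                    b_effect = 1, baseline_hazard = 0.5, direct_effect = 0.1,
                    seed = 3)
  expect_error(generate_study(cfg), "nonpositive hazard")
})

test_that("planted gene sets are recovered by the hypergeometric ORA", {
  cfg <- sim_config(n_genes = 500, seed = 23)
  truth <- generate_truth(cfg)
  gs <- generate_genesets(truth, n_sets = 8, set_size = 15, enrichment = 0.8,
                          seed = 41)
  mediators <- truth$gene[truth$class == "supporting_mediator"]
  res <- ora_hypergeometric(mediators, truth$gene, gs)
  expect_equal(res$set[1], "PLANTED_MEDIATOR_SET")
  expect_lt(res$p[1], min(res$p[-1]))
  # enrichment = 1 with a small set: designated set is all mediators
  gs1 <- generate_genesets(truth, n_sets = 3, set_size = 5, enrichment = 1,
                           seed = 42)
  expect_true(all(gs1$sets$PLANTED_MEDIATOR_SET %in% mediators))
})

test_that("evaluation metrics agree with hand set arithmetic", {
  cfg <- sim_config(n_genes = 100, seed = 8)
  truth <- generate_truth(cfg)
  sup <- truth$gene[truth$supporting_mutation]
  other <- setdiff(truth$gene, sup)[1:3]
  validated <- c(sup[1], other)
  m <- evaluate_against_truth(validated, truth, "mutation")
  expect_equal(m$sensitivity, 1 / length(sup))
  expect_equal(m$fdp, 3 / 4)
  expect_equal(m$n_validated, 4)
  m0 <- evaluate_against_truth(character(0), truth, "mutation")
  expect_equal(m0$sensitivity, 0)
  expect_equal(m0$fdp, 0)
  m1 <- evaluate_against_truth(sup, truth, "mutation")
  expect_equal(m1$sensitivity, 1)
  expect_equal(m1$fdp, 0)
  expect_error(evaluate_against_truth("NOT_A_GENE", truth), "unknown gene")
})
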