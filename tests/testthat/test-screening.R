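# One feasible screening world used across these tests: a mutation-only
# exposure, 5 supporting mediators with strong effects among 1000 genes,
# and a baseline hazard about 3.3 SD above the covariate hazard spread so
# the additive model stays positive.
screen_world <- function(seed) {
  sim_config(n_genes = 1000, n_samples_per_cohort = 800, n_cohorts = 2,
             class_fractions = c(supporting_mediator = 0.005,
                                 opposing_mediator = 0.002, de_only = 0.05,
                                 prognostic_only = 0.002, null = 0.941),
             alteration_probs = c(none = 0.8, mutation = 0.2, fusion = 0),
             a_effect = 0.8, b_effect = 0.5, baseline_hazard = 5,
             direct_effect = 1, seed = seed)
}

test_that("BH adjustment reproduces the step-up hand examples", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.05, 10)), rep(0.05, 10))
  expect_equal(bh_adjust(c(0.04, 0.01, 0.02, 0.03)), rep(0.04, 4))  # order kept
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("comparison subsets follow the Venn logic on alteration flags", {
  expr <- matrix(rnorm(5 * 8, 7), nrow = 5,
                 dimnames = list(paste0("G", 1:5), paste0("S", 1:8)))
  clin <- data.frame(
    sample_id = paste0("S", 1:8), time = c(1, 2, 3, 4, 2, 1, 3, 2),
    event = c(1, 0, 1, 1, 1, 0, 1, 1), sex = rep(0:1, 4),
    age = rnorm(8, 55), cytogenetics = "intermediate",
    runx1_mutation = c("present", "absent", "absent", "missing",
                       "present", "absent", "absent", "present"),
    fusion_t8_21 = c("absent", "present", "absent", "present",
                     "absent", "missing", "present", "absent"),
    stringsAsFactors = FALSE)
  co <- cohort_dataset("c1", expr, clin)
  s3 <- survmedscreen:::comparison_subset(co, "fusion_only_vs_mutation_only")
  # retained: fusion-only S2, S7; mutation-only S1, S5, S8; excluded:
  # S3 (neither), S4 (mutation missing), S6 (fusion missing)
  expect_setequal(s3$clinical$sample_id, c("S1", "S2", "S5", "S7", "S8"))
  expect_equal(sum(s3$exposure == 1), 2)   # fusion-only arm
  expect_equal(sum(s3$exposure == 0), 3)   # mutation-only arm

  s1 <- survmedscreen:::comparison_subset(co, "fusion_vs_no_fusion")
  expect_setequal(s1$clinical$sample_id,
                  c("S1", "S2", "S3", "S4", "S5", "S7", "S8"))

  clin_nofus <- clin; clin_nofus$fusion_t8_21 <- "absent"
  co2 <- cohort_dataset("c2", expr, clin_nofus)
  expect_error(survmedscreen:::comparison_subset(co2, "fusion_vs_no_fusion"),
               "exposed arm is empty")
})

test_that("pre-selection applies the direction filter and a strict threshold", {
  results <- data.frame(gene = paste0("G", 1:5),
                        p = c(0.04, 0.04, 0.06, 0.05, 0.001),
                        direction = c("supporting", "opposing", "supporting",
                                      "supporting", "supporting"),
                        stringsAsFactors = FALSE)
  kept <- preselect_genes(results, alpha = 0.05)
  expect_equal(as.character(kept), c("G5", "G1"))   # ordered by p; G4 at exactly 0.05 dropped
  expect_equal(attr(kept, "n_p_below"), 3)
  expect_warning(out <- preselect_genes(results[0, ]), "empty")
  expect_length(out, 0)
})

test_that("null-simulated screens keep at most the nominal fraction at pre-selection", {
  cfg <- sim_config(n_genes = 2000, n_samples_per_cohort = 400, n_cohorts = 1,
                    class_fractions = c(supporting_mediator = 0,
                                        opposing_mediator = 0, de_only = 0,
                                        prognostic_only = 0, null = 1),
                    baseline_hazard = 1.6, direct_effect = 0.3, seed = 88)
  study <- generate_study(cfg)
  res <- mediation_test_all(study$cohorts[[1]], "mutation_vs_no_mutation")
  kept <- preselect_genes(res, 0.05)
  # the product test is conservative under the complete null, so the kept
  # fraction sits at or below alpha * P(supporting); bound from above only
  frac <- length(kept) / nrow(res)
  expect_lte(frac, 0.025 + 3 * sqrt(0.025 * 0.975 / nrow(res)))
})

test_that("validation contracts: empty input, BH family, nesting", {
  study <- generate_study(screen_world(12))
  spec <- comparison_spec("mutation_vs_no_mutation", "cohort_2", "cohort_1")

  empty <- validate_genes(study$cohorts$cohort_1, character(0), spec)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "bh_family_size"), 0L)

  pre_res <- mediation_test_all(study$cohorts$cohort_2, spec)
  preselected <- preselect_genes(pre_res, 0.05)
  val <- validate_genes(study$cohorts$cohort_1, preselected, spec)
  expect_true(all(val$gene %in% preselected))                  # nesting
  expect_equal(attr(val, "bh_family_size"), sum(!is.na(val$p_adj)))
  expect_true(all(val$p_adj >= val$p - 1e-12, na.rm = TRUE))   # adjusted >= raw
  expect_true(all(val$gene[val$significant] %in% preselected))

  # a pre-selected gene absent from the validation cohort is untested and
  # excluded from the BH family
  co_small <- study$cohorts$cohort_1
  keep_genes <- setdiff(rownames(co_small$expression), preselected[1])
  co_small$expression <- co_small$expression[keep_genes, , drop = FALSE]
  val2 <- validate_genes(co_small, preselected, spec)
  expect_equal(attr(val2, "untested"), preselected[1])
  expect_false(preselected[1] %in% val2$gene)

  # no pre-selected gene measured at all: empty table, empty BH family
  co_none <- study$cohorts$cohort_1
  keep_none <- setdiff(rownames(co_none$expression), preselected)
  co_none$expression <- co_none$expression[keep_none, , drop = FALSE]
  expect_warning(val3 <- validate_genes(co_none, preselected, spec),
                 "none of the pre-selected")
  expect_equal(nrow(val3), 0)
  expect_equal(attr(val3, "bh_family_size"), 0L)
})

test_that("the screen recovers planted mediators in a feasible world without leakage", {
  study <- generate_study(screen_world(5))
  spec <- comparison_spec("mutation_vs_no_mutation", "cohort_2", "cohort_1")
  scr <- run_screen(study$cohorts, list(spec))
  cmp <- scr$comparisons$mutation_vs_no_mutation
  expect_equal(cmp$status, "ok")
  truth <- study$truth
  planted <- truth$gene[truth$class == "supporting_mediator"]
  # pre-selection should catch most planted mediators
  expect_gte(length(intersect(cmp$preselected, planted)), 4)
  ev <- evaluate_against_truth(cmp$validation_table, truth, "mutation")
  expect_gte(ev$sensitivity, 0.6)           # this seed validates 4 of 5
  expect_equal(ev$fdp, 0)
  expect_equal(unname(ev$leaks["opposing_mediator"]), 0L)
  expect_equal(unname(ev$leaks["de_only"]), 0L)
})

test_that("run_screen equals the manual stage-by-stage composition and is deterministic", {
  study <- generate_study(screen_world(7))
  spec <- comparison_spec("mutation_vs_no_mutation", "cohort_2", "cohort_1")
  scr <- run_screen(study$cohorts, list(spec))
  cmp <- scr$comparisons$mutation_vs_no_mutation

  pre_res <- mediation_test_all(study$cohorts$cohort_2, spec)
  preselected <- preselect_genes(pre_res, 0.05)
  val <- validate_genes(study$cohorts$cohort_1, preselected, spec)
  expect_equal(cmp$preselected, as.character(preselected))
  expect_equal(cmp$validation_table$p, val$p)
  expect_equal(cmp$log$n_validated, sum(val$significant))

  scr2 <- run_screen(study$cohorts, list(spec))
  expect_identical(serialize(scr, NULL), serialize(scr2, NULL))
})

test_that("intersection and panel screens honor their contracts", {
  tabA <- data.frame(gene = c("G1", "G2"), nie = c(1, 2), p = c(0.01, 0.02),
                     p_adj = c(0.02, 0.03), significant = c(TRUE, TRUE))
  tabB <- data.frame(gene = c("G3", "G4"), nie = c(1, 2), p = c(0.01, 0.02),
                     p_adj = c(0.02, 0.03), significant = c(TRUE, TRUE))
  expect_equal(nrow(intersect_candidates(tabA, tabB)), 0)
  tabC <- data.frame(gene = c("G2", "G5"), nie = c(3, 4), p = c(0.01, 0.5),
                     p_adj = c(0.02, 0.5), significant = c(TRUE, FALSE))
  both <- intersect_candidates(tabA, tabC)
  expect_equal(both$gene, "G2")

  study <- generate_study(screen_world(19))
  spec <- comparison_spec("mutation_vs_no_mutation", "cohort_2", "cohort_1")
  one <- panel_screen(study$cohorts$cohort_1, "G0001", spec)
  ok <- !is.na(one$p_adj)
  expect_equal(one$p_adj[ok], one$p[ok])        # family of size 1
  expect_error(panel_screen(study$cohorts$cohort_1, "NOT_THERE", spec),
               "no panel gene")
  # a missing panel member shrinks the family, the rest is still tested
  mixed <- panel_screen(study$cohorts$cohort_1,
                        c("G0001", "G0002", "ABSENT"), spec)
  expect_equal(attr(mixed, "untested"), "ABSENT")
  expect_equal(nrow(mixed), 2)
})

test_that("a panel of strong planted mediators is fully significant after BH", {
  cfg <- sim_config(n_genes = 17, n_samples_per_cohort = 600, n_cohorts = 1,
                    class_fractions = c(supporting_mediator = 3 / 17,
                                        opposing_mediator = 0, de_only = 0,
                                        prognostic_only = 0, null = 14 / 17),
                    alteration_probs = c(none = 0.75, mutation = 0.25, fusion = 0),
                    a_effect = 1.2, b_effect = 0.8, baseline_hazard = 4.5,
                    direct_effect = 1, censoring_rate = 0.25,
                    admin_censor_time = 8, seed = 12)
  study <- generate_study(cfg)
  spec <- comparison_spec("mutation_vs_no_mutation", "cohort_x", "cohort_1")
  tab <- panel_screen(study$cohorts$cohort_1, study$truth$gene, spec)
  planted <- study$truth$gene[study$truth$class == "supporting_mediator"]
  expect_true(all(planted %in% tab$gene[tab$significant]))
})

test_that("fusion-only vs mutation-only contrast flips the mediator signs coherently", {
  cfg <- sim_config(n_genes = 300, n_samples_per_cohort = 1500, n_cohorts = 1,
                    class_fractions = c(supporting_mediator = 0.01,
                                        opposing_mediator = 0, de_only = 0.05,
                                        prognostic_only = 0, null = 0.94),
                    alteration_probs = c(none = 0.5, mutation = 0.25, fusion = 0.25),
                    a_effect = 1, b_effect = 0.5, baseline_hazard = 6,
                    direct_effect = 2, seed = 33)
  study <- generate_study(cfg)
  co <- study$cohorts[[1]]
  res <- mediation_test_all(co, "fusion_only_vs_mutation_only")
  planted <- study$truth$gene[study$truth$class == "supporting_mediator"]
  # fusion (protective) lowers the hazard both directly and through the
  # mediators, so planted mediators support this contrast as well
  rows <- res[res$gene %in% planted, ]
  expect_true(all(rows$direction == "supporting"))
  expect_true(all(rows$p < 0.05))
})

test_that("the full three-comparison screen runs with a harmonized concatenated pre-selection", {
  cfg <- sim_config(n_genes = 600, n_samples_per_cohort = 500, n_cohorts = 3,
                    class_fractions = c(supporting_mediator = 0.01,
                                        opposing_mediator = 0, de_only = 0.05,
                                        prognostic_only = 0, null = 0.94),
                    alteration_probs = c(none = 0.7, mutation = 0.15,
                                         fusion = 0.15),
                    a_effect = 0.8, b_effect = 0.5, baseline_hazard = 7,
                    direct_effect = 1, batch_sd = 0.8, seed = 42)
  study <- generate_study(cfg)
  specs <- list(
    comparison_spec("fusion_vs_no_fusion", c("cohort_2", "cohort_3"), "cohort_1"),
    comparison_spec("mutation_vs_no_mutation", c("cohort_2", "cohort_3"), "cohort_1"),
    comparison_spec("fusion_only_vs_mutation_only", c("cohort_2", "cohort_3"),
                    "cohort_1"))
  scr <- run_screen(study$cohorts, specs)
  for (cmp in scr$comparisons) expect_equal(cmp$status, "ok")

  # shared-mechanism mediators are pre-selected under BOTH main contrasts
  planted <- study$truth$gene[study$truth$class == "supporting_mediator"]
  expect_gte(length(intersect(scr$comparisons$fusion_vs_no_fusion$preselected,
                              planted)), 4)
  expect_gte(length(intersect(scr$comparisons$mutation_vs_no_mutation$preselected,
                              planted)), 4)

  # exposure direction is estimated per contrast: fusion protective,
  # mutation harmful
  expect_equal(scr$comparisons$fusion_vs_no_fusion$preselection_table$total_sign[1], -1)
  expect_equal(scr$comparisons$mutation_vs_no_mutation$preselection_table$total_sign[1], 1)

  # cross-comparison intersections contain exactly the genes validated in both
  inter <- scr$intersections[["fusion_vs_no_fusion & mutation_vs_no_mutation"]]
  vfus <- scr$comparisons$fusion_vs_no_fusion$validation_table
  vmut <- scr$comparisons$mutation_vs_no_mutation$validation_table
  expect_setequal(inter$gene, intersect(vfus$gene[vfus$significant],
                                        vmut$gene[vmut$significant]))
  expect_true(all(inter$gene %in% planted))
})
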