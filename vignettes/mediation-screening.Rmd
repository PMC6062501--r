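---
title: "Survival mediation screening with additive hazards: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival mediation screening with additive hazards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survmedscreen)
```

# The question and the estimand

A binary genetic alteration (the *exposure* E — think of a RUNX1 point
mutation, harmful, or a RUNX1/RUNX1T1 fusion, protective) influences
overall survival. Part of that influence may be transmitted through the
expression of downstream genes: the alteration shifts a gene's expression,
and the gene's expression in turn shifts the hazard. A gene carrying both
arms is a *mediator*; the per-gene quantity of interest is the **natural
indirect effect (NIE)** — the portion of the exposure's hazard effect
transmitted through that gene.

Neither of the two standard analyses answers this question. Differential
expression (e.g. moderated-t) tests only the exposure→expression arm. A
per-gene Cox model tests only an expression→survival association, which can
be entirely confounded by the exposure acting on both. The mediation test
requires both arms jointly, with the outcome arm adjusted for the exposure.

# Models

For each gene M, with confounders C (sex, age, cytogenetic risk group):

**Mediator model** (ordinary least squares):
$$M = \alpha_0 + \alpha_E E + \alpha_C' C + \varepsilon .$$

**Outcome model** (semiparametric additive hazards with time-constant
effects):
$$\lambda(t \mid E, M, C) = \lambda_0(t) + \gamma_E E + \gamma_M M + \gamma_C' C .$$

The additive-hazards form is essential, not incidental: on the additive
scale the exposure's total hazard effect decomposes exactly into a direct
term and a sum of mediated terms, so the product
$$\mathrm{NIE} = \alpha_E \, \gamma_M$$
is the mediated hazard increment. On the proportional-hazards scale no such
clean decomposition exists.

## Estimation

The outcome model is fitted by the closed-form Lin–Ying estimating-equation
estimator: with at-risk average $\bar Z(t)$,
$$\hat\gamma = A^{-1} b, \qquad
  A = \sum_i \int_0^\tau Y_i(t) (Z_i - \bar Z(t))^{\otimes 2}\, dt, \qquad
  b = \sum_i \int_0^\tau (Z_i - \bar Z(t))\, dN_i(t),$$
with sandwich covariance $A^{-1} [\sum_i \int (Z_i - \bar Z(t))^{\otimes 2}
dN_i(t)] A^{-1}$ and cumulative baseline
$\hat\Lambda_0(t) = \sum_{s \le t} d\bar N(s)/Y(s) - \hat\gamma' \int_0^t
\bar Z(s) ds$. This estimator was chosen over the fully nonparametric
(time-varying coefficient) additive model because it is closed-form,
delta-method compatible, and directly checkable against a brute-force root
of the estimating equation — the test suite carries an independent
finite-difference Newton solver and requires agreement to 1e-8. With all
coefficients forced to zero the baseline reduces exactly to the
Nelson–Aalen estimator, which is also asserted.

Numerical conventions: tied event times are processed in one Breslow-style
risk-set update; the integration horizon $\tau$ is the largest observed
time; cytogenetic risk is encoded as favorable/adverse indicators with
"intermediate" as the reference; age is centered at 55 years. Designs are
checked for full rank *including the implicit baseline* — a constant
covariate is a collinearity error, never a silent drop.

## Inference on the product

$$se(\widehat{\mathrm{NIE}}) = \sqrt{\gamma_M^2 \mathrm{Var}(\hat\alpha_E)
  + \alpha_E^2 \mathrm{Var}(\hat\gamma_M)}, \qquad
  z = \widehat{\mathrm{NIE}} / se, \qquad p = 2(1 - \Phi(|z|)).$$

The covariance cross-term between the two fits (estimated on the same
samples) is omitted — the classical Sobel convention. Two consequences are
documented rather than hidden:

- **Conservatism under the complete null.** When both arms are null the
  product statistic is far from normal and the test rejects much less often
  than $\alpha$; the acceptance suite measures the rejection rate at
  $\alpha = 0.05$ over 2000 null genes and finds it well below 0.01. The
  screen therefore loses no error control from this approximation, only
  power.
- **Finite-sample coverage.** The 95% Wald interval for the NIE covers the
  truth at close to, but not exactly, the nominal rate; coverage depends on
  the follow-up regime because the sandwich variance of $\hat\gamma_M$ has
  small-sample bias when follow-up is dominated by a long exponential tail.
  The acceptance world for the calibration check uses mature follow-up
  (about 80% events), where the suite measures coverage near 0.95; in
  heavily censored regimes we observed values nearer 0.93.

Exact zeros are conventioned: $\mathrm{NIE} = 0$ with positive standard
error gives p = 1, and a degenerate gene (constant expression, collinear
design) is flagged `degenerate` with p = 1 instead of raising, so a
genome-wide screen survives pathological genes.

## Direction constraint

Only *supporting* mediators are of interest: genes whose indirect effect
has the same sign as the exposure's total effect on the hazard (for a
harmful mutation: up-regulated and hazard-increasing, or down-regulated and
hazard-decreasing). The total-effect sign is estimated per cohort from the
mediator-free additive-hazards fit (exposure + confounders); an a-priori
fixed sign can be imposed by the caller instead, but estimation is the
default since the fitted models should be self-consistent. The test itself
stays two-sided and direction-agnostic; the filter is applied by the
screening stages.

# The two-stage screen

Testing tens of thousands of genes with BH adjustment in one family would
leave almost nothing; pooling cohorts of different platforms into one test
misbehaves because of batch structure. The screen therefore:

1. tests every gene on a **pre-selection cohort** and keeps genes with
   supporting direction and unadjusted p strictly below 0.05;
2. re-tests only those genes on an independent **validation cohort**,
   BH-adjusting over the reduced family, and calls a gene validated when
   its direction is again supporting and its adjusted p is strictly below
   0.05.

Conventions fixed here (and logged per run):

- The direction filter runs **before** each stage's thresholding, so the
  validation BH family is the set of tested, supporting-direction genes;
  both the pre-filter and post-filter counts are exposed in the logs so
  either convention can be read off.
- Both thresholds are strict `<`.
- Genes not measurable on the validation cohort are recorded as untested
  and **excluded** from the BH family (assigning them p = 1 would distort
  the other genes' adjusted values).
- Pre-selection/validation roles are never swapped for a sensitivity
  re-run; repeated selection on high-dimensional data accumulates false
  positives across repetitions.
- When the pre-selection set is a concatenation of cohorts, the matrices
  are harmonized first (below); validation cohorts are never harmonized.

A restricted **panel screen** runs the same machinery over a small a-priori
gene panel (such as a published prognostic signature), where the
multiplicity burden is only the panel size.

# Batch harmonization

Cohort concatenation uses a location/scale empirical-Bayes adjustment:
standardize each gene under a pooled model (batch means + protected
covariates, pooled residual variance), estimate per-batch location shifts
and scale factors, shrink them toward across-gene priors (normal for
locations, inverse-gamma for scales, method-of-moments hyperparameters,
iterated jointly), back-transform. Decisions:

- The pooled variance uses residual degrees of freedom (n − parameters),
  which makes the plain-mode two-batch example exactly hand-checkable:
  batches {1,2,3} and {3,4,5} both become {2,3,4}.
- The exposure is passed as a **protected covariate** during pre-selection
  harmonization, so batch removal cannot absorb the exposure→expression
  signal the screen is hunting. A covariate-free mode is also available;
  which covariates (if any) a given study should protect is a
  design question the run log records.
- A plain (non-EB) mode exists for exact tests; with no true batch effect
  the EB mode provably perturbs the data less than the plain mode, which is
  asserted on a null study.

# The synthetic world

The generator emulates the structure the screen is designed for: two to
three cohorts; a RUNX1-mutation-like and a fusion-like alteration, strictly
mutually exclusive by default (an overlap probability exists and defaults
to 0); confounding (fusion samples receive favorable cytogenetics with
probability 0.9; age and sex affect both expression and hazard); per-gene,
per-cohort batch location shifts and noise-scale factors; expression on a
log2-like Gaussian scale; survival from a time-constant additive hazard
(hence exponential given covariates) with independent exponential censoring
truncated at an administrative horizon. Gene classes: supporting mediators,
opposing mediators, de-only (expression arm only), prognostic-only (hazard
arm only), and null. Mediator genes respond to the two alterations with
opposite signs — a shared-mechanism response, so the same genes support
both the harmful-mutation and the protective-fusion contrasts, as in the
two-alteration design the screen targets.

The hazard uses each gene's *deviation from its cohort-level baseline*
(baseline + batch shift), so gene baselines are absorbed into the baseline
hazard rather than nonsensically shifting it by the sum of thousands of
log-expression levels.

**Positivity.** An additive hazard with many covariates can go negative.
The generator clamps nonpositive hazards to 1e-6 and *errors* when more
than 0.5% of samples need clamping — it refuses to silently simulate from
a model that the stated parameters contradict. With G hazard-active genes
of slope b and independent unit-variance expression, the covariate hazard
spread is $b\sqrt{G}$, so the baseline rate must satisfy roughly
$\lambda_0 \gtrsim 2.6\, b\sqrt{G}$ (plus protection for the
protective-exposure arm and confounders).

**A hard consequence.** The sandwich standard error of $\hat\gamma_M$
scales as $\bar\lambda/\sqrt{n}$ — precision is relative to the *total*
event intensity. Combining with positivity,
$$ z_b \;=\; \frac{b\sqrt n}{\bar\lambda} \;\lesssim\;
   \frac{\sqrt{n/G}}{2.6},$$
independent of b. At n = 400 with 15 supporting mediators alone the cap is
about 2; with the full 115 hazard-active genes of the default world it is
about 0.7. Two-stage validation at BH-adjusted p < 0.05 needs per-gene z
around 3. Therefore **no positivity-respecting parameterization of the
default class mix can reach 60% validated sensitivity at n = 400**; the
acceptance suite states that criterion anyway and it fails honestly, while
the same runs demonstrate the properties that are attainable: zero
opposing-direction validations, de-only leakage below the nominal level,
and mean false-discovery proportion under 0.05. A feasible demonstration
world (five supporting mediators, few other hazard-active genes, n = 800,
mutation-only exposure) is used in the unit suite and the `analysis/`
workflow, where the screen validates most planted mediators with zero
false discoveries.

**Coherence of the default world.** Fifty opposing mediators at the same
effect magnitudes as the supporting ones drag the mutation's mediated
hazard by more than the supporting genes push it, so the default
`direct_effect` (10 hazard units) is set large enough that the *net* total
effect keeps its stated direction (mutation harmful, fusion protective).
The side effect — a modest net total effect relative to the baseline rate —
is why the DE-versus-mediation contrast is demonstrated on a de-only-rich
world (30% de-only genes, no opposing mass, strong relative exposure
effect), which is the regime that contrast is about.

Other defaults state, once: alteration probabilities 10% mutation / 5%
fusion (frequencies of the two alterations in large AML cohorts), a = 0.8
SD, b = 0.3 hazard units per SD, cohorts of 400, batch shift SD 0.5,
log-scale factor SD 0.1, censoring rate 2 with administrative horizon 2
(about 80–90% events at the default rates), age ~ N(55, 10), gene
baselines ~ N(7, 1.5) on the log2 scale.

What the generator does **not** emulate: realistic transcriptome
correlation structure (genes are independent given exposure and
confounders), probe-level microarray artifacts, competing risks, and
time-varying effects. A green test therefore establishes correctness of
the estimators and the screen's operating characteristics under the stated
model — not performance on real AML data.

# DE is not mediation

The contrast module selects differentially expressed genes by moderated t
(empirical-Bayes variance shrinkage; the prior degrees of freedom and prior
variance are estimated by moment matching on the log residual variances,
inverting the trigamma function — the closed-form testable choice; the
profile-likelihood refinement used elsewhere is a noted alternative), then
fits two Cox models per DE gene: (a) gene alone, (b) gene + exposure, each
family BH-adjusted separately. On de-only-rich synthetic data the count of
genes surviving in (b) is strictly below (a) in essentially every
replicate: the apparent survival relevance of merely differentially
expressed genes is the exposure's own effect leaking through the
expression arm. Cox fitting is delegated to the `survival` package — it is
surrounding contrast logic, not this package's contribution; the moderated
t is implemented here and cross-checked against `limma` as an independent
oracle in the tests.

# Descriptives and enrichment

Validated genes are characterized by: univariate Cox per SD of
standardized log2 expression (so hazard ratios are comparable across
genes) with Harrell's concordance; Kaplan–Meier curves split at the median
(ties at the median go to the low group — a fixed convention) with
log-rank tests; Wilcoxon rank-sum comparisons of expression between
alteration groups; partial correlations from the inverse correlation
matrix, displayed above a strict 0.2 threshold; and the agreement between
complete-linkage Euclidean hierarchical clustering and seeded k-means
(k = 2, Euclidean on the same standardized matrix) measured by the
adjusted Rand index.

Enrichment is a local hypergeometric over-representation analysis over
user-supplied GMT sets: candidates are genes with supporting direction and
unadjusted validation p < 0.10 (a deliberately lenient, explicitly
exploratory cut), the universe is the family of genes actually tested on
the validation cohort (not the whole genome), and set p-values are
BH-adjusted. The hypergeometric (not binomial) tail is used and is checked
against exhaustive enumeration on small universes.

# Known limitations

- The Sobel variance omits the cross-fit covariance; conservative in our
  simulations, but not a proof.
- Asymptotic normal inference only; a resampling-based alternative would
  slot in at `indirect_effect()` but is not implemented.
- One mediator at a time; joint multivariable mediation for survival
  outcomes is out of scope.
- No exposure–mediator interaction terms; mediation proportions on the
  survival scale are not reported.
- Mediation here is regression-based association with a counterfactual
  interpretation *under assumptions* (no unmeasured confounding of all
  three arms); it does not by itself establish causality.
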