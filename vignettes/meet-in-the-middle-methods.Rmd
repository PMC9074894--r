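---
title: "Methods: meet-in-the-middle screening of methylation mediators"
author: "meetmiddle package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meet-in-the-middle screening of methylation mediators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meetmiddle)
```

## The problem

Birth-cohort studies that measure a spectrum of prenatal environmental
exposures (phenols, pesticides, phthalates, flame retardants, air
pollutants), genome-scale cord-blood DNA methylation, and a battery of
childhood cognitive and behavioral outcomes (full-scale IQ, CBCL syndrome
scales, DSM-oriented ADHD scores) face a severe multiple-comparisons
problem: exposures x outcomes x hundreds of thousands of CpG sites is far
too many mediation hypotheses to test directly at cohort sample sizes of a
few hundred children.

The meet-in-the-middle design tackles this by screening the two legs of
each candidate mediation triangle separately — marker to outcome, exposure
to marker — and intersecting the survivors, after first shrinking the CpG
universe to sites on genes in biologically relevant pathways. The package
implements this as five sequential steps per outcome:

1. **Pathway preselection.** A keyword profile per outcome (e.g. *children,
   brain, neuron, autism, social* for social-problem scales) is matched,
   case-insensitively and by substring, against each pathway's name,
   description, disease annotation and reference titles. Genes of matched
   pathways, intersected with the array annotation, define the outcome's
   CpG universe.
2. **Outcome--CpG screen.** Each universe CpG is regressed on the outcome
   scale: linear for continuous outcomes, negative-binomial log-link for
   over-dispersed counts, adjusting for sex, ethnicity and age at testing.
   Benjamini--Hochberg FDR at 0.05 within the outcome's universe selects
   CpGs.
3. **Exposure--CpG screen.** Each surviving CpG is regressed (OLS) on each
   exposure, adjusting for sex and ethnicity only — there is no testing
   occasion in the exposure-methylation relationship, so no age term. FDR
   family: exposures x surviving CpGs, per outcome.
4. **Exposure--outcome test.** Each surviving (exposure, outcome) pair is
   tested with the Step-2 model form. The FDR family is the set of Step-4
   tests actually run; with a single surviving test this reduces to the raw
   p-value, which is how a single surviving pair should (and does) advance.
5. **Mediation.** For each surviving triangle, the exposure effect is
   decomposed on the link scale into direct and indirect components with a
   bootstrap over individuals, and summarized as the mediation proportion
   `p = |IE| / (|IE| + |DE|)`.

An EWAS comparison mode runs the same Steps 2--5 with every post-QC CpG in
every outcome's universe, isolating the value of the pathway prefilter: the
same effect must then survive a much larger multiple-testing family.

## Methylation preprocessing

Beta-values (methylation fractions) pass coverage QC — samples with <95%
non-missing CpGs are dropped, then CpGs with <70% non-missing samples, then
CpGs annotated to chrX/chrY — and are transformed to M-values,
`M = log2(beta/(1-beta))`, the approximately Gaussian modeling scale.
Boundary betas are clamped to `[1e-6, 1-1e-6]` first (the logit is
unbounded there; the clamp count is reported). Cell-type composition is
then regressed out per CpG (OLS on the proportion columns, one dropped
against the sum-to-one constraint, with intercept); the residuals — the
*M-value residuals* — are the mediator variable everywhere downstream.
Exposures and outcomes (never methylation) are trimmed by a single-pass
4-SD rule before analysis; a single pass is chosen over iteration for
determinism, and at cohort scale it removes at most a point or two per
variable.

The discovery/validation split follows the printed-percentage convention:
for a whole-percentage fraction the discovery set is the largest subset
whose share still rounds to that percentage. This reproduces the canonical
240/101 allocation of a 341-sample cohort at 70% — note that plain
round-to-nearest would give 239/102, which contradicts how such splits are
reported — while reducing to the familiar 70/30 at round sample sizes.
Selection happens only on discovery; the validation pass refits the
selected models and reports estimates and coefficient-sign agreement, with
no further selection.

## Regression engines and numerical choices

Count outcomes use NB2 (variance `mu + mu^2/theta`) with log link and
per-fit maximum-likelihood dispersion, alternating IRLS for the
coefficients with ML for theta until the dispersion stabilizes (relative
tolerance 1e-8, agreeing with `MASS::glm.nb` to machine precision — the
test suite asserts this). When the dispersion estimate diverges (theta
above 1e4: no evidence of over-dispersion) the fit falls back to Poisson
with HC0 robust standard errors and is flagged. P-values are Wald-type
throughout (t reference for OLS, normal for NB).

Degenerate fits never vanish silently: constant predictors, rank-deficient
designs (e.g. an exposure duplicated as a covariate), or non-convergence
yield flagged rows carrying `p = 1`, so they still count against their FDR
family. The BH adjustment accepts an explicit family size `m >=` the number
of supplied p-values; untested family members implicitly carry p = 1.

## Mediation estimand

The primary estimator is difference-of-coefficients on the link scale:
total effect from `outcome ~ exposure + covariates`, direct effect from the
same model with all mediators added, indirect effect their difference. This
is well-defined for the NB log link, where product and difference methods
diverge in general; in the linear-Gaussian case with shared covariate sets
the difference equals the product `a*b` algebraically (asserted to 1e-10).
Per-mediator contributions `a_k * b_k` are rescaled to sum exactly to the
indirect effect. The covariate asymmetry of the screens is preserved by
default (mediator models: sex + ethnicity; outcome models: sex + ethnicity
+ age); `mediator_covariates` can force equal sets.

Uncertainty comes from a percentile bootstrap over individuals (default 500
resamples, 95% intervals, seed-reproducible). When the mediators' M-values
and cell proportions are supplied, the cell-composition residualization is
re-estimated inside every resample, so the preprocessing step's sampling
uncertainty propagates into the intervals; the pipeline always does this.
In 100-replicate simulations at n = 240 with an NB outcome, percentile
intervals outperformed basic, bias-corrected and normal constructions for
the mediation proportion. Two finite-sample effects still matter and are
worth knowing about: (i) the mediator is an *estimated* residual, and
projecting out `k` cell columns leaks roughly `a*b*(k+1)/n` of the indirect
effect into the direct effect (about +0.03 on the link scale at n = 240
with 6 columns), biasing the estimated proportion slightly toward zero;
(ii) the proportion's fold at zero skews its bootstrap distribution when
either effect is near zero. Together these put the proportion CI's measured
coverage near 88% at n = 240, rather than the nominal 95%; coverage for the
indirect effect itself is closer to nominal. At validation-set sizes
(n ≈ 100) intervals are wide and should be read qualitatively.

## The synthetic-cohort generator

Because raw cohort data of this kind are not redistributable, the package
ships a generator whose defaults define the simulated study conditions, and
a ground-truth ledger so every stage is testable:

* **Cohort**: n = 341 (split 240/101); sex and ethnicity Bernoulli(0.5)
  (two-level, mirroring male/female and Dominican/African-American
  indicators); age at testing uniform within half a year of the nominal
  testing age.
* **Exposures**: log-normal (meanlog 0, sdlog 0.5), the right shape for
  analyte concentrations; 10 exposures by default.
* **Cell proportions**: Dirichlet with a granulocyte-dominant, cord-blood
  like concentration (Gran 45, CD4T 12, CD8T 8, Mono 5, Bcell 4, NK 3).
* **Methylation**: per-CpG baseline M ~ N(0, 2), additive cell-composition
  shifts (loadings N(0, 2) on centered proportions), planted exposure
  effects `a * X`, Gaussian noise SD 0.4; transformed to beta by inverse
  logit2, so the preprocessing logit2 recovers the generative scale
  exactly, and residualization is a real de-confounding step (outcomes
  depend on the cell-free mediator component only).
* **Outcomes**: two continuous (IQ-like: mean 100, residual SD 12) and two
  count (CBCL-like: NB2, baseline mean 3, theta 2) outcomes, with small
  fixed sex/ethnicity/age effects.
* **Planted triangle default**: `a = 0.8`, `b = 0.8`, `c_direct = 0.3` on
  the first exposure, first CpG and the count outcome at age 7, giving a
  closed-form mediation proportion `0.64/0.94 = 0.681` and standardized
  leg effects strong enough that the cascade should recover the triangle at
  discovery scale. Effect sizes of the magnitude such cohorts report
  (roughly 0.2--0.6 per unit on the link scale) are used in the recovery
  tests, where consistency (within 3 SEs), not power, is at stake.

Because the mediator given to the outcomes is conditionally Gaussian, the
marginal log-mean of a count outcome stays linear in the exposure with
slope `c_direct + a*b`, so the closed-form ledger is the correct target for
the difference-of-coefficients estimator under both families.

What the generator deliberately does **not** emulate: array probe-type
bias, batch effects, detection p-values, bimodal beta mixtures, correlated
CpG blocks, exposure measurement error, or missing-not-at-random outcomes.
Passing tests therefore certify the statistical machinery under the stated
model, not robustness to array artifacts — those belong to upstream
preprocessing tools.

## Problem sizes used by the test suite

The suite exercises the cascade at the simulated study scale: 50-replicate
coefficient-recovery and triangle-recovery studies at n = 240 (universe of
~200 CpGs, 10 exposures, 4 outcomes, bootstrap of 200 resamples), and a
100-replicate null-calibration study with 500-CpG universes. These sizes
give binomial error bars of a few percent on the reported rates while
keeping a full run in the minutes range on one core.

## Known limitations

* Keyword matching is plain substring; no stemming, synonyms or ontology
  expansion. Gene identity is symbol-string equality (any of a CpG's
  semicolon-separated genes counts).
* The Step-3 FDR family is exposures x surviving CpGs actually tested; when
  published analyses imply a different family (e.g. a larger exposure set),
  the adjusted p-values differ accordingly.
* No exposure-mediator interaction, natural-effect estimands, sensitivity
  analysis for unmeasured confounding, or confounders beyond sex, ethnicity
  and age at testing.
* The NB fallback covers dispersion divergence, not separation or extreme
  leverage; such fits surface as flagged rows.
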