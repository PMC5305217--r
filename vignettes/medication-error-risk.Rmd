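---
title: "Predicting clinically significant medication errors and simulating risk-based triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting clinically significant medication errors and simulating risk-based triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mederrisk` implements a complete development-and-evaluation workflow for a
clinical prediction model of in-hospital medication errors: a seeded
synthetic-cohort generator, severity grading of error records, predictor
screening, fractional-polynomial logistic modelling with permissive backward
elimination, bootstrap internal validation with uniform shrinkage, a frozen
reference scorer, and a simulated randomized-trial engine for comparing
triage policies. This vignette records the scientific and numerical choices
behind each stage.

## The endpoint

Medication errors are graded on the NCC MERP index, collapsed here to four
codes: C (no potential harm), D (requires monitoring or intervention to
preclude harm), E+ (potential harm, category E and above) and H (actual harm
occurred). The study endpoint is patient-level and binary: at least one
error graded D or above during the stay. Category C errors are tabulated but
never count as events of interest; actual-harm errors are stored as their
own category but pooled with E+ and D wherever "clinically significant" is
meant, so `tabulate_severity()` reports events of interest as the D + E+ + H
total. Clinical adjudication is out of computational scope — severities
arrive as labels.

## The synthetic cohort generator

No patient-level data ship with the package; every downstream stage is
exercised on synthetic cohorts from `cohort_spec()` / `generate_cohort()`.
The defaults emulate an adult (≥ 18 years) inpatient population with:

* **Age**: a normal distribution (mean 69, sd 17.5 years) truncated to
  [18, 105], which reproduces the target quantiles — median 68, IQR 57–80 —
  to within half a year. A symmetric truncated family suffices because the
  target quartiles are themselves nearly symmetric around the median; the
  truncation point, not skewness, does the work at the young end.
* **Binary covariates**: independent Bernoulli draws at the tabulated
  prevalences (52.4% male, 92.2% treatment initiated before admission,
  54.8% BPMH available, 25.2% surgical, and so on).
* **Drug count**: a zero-inflated negative binomial (zero inflation 0.25,
  mean 2.9, size 1.2), right-skewed with median 1. The association between
  drug count and the outcome is induced entirely through the outcome model,
  never wired into the generator.
* **ATC class indicators**: independent Bernoulli draws. Class prevalences
  are not tabulated for the emulated cohort, so plausible adult-inpatient
  values were chosen once (B01 0.35, J01 0.25, N05 0.30, B05 0.25,
  N02 0.40) and frozen.

Outcomes are drawn per patient as Bernoulli(p) with p from a configurable
true logistic model (`true_outcome_model()`); `published_true_model()` uses
the frozen reference coefficients. The drug-count and ATC parameters were
calibrated once by simulation (400,000 draws) so that the mean outcome
probability under those coefficients is 0.259, matching the development
cohort's 25.9% prevalence, and then frozen as package defaults.

What the generator does **not** emulate: covariates are independent (real
admission covariates are correlated — older patients take more drugs), there
is no length-of-stay process, and no inter-hospital heterogeneity.
Consequently, passing tests demonstrate the correctness of the algorithms
under a known data-generating process, not the transportability of the
frozen coefficients to any real population.

A companion fixture generator, `generate_me_records()`, draws error-level
records consistent with the patient-level outcomes: every positive patient
receives at least one significant record, severities follow the observed
category mix (D : E+ : H = 315 : 157 : 3 among significant errors), and
hospitalization days follow a geometric distribution with mode at day 1,
where admission-order discrepancies surface.

## Predictor screening

Univariate screening follows the conventional split: Wilcoxon–Mann–Whitney
(normal approximation with tie correction) for continuous variables,
chi-square for binary ones — **with Yates continuity correction**, because
the corrected test reproduces the reference sex-row p-value of 0.119 where
the uncorrected test gives 0.105. Variables pass at the deliberately
permissive p < 0.50; a constant variable yields an NA p-value and a warning
rather than an error.

Drug classes are screened by association-rule mining with the endpoint as
the fixed consequent: support is the probability that the antecedent classes
and the endpoint co-occur (threshold 0.05), confidence the probability of
the endpoint given the classes (threshold 0.10). The antecedent size is
capped at 2 by default, which keeps the enumeration exact and fast; rules
among drug classes only are never emitted, and retained rules are ordered by
descending support with lexicographic tie-breaks so output is invariant to
transaction order. No general frequent-itemset machinery (FP-growth, lift)
is provided — with a handful of indicator columns, exact enumeration is the
simpler and fully testable tool.

## Model development

Age is scaled by 100 and enters through fractional polynomials with powers
from {−2, −1, −0.5, 0, 0.5, 1, 2, 3} (0 meaning log). `select_fp()`
evaluates all 36 FP2 pairs (28 distinct plus 8 repeated-power pairs, a
repeated power p contributing x^p and x^p·log x) and applies the standard
closed test — FP2 against no age effect (4 df), against linear (3 df),
against the best FP1 (2 df) — at α = 0.05, stopping at the first
non-significant comparison. Because distinct FP2 pairs can be nearly
aliased on a bounded age range, tests of power recovery compare fitted
curves on [18, 100] rather than demanding the exact pair.

`fit_logistic()` wraps iteratively reweighted least squares (`glm.fit`) and
applies backward elimination: while the largest Wald p-value among removable
terms is ≥ 0.30, that term is dropped and the model refitted. Backward
(rather than forward) selection and Wald (rather than likelihood-ratio)
p-values are conventions chosen for predictability and speed; the permissive
0.30 threshold keeps weakly informative predictors whose omission would cost
calibration. Selected age terms enter as a block and are never eliminated;
a force-include list is supported for predictors that must stay regardless.
Degenerate inputs fail loudly: constant columns, rank-deficient designs and
complete separation (diagnosed as any |coefficient| > 20 on the logit scale)
raise errors naming the offending term, and the IRLS deviance trace is
stored on every fit so monotone convergence is inspectable.

## Internal validation and shrinkage

`c_statistic()` computes the concordance probability from midranks
(ties count ½), in O(n log n); its unit tests pin it to an O(n²)
pair-counting oracle. Calibration is summarised by logistic recalibration of
the outcomes on the linear predictor: the slope from `outcome ~ logit(p)`,
and the intercept as calibration-in-the-large (slope fixed at 1 via an
offset fit), matching the paired intercept/slope reporting convention.

`bootstrap_validate()` implements Harrell's optimism correction. In each
replicate the **entire** development procedure — fractional-polynomial
search included — is re-run on the resample; skipping reselection
understates optimism, so the honest mode is the default (callers wanting a
fast approximation can pass a cheaper `model_fn`). Optimism is the mean
difference between a replicate model's performance on its own bootstrap
sample and on the original cohort; corrected = apparent − optimism. The
corrected calibration slope is the uniform shrinkage factor:
`apply_shrinkage()` multiplies every slope coefficient by it and
re-estimates the intercept by an offset refit, which by the logistic score
equation makes the mean predicted probability equal the observed prevalence
exactly. Failed replicate refits are dropped and counted; more than 20%
failures abort the validation. Whether a corrected calibration intercept
should be read from the optimism of calibration-in-the-large or from
re-estimation after shrinkage is ambiguous in common practice, so the report
exposes both (`corrected_intercept` and the refitted intercept of the
shrunken model).

## The frozen reference model

`published_coefficients()` stores the corrected (shrunken) log-odds ratios:
intercept −3.83, age terms 7.07·(age/100)² − 6.26·(age/100)³, 0.14 per
prescribed drug, 1.60 for treatment initiated before admission, −0.64 for an
available BPMH, and six further admission-circumstance terms, with shrinkage
0.926. Probabilities are always computed from the corrected coefficients;
the uncorrected odds-ratio scale is recovered by
`unshrink_odds_ratio(logor, 0.926) = exp(logor / 0.926)` — e.g. 0.14 → 1.16
per drug and −0.64 → 0.50 — which is how the reference odds-ratio column is
reproduced from the corrected table (direct exponentiation of 0.14 gives
1.15, confirming that the published odds ratios are the unshrunk estimates).
The age effect is n-shaped with closed-form maximum at
100·2b₂/(3|b₃|) ≈ 75.3 years; the odds ratio at the peak, computed from the
unshrunk age coefficients, is ≈ 4.23, within the 2% wobble implied by
two-decimal coefficient rounding of the reported 4.26. Scoring demands every
predictor field and refuses silent imputation: a missing-data patient is a
clinical decision, not a default.

## The simulated-trial engine

`run_trial()` mirrors an external-application setting: the training model is
refitted on a bootstrap resample (so the ranking never benefits from
evaluating on its own training optimism), the original cohort is randomized
1:1, each arm treats its top coverage fraction by its strategy's key, and a
harmful-error patient counts as intercepted if reviewed and missed
otherwise. The treated count is ⌈coverage · arm size⌉. Ranking ties —
inevitable with integer ages — are broken by a seeded uniform draw, making
age-based triage well defined; a strict descending ranking is used rather
than an age cut-off, the natural reading of "oldest first". The
randomized halves are allocated to the two strategies in canonical
(sorted-label) order, which makes the engine invariant to label order:
swapping the strategies negates the reported improvement exactly. The
between-arm difference in interception rates is tested per trial with the
Yates-corrected chi-square on the arm × intercepted/missed table — the same
convention as the screening stage; the test behind the reported
significance shares is a package convention, as no particular test is
canonical for this design.

`run_suite()` repeats this across coverage scenarios (default 10–90% in five
steps, 1,000 replicates each) with per-replicate seeds pre-drawn from the
master seed, so results are reproducible and replicates independent. The
summary reports per-arm mean interception rates, the mean improvement of the
model arm, the share of significant replicates, and two numbers needed to
treat: against the comparator (ceiling of 1 / mean improvement) and against
no intervention at all (ceiling of 1 / model-arm interception rate).
Ceiling rounding is the convention that maps a 17.5-point improvement to
NNT 6 and a 50.6% absolute interception probability to NNT 2. The
"harmful error" endpoint is the patient-level significant-error outcome
(categories D and above), consistent with the model's endpoint; a
restriction to E+ only is possible where error-level records exist, by
re-deriving the outcome with `derive_endpoint()` on the filtered records.

## Problem sizes and tolerances in the test suite

The suite checks exact arithmetic directly and stochastic properties at
sizes chosen to keep the full run in a few minutes on one core: marginal
convergence at n = 100,000 (1 percentage point), prevalence calibration at
n = 20,000, coefficient recovery at n = 30,000–50,000, full-pipeline
bootstrap validation at n = 20,000 with 100 replicates, and trial properties
at 200 replicates on an n = 1,000 cohort. Oracles are independent of the
paths they check: pair counting for concordance, the contingency-table
formula for the Yates chi-square, brute-force antecedent enumeration for
rule mining, and hand enumeration for an 8-patient trial. Calibration-slope
identities are asserted to 10⁻⁶ (maximum-likelihood exactness), equality of
serialized models to 10⁻¹², and Monte-Carlo quantities at 2–3 standard
errors of their simulation noise.

## Known limitations

The generator's independence assumption means interactions and collinearity
patterns of real cohorts are absent, so elimination order on synthetic data
should not be read as clinically meaningful. The simulated trials assume
every reviewed harmful error is intercepted — an upper bound on pharmacist
effectiveness — and inherit the frozen coefficients' development-setting
calibration. Neither external validation nor decision-curve analysis is in
scope; both would be required before any clinical deployment.
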