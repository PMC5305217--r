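# mederrisk

Risk prediction and triage simulation for clinically significant in-hospital
medication errors.

Clinical pharmacists cannot review every admitted patient, so the patients
most likely to suffer a clinically significant medication error (an
unintentional discrepancy or prescribing error graded NCC MERP category D or
above) must be identified at admission. `mederrisk` implements, end to end,
the development and internal validation of a multivariable logistic risk
model for that endpoint and the evaluation of its clinical impact through
simulated randomized controlled trials, where model-guided triage is
compared against the traditional single-criterion rules (oldest first, or
most-medicated first) under realistic pharmacist coverage constraints.

## The model

The binary endpoint is the occurrence of at least one clinically significant
medication error during the hospital stay. The risk model is a logistic
regression on eleven admission-time predictors, with age entering through a
second-degree fractional polynomial:

    logit p = β₀ + b₂·(age/100)² + b₃·(age/100)³ + Σ βⱼ·xⱼ

where the xⱼ are the number of prescribed drugs, treatment initiated before
admission, availability of a best possible medication history (BPMH),
psycholeptic (ATC N05) and blood-substitute/perfusion (B05) prescriptions,
surgical admission, hospitalization within the previous 30 days, admission
from the emergency room, night admission, and admission from an outside
institution. Candidate predictors are screened univariately at a permissive
p < 0.50, drug classes by association-rule mining (support ≥ 5%,
confidence ≥ 10%), and the multivariable model is reduced by backward
elimination at p < 0.30. Internal validation uses Harrell's bootstrap
optimism correction, re-running the entire selection pipeline in every
replicate; the corrected calibration slope becomes a uniform shrinkage
factor applied to all coefficients. The frozen reference coefficients
(shrinkage 0.926, b₂ = 7.07, b₃ = −6.26) give an n-shaped age effect with
maximal risk around 75 years.

The trial engine randomizes a cohort 1:1, ranks one arm by a comparator key
(age or drug count) and the other by the predicted probability of a training
model refitted on a bootstrap resample, treats the top coverage fraction of
each arm, and counts intercepted (reviewed ∧ event) versus missed events,
summarising interception rates, the share of significant trials, and numbers
needed to treat.

## Worked example

```r
library(mederrisk)

# Score a 75-year-old on 5 drugs whose treatment began before admission
pat <- data.frame(age = 75, n_drugs = 5,
                  treatment_initiated_before_admission = 1,
                  bpmh_available = 0, atc_N05 = 0, atc_B05 = 0,
                  surgical_admission = 0, prior_hospitalization_30d = 0,
                  admission_from_ed = 0, night_admission = 0,
                  admission_from_outside = 0)
predict_probability(pat)
#> [1] 0.4516361

age_risk_profile()$peak_age_rounded   # age of maximal risk
#> [1] 75

# Synthetic cohort and a small simulated-trial suite
co <- assign_outcomes(generate_cohort(cohort_spec(1408, seed = 1)),
                      published_true_model(), seed = 2)
sum(co$outcome)
#> [1] 398
run_suite(co, sim_config(coverages = c(0.1, 0.5, 0.9),
                         replicates = 100, master_seed = 3))
#> Simulated randomized trials: model vs age_desc, 100 replicates/coverage
#>   coverage  10%: interception  21.1% vs   8.4%, improvement +12.7%, significant in 100.0%, NNT 8 (vs none 5)
#>   coverage  50%: interception  68.7% vs  52.2%, improvement +16.5%, significant in  96.0%, NNT 7 (vs none 2)
#>   coverage  90%: interception  97.4% vs  92.7%, improvement  +4.7%, significant in  48.0%, NNT 22 (vs none 2)
```

The scored probability is the exact evaluation of the published formula; the
trial summary reads: at 10% pharmacist coverage, model-guided triage
intercepted 21.1% of harmful errors versus 8.4% under oldest-first triage, a
+12.7-point mean improvement that was statistically significant in every
replicate, i.e. one extra error averted per 8 reviews (NNT 8), or one per 5
reviews relative to no pharmacist service at all.

`run_pipeline(pipeline_config())` chains every stage — generation,
screening, fitting, bootstrap validation with shrinkage, and simulation —
and writes CSV/JSON artifacts stamped with the master seed. A thin
command-line wrapper with `generate`, `score`, `simulate` and `run-all`
subcommands ships in `inst/cli/mederrisk.R`.

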