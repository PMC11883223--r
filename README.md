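# pktsurv

Pre-transplant prediction of kidney graft survival for pediatric
transplant recipients, with full internal/external validation and
country-adaptation machinery.

## The problem

Choosing a donor for a child with kidney failure involves trade-offs —
wait on dialysis for a well-matched deceased donor, or transplant now,
perhaps pre-emptively, from a less well-matched living donor. A model
that turns covariates known *before* surgery into an individual monthly
graft-survival curve supports that decision and the conversation around
it. Models of this kind are developed nationally; whether they transport
across countries — and whether a pooled international model beats
country-specific ones — is exactly the question this package's validation
and adaptation tooling is built to answer.

## The model

Follow-up is split into months and stacked into a person-period file (one
row per subject per at-risk month). The discrete-time hazard — the
probability of graft failure in month *m* given survival so far — is a
logistic regression

h(m | x) = logit⁻¹( α + xᵀβ + B(m)ᵀγ )

where *x* holds the pre-transplant covariates (recipient age, donor age,
living-donor status, pre-emptive transplantation, re-transplant, HLA and
HLA-DR mismatch counts, primary disease) and B(m) is a five-column
natural cubic spline in the month index (four interior knots at the
0.05/0.35/0.65/0.95 quantiles of the at-risk months). Predicted survival
multiplies the complements: S(t | x) = ∏₍m≤t₎ (1 − h(m | x)).

Around that core the package provides:

* `generate_registry()` — a synthetic four-country registry
  (Dutch/French/German/other-European cohort structure) with outcomes
  drawn from a known truth hazard, so everything is testable without
  registry microdata;
* `read_cohort()` / `apply_inclusion()` — CSV I/O and the 2005–2021,
  under-19, single-organ, in-Europe, complete-case filter with an
  auditable exclusion log;
* `fit_hazard()` / `predict_survival()` / `compare_scenarios()` — maximum
  likelihood fitting (Newton iteration, optional ridge), curves, donor
  scenario comparison;
* `split_cohort()`, `internal_validate()`, `external_validate()` — 80/20
  split, yearly time-dependent ROC-AUC with bootstrap CIs, decile
  calibration against within-bin Kaplan–Meier, Hosmer–Lemeshow test;
* `reestimate()`, `country_weights()`, `add_country_dummies()`,
  `build_international_model()` — full coefficient re-estimation on a new
  cohort, inverse-size country weighting and country dummies for pooled
  international models;
* `summarize_cohorts()`, `km_estimate()`, `log_rank()`,
  `run_pipeline()` — registry-style characteristics tables,
  Kaplan–Meier/log-rank comparisons, and a seeded, config-driven
  end-to-end pipeline.

## Worked example

```r
library(pktsurv)

registry <- generate_registry(default_profiles(), seed = 1)  # 2475 records
included <- apply_inclusion(registry)$cohort
dev <- reestimate(included, seed = 2, years = c(1, 5, 10), n_boot = 200)
dev$report
#> validation report [internal]: 495 subjects, horizon 60 months
#>   year  1 AUC 0.80 (95% CI 0.69-0.88)  [good]
#>   year  5 AUC 0.75 (95% CI 0.70-0.81)  [good]
#>   year 10 AUC 0.74 (95% CI 0.68-0.81)  [good]
#>   Hosmer-Lemeshow: 10.169 on 8 df (P = 0.25)
```

The model was developed on an 80% derivation cohort (1980 subjects) and
internally validated on the held-out 495: discrimination is the yearly
time-dependent AUC (cumulative cases / dynamic controls; above 0.7 is
conventionally "good"), and calibration is summarised by the
Hosmer–Lemeshow test at 60 months (here P = 0.25: no evidence of
miscalibration).

Comparing two donor scenarios for one 10-year-old with CAKUT:

```r
patient <- data.frame(recipient_age = 10, donor_age = 45,
                      living_donor = TRUE, preemptive = FALSE,
                      retransplant = FALSE, hla_mm = 2, hla_dr_mm = 1,
                      primary_disease = "CAKUT")
curves <- compare_scenarios(dev$model, patient,
  list("living donor, pre-emptive"    = list(living_donor = TRUE,
                                             preemptive = TRUE, hla_mm = 3),
       "deceased donor, well matched" = list(living_donor = FALSE,
                                             donor_age = 20, hla_mm = 1)),
  horizon = 120)
round(sapply(curves, function(cv) cv$survival[c(12, 60, 120)]), 3)
#>      living donor, pre-emptive deceased donor, well matched
#> [1,]                     0.986                        0.975
#> [2,]                     0.945                        0.901
#> [3,]                     0.924                        0.864
```

Rows are predicted graft survival at 1, 5 and 10 years: under this fitted
(synthetic-registry) model the pre-emptive living-donor scenario keeps
~92% predicted graft survival at 10 years against ~86% for the
well-matched deceased donor — the kind of side-by-side clinicians would
weigh alongside everything the model does not see.

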