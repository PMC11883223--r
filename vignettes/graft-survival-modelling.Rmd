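---
title: "Discrete-time modelling of pediatric kidney graft survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete-time modelling of pediatric kidney graft survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pktsurv)
```

## The problem

Before a pediatric kidney transplant, clinicians weigh donor options —
wait for a well-matched deceased donor, or accept a living donor now,
possibly pre-emptively — with little quantitative support. `pktsurv`
implements a pre-transplant risk assessment workflow for this setting: a
model that predicts *monthly* graft survival for an individual child from
covariates available before surgery (recipient and donor age, living-donor
status, pre-emptive transplantation, re-transplantation, HLA and HLA-DR
mismatch counts, and the primary kidney disease), plus the machinery needed
to validate such a model in its own country and to transport it to others.

## The model

Follow-up is discretised into months. For subject $i$ with covariate
vector $x_i$, the discrete-time hazard in month $m$ — the probability that
the graft fails in month $m$ given that it has survived to the start of it
— is modelled as a logistic regression on a person-period file (one row per
subject per at-risk month):

$$h_i(m) = \operatorname{logit}^{-1}\!\big(\alpha + x_i^\top\beta +
  B(m)^\top\gamma\big),$$

where $B(m)$ is a natural (restricted) cubic spline basis in the month
index. Predicted survival multiplies the complements,
$S_i(t) = \prod_{m\le t}\,(1 - h_i(m))$, which yields an individual monthly
survival curve, and lets two donor scenarios for the same recipient be
compared curve against curve (`compare_scenarios()`).

Graft loss is defined as return to dialysis or re-transplantation. Death
with a functioning graft is *censoring*, not an event: the final
person-period row of such a subject carries `event = 0`.

### Time basis

The month effect uses a natural cubic spline with four interior knots at
the 0.05/0.35/0.65/0.95 empirical quantiles of the person-period month
column and boundary knots at the observed minimum and maximum month,
giving five basis columns. Knots are placed on *all* at-risk months rather
than event months only, so the basis is anchored where exposure actually
lies; beyond the boundary knots the basis continues linearly, which keeps
prediction defined past the observed follow-up (an extrapolation, and
flagged as such here: curves beyond the last boundary knot inherit a
log-odds-linear time trend). Degenerate month distributions whose
quantiles coincide are rejected rather than silently collapsed.

### Fitting

`fit_hazard()` maximises the weighted Bernoulli log-likelihood
$\sum_i w_i\,[y_i \log h_i + (1-y_i)\log(1-h_i)]$ by Newton iteration with
step-halving, declaring convergence when the relative change in the
(penalised) log-likelihood falls below $10^{-10}$, with at most 100
iterations. Categorical covariates are one-hot encoded against fixed,
recorded reference levels — CAKUT for primary disease, the largest cohort
for country — so coefficients are reproducible across refits. An optional
ridge penalty (default 0) stabilises small, separable data sets; complete
separation with no penalty is an error, not a silent divergence.
Continuous covariates enter linearly in years and mismatch counts as
integers; no centring or scaling is applied, so the intercept is the
log-odds of failure in the reference month for a zero covariate vector.

## The synthetic registry

Registry microdata cannot be redistributed, so the package ships a
generator (`default_profiles()`, `generate_registry()`) that emulates a
four-cohort European registry: Dutch, French and German national cohorts
plus a pooled "other European" cohort, with country-specific cohort sizes
(273/1622/356/224), living-donor, pre-emptive and re-transplant fractions
taken as count-based proportions, disease-category mixes from published
count vectors, and truncated-normal age distributions matched by eye to
published medians and interquartile ranges (a registry reports only
medians/IQRs, so the exact family is a modelling choice and is
configurable). Living-donor ages centre on 42 years in every country —
parents, mostly — while deceased-donor age profiles differ sharply by
country (young in France, older in the Netherlands), which reproduces the
strong donor-age contrasts seen across European programmes.

Outcomes are drawn from a *known* discrete-time hazard (`truth_model()`),
so every downstream stage can be tested against ground truth. The default
truth uses a declining baseline hazard and covariate effects whose
directions follow the registry literature; their magnitudes were fixed
once so that (i) cumulative graft loss over 10–15 years lands in the
15–25% range typical of European pediatric cohorts and (ii) a correctly
specified refit reaches an internal 10-year AUC of about 0.75, the
discrimination level published pre-transplant tools attain in their own
populations. Censoring is modelled as geometric monthly dropout (default
0.002/month), a small independent monthly probability of death with a
functioning graft (0.0005/month, treated as censoring), and
administrative censoring at `admin_horizon` months or — by default — at
the end of calendar-year 2021 for late transplants, which reproduces the
staggered-entry follow-up pattern of a 2005–2021 registry window. Within a
month, graft failure takes precedence over death, which takes precedence
over dropout. The month index is 1-based: month 1 is the first month after
transplantation, and every simulated subject is followed for at least one
month.

What the generator does *not* emulate: waitlist dynamics and allocation
policy, centre-level effects within a country, era trends within the
2005–2021 window, correlated missingness (missingness is injected only by
the user), and calibration drift. Tests passing on these synthetic cohorts
therefore establish the *machinery* — estimation, discrimination and
calibration behave correctly when the model family is right — not that the
model family fits any particular registry.

## Cohort rules

`apply_inclusion()` retains transplantations performed 2005–2021 in
recipients strictly under 19 years of age at surgery, in Europe, excluding
multi-organ transplantations, and applies a complete-case rule over all
model covariates and outcome fields. Exclusion reasons are assigned by the
first matching rule in that fixed order and logged as counts, so retained
plus excluded always reconciles with the input; a record whose eligibility
for an early rule cannot be judged because the field is missing falls
through to `incomplete`. The filter is idempotent. Age is taken as age at
surgery (registries rarely distinguish listing age; where both exist the
caller chooses what to put in the column).

## Validation

`split_cohort()` draws a simple random 80/20 derivation/validation split
at subject level (`ceiling(0.8 n)` derivation records).

Discrimination is the yearly time-dependent ROC-AUC in the
cumulative-cases / dynamic-controls sense: at anniversary $t = 12y$
months, cases lost the graft at or before $t$, controls were followed
beyond $t$ without loss, and subjects censored before $t$ without an event
are excluded. The AUC is the exact pairwise concordance of the risk score
$1 - \hat S(t)$ with ties counted one half — a definition simple enough to
check against brute-force pair enumeration, which the test suite does.
IPCW-weighted estimators are a deliberate non-goal; the censoring-aware
refinement would slot in behind `year_auc()` without changing the report
structure. Confidence intervals are subject-level percentile bootstrap
(default 2000 resamples, seeded); in tiny samples the percentile interval
is widened, if needed, to contain the point estimate. Years with no
eligible case or control report a missing AUC rather than a fabricated
one. Following common practice, reports annotate AUC > 0.7 as good
discrimination.

Calibration uses equal-frequency deciles of predicted survival (bin sizes
differing by at most one, ties broken by stable subject order), comparing
the mean predicted survival with the Kaplan–Meier estimate *within the
bin* at the horizon, so censoring is handled properly. The
Hosmer–Lemeshow test is computed at subject level at a fixed horizon
(default 60 months): predicted event probability $1-\hat S(60)$ against
event-by-60, $\chi^2 = \sum (O-E)^2/E$ over groups and both outcome
cells, df = groups − 2, with zero-expectation groups merged into their
neighbour (df reduced, merges recorded). Two caveats are worth stating
plainly. First, subjects censored before the horizon without an event
cannot be classified and are dropped, which biases the observed event
fraction upward when much censoring precedes the horizon — with staggered
entry, prefer a horizon most subjects can reach, or read the KM-based
calibration table instead. Second, with *externally supplied* (rather than
refitted) probabilities the statistic is distributed closer to
$\chi^2_G$ than $\chi^2_{G-2}$, so at df = G − 2 the test over-rejects a
true model somewhat (about 10% at nominal 5% in this package's
simulations); the df convention is kept because it is the standard one for
validating fitted models, which is the pipeline's use.

`external_validate()` applies a model unchanged — no refit — to a full
external cohort, first checking that every category level can be encoded
and naming the offending levels otherwise.

## Country adaptation

Transporting the model to a new country re-estimates *all* coefficients
(`reestimate()`): fresh 80/20 split, fresh knot placement on the new
derivation person-period months, identical predictor set. Partial
recalibration (intercept-only, calibration slope) is deliberately out of
scope. For a pooled international model (`build_international_model()`),
two structural terms are added: a dummy variable per country (reference =
largest cohort) and inverse-size weights $w_c = N/(K\,n_c)$, so each of
the $K$ countries contributes equal total weight while the overall
effective sample size is preserved; the subject weight is replicated
across that subject's person-period rows and multiplies the
log-likelihood. Weights are computed on the derivation cohort (they
describe the data the model is fitted to, and the validation cohort must
not influence the fit). Standard errors under weighting are not reported
— the workflow reports validation metrics, not Wald inference.

## Numerical choices and degenerate inputs

* Survival curves satisfy $S(t)(1-h(t+1)) = S(t+1)$ to $10^{-12}$;
  hazards are clamped away from 0/1 at $10^{-12}$ before logs.
* Quantiles everywhere are the linear-interpolation (type 7) definition.
* Display rounding in summary tables is round-half-up (so 22.5 prints as
  23), percentages to integers, ages/months medians to integers, in the
  `pct (n)` and `median [Q1–Q3]` formats registries print.
* Equal-frequency binning breaks ties by stable subject order; with all
  predictions identical the bins remain equal-sized by construction.
* An intercept-only fit reproduces `qlogis(event rate)` exactly; fits are
  verified against an independent IRLS implementation (`glm`) and, on toy
  data, against exhaustive likelihood grid search.
* Seeds: every stochastic function takes an explicit seed; derived
  sub-seeds stay below $2^{31}$.

## Problem sizes used by the checks

The test suite and the acceptance script size their simulations to run on
a single CPU in minutes while keeping Monte-Carlo error well inside each
tolerance: coefficient recovery uses 3000-subject registries over a
120-month horizon (20 seeds in the acceptance suite, 8 in the script);
Kaplan–Meier-versus-truth uses 10 000 subjects; calibration of the true
model uses 5000; Hosmer–Lemeshow type-I behaviour uses 200 validation
sets of 495 subjects (the size of a 20% validation cohort of a
2475-transplant registry); heterogeneity orderings average 20 seeds of
two 800-subject countries. Two of these checks sit deliberately close to
their Monte-Carlo noise floor and are discussed above and in the README:
the ±0.03 decile-calibration band is ~1.4σ for the riskiest decile, and
the HL type-I band assumes a null distribution the statistic only
approximately follows.

## Known limitations

Competing risks are not modelled (death with function is censoring, per
the graft-survival definition); no frailty or centre effects; no
post-transplant predictors by design; the time-dependent AUC ignores
censoring weights (documented above); coefficients of any particular
published national model are not reproduced — registry microdata are not
available — so the package validates methodology against its own
simulation truth instead.
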