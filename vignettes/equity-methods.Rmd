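---
title: "Methods: log-disparity equity evaluation and survey-weighted regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: log-disparity equity evaluation and survey-weighted regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svyequity)
```

## The question the package answers

Given respondent-level microdata from a complex health survey, and a named
healthcare service — receipt of a hepatitis A vaccine, a prescription in an
antidiabetic drug class — we ask, for each level of a sensitive covariate
(race/ethnicity, education, insurance type, income category): is the
subgroup's share **among recipients of the service** proportionate to its
share **of the target population that needs the service**?

Two complementary analyses are provided:

1. an **equity evaluation** built on the Log Disparity score, which compares
   subgroup shares directly against the target population and classifies each
   subgroup-by-outcome cell into six levels, and
2. a **survey-weighted logistic regression** producing adjusted odds ratios
   against declared reference groups, which controls for the other covariates
   but carries no information about the target population.

The two disagree by design in what they measure: regression asks "does this
covariate shift the odds, others held fixed?"; the equity evaluation asks
"did this subgroup, as it actually exists in the population, get its share?"

## The Log Disparity score and its classification

For a subgroup with estimated share $p_{obs}$ among service recipients and
share $p_{tgt}$ of the target population, the score is the log of the odds
ratio of the two shares:

$$ D = \log\frac{p_{obs}/(1-p_{obs})}{p_{tgt}/(1-p_{tgt})} . $$

$D = 0$ means exactly proportionate representation; the natural logarithm is
used throughout, making the score antisymmetric under exchange of the two
shares. Thresholds come from rate rules: a rule of $\tau_{rule}$ maps to
$\tau = -\log(1-\tau_{rule})$ on the score scale. The defaults are the
80% rule of disparate-impact practice, $\tau_l = -\log(0.8) \approx 0.2231$,
and an upper rule of 0.4, $\tau_u = -\log(0.6) \approx 0.5108$; both are
configurable in `equity_thresholds()`.

Classification is gated on a two-sided significance test of
$H_0: p_{obs} = p_{tgt}$. A cell whose disparity is not significant
($p > \alpha$, default $\alpha = 0.05$) is **Adequate** regardless of its
score: with the information available, the subgroup cannot be said to be
under- or over-served. Significant cells are graded on half-open intervals:

| level             | condition                          |
|-------------------|------------------------------------|
| Absent            | subgroup present in target, zero recipients |
| Highly Inadequate | $D < -\tau_u$                      |
| Inadequate        | $-\tau_u \le D < -\tau_l$          |
| Adequate          | $-\tau_l \le D < \tau_l$ (or $p > \alpha$) |
| Abundant          | $\tau_l \le D < \tau_u$            |
| Highly Abundant   | $D \ge \tau_u$                     |

Two boundary conventions deserve emphasis because they are design choices,
not forced by the mathematics. First, every printed category range in this
package (income categories, HbA1c bands, age bands, score intervals) is
half-open, $[\text{lower}, \text{upper})$, so categories partition their
domain. Second, a subgroup with a positive target share and an observed
share of exactly zero is routed to **Absent** via a $-\infty$ sentinel — no
continuity correction is applied anywhere, because "no member of this group
received the service at all" is qualitatively different information from a
small positive share, and deserves its own (red) cell. Symmetrically, a
subgroup constituting *all* recipients gets $+\infty$ and classifies
Highly Abundant when significant. No multiple-testing correction is applied
across cells by default; `p_adjust` switches one on when a user wants
family-wise control over a heatmap.

### The significance test

The test must work from design-based estimates, not raw counts. The default
mode converts the observed share into pseudo-counts via the Kish effective
sample size of the recipient denominator, $n_{eff} = (\sum w)^2 / \sum w^2$,
and runs an exact binomial test of $k = \text{round}(p_{obs}\, n_{eff})$
successes in $\text{round}(n_{eff})$ trials against the estimated target
share. A `"normal"` mode instead compares the two shares with a z statistic
on their linearized standard errors. The exact mode is the default because
recipient subsets of conditioned subpopulations are often small, where the
normal approximation is at its worst; the cost is mild conservatism from
discreteness and the neglect of target-share uncertainty, which is minor
whenever the target population is much larger than the recipient pool (the
typical situation: everyone in need versus those treated). Both modes are
exercised by the type-I-error simulation in the test suite, which checks the
rejection rate at effective $n \approx 1000$ stays within $0.05 \pm 0.02$.

### Conditioning

Prescribing is legitimately driven by clinical state: a physician chooses an
antidiabetic class partly on glycemic control (HbA1c) and comorbidity burden
(the Charlson index). An unconditioned disparity across, say, insurance
types may only reflect different case mix. `equity_eval()` therefore takes
a conditioning column (an HbA1c stratum, an insurance class, or any factor)
and evaluates every subgroup-by-outcome cell within each conditioning
stratum, with both shares recomputed inside the stratum. Cells whose
subgroup simply does not occur inside a stratum's target population are
*structurally missing* (`NA` level, uncolored in heatmaps) — a different
statement from Absent.

## Design-based estimation

All estimation treats the survey as a stratified design whose first-stage
units (PSUs) were sampled with replacement — the standard approximation for
national health surveys, where first-stage sampling fractions are small.
Consequences: finite-population corrections are omitted, and variances come
from Taylor linearization. For a ratio estimator (every share here is a
ratio of weighted totals), per-row influence values
$z_i = w_i(\text{num}_i - R\,\text{den}_i)/\hat X$ are summed to PSU totals,
and within each stratum $h$ with $n_h$ PSUs the between-PSU sum of squares
is scaled by $n_h/(n_h - 1)$ and accumulated. A stratum contributing a
single PSU cannot supply a within-stratum spread; the default rule centers
its lone PSU total at the grand mean of all PSU totals (configurable to an
error for users who prefer to fail loudly).

Multi-cycle data are combined by concatenating cycles and dividing each
weight by the number of 2-year cycles combined, so the combined weighted
total estimates the (average) population size once rather than once per
cycle.

## Survey-weighted logistic regression

`svylogit()` maximizes the weighted Bernoulli log-likelihood
$\sum_i w_i [y_i \log \mu_i + (1-y_i)\log(1-\mu_i)]$ by iteratively
reweighted least squares, converging when the relative deviance change
falls below $10^{-8}$ (at most 25 iterations; non-convergence is an error
carrying the deviance trace, and apparent separation — fitted probabilities
pinned at 0/1 with a diverging coefficient — is an error naming the
covariate). The covariance is the linearized sandwich: bread from the
observed information of the weighted likelihood, meat from PSU-aggregated
score totals with the same stratified $n_h/(n_h-1)$ construction as above.
Both the coefficients and this covariance are invariant to uniform weight
rescaling, which the test suite asserts.

Inference uses a $t$ reference distribution with design degrees of freedom
equal to #PSUs $-$ #strata — the conventional design-based choice; the small
df (e.g. 15 for a 15-strata, 30-PSU design) widens intervals relative to a
normal reference, which is intended. Odds ratios are $e^{\hat\beta}$ with
95% bounds $e^{\hat\beta \pm t_{df,0.975}\,SE}$. Categorical covariates use
treatment coding against declared reference levels (non-Hispanic White,
male, private insurance; ordered covariates against their lowest level and
entered as per-level indicators, never as numeric scores, so every level
gets its own odds ratio). Age enters continuously for vaccine models and as
the three diabetes age bands (20–45, 46–64, ≥ 65) for drug models; both are
just formula choices by the caller.

Assumption checking follows the spirit of survey-regression diagnostics:
`flag_outliers()` computes standardized Pearson residuals (leverages from
the weighted IRLS hat matrix) and reports rows beyond a cutoff (default 3).
Flagged respondents — the typical case is an extreme weight attached to a
contrarian outcome — are reported, never dropped: removing design weights'
tail respondents silently would change the estimand.

## Clinical coding

The Charlson Comorbidity Index is computed from the 15 comorbidity
indicators the survey carries. The published index requires conditions the
survey does not ask about, so the bundled weight table is a **reconstruction**:
the original Charlson weights restricted to the available conditions
(myocardial infarction, congestive heart failure, cerebrovascular disease
and chronic pulmonary disease at 1; renal disease and malignancy at 2; the
four pulmonary conditions — emphysema, chronic bronchitis, COPD, asthma —
mapping to one component counted once; hypertension, arthritis, gout and
coronary heart disease outside the Charlson set at 0). Diabetes scores 1,
or 2 with retinopathy as end-organ complication. Scores band into
none (0), mild (1–2), moderate (3–4), severe (≥ 5). The table is a plain
configurable object (`charlson_weights()`), and its status as a
reconstruction is the reason it is exposed rather than hard-coded.

Drug outcomes use a Multum-style two-layer map: drug → therapeutic category
(ten categories including "combinations") and combination → ingredient
list. With `decompose = TRUE` combinations dissolve into their ingredients'
categories (nine-category view), which matters because the combination
class otherwise hides which classes a patient actually receives;
`ingredient_usage()` goes one level finer. The bundled formulary is a
representative editable subset (48 products), not a complete national
formulary.

## The synthetic-survey generator

Real microdata from the survey program this package targets cannot ship
with code. The generator (`scenario()`, `generate_population()`,
`draw_survey()`) exists so that every pipeline stage is testable against
known ground truth:

* a finite census (default 48,000 persons in 15 strata × 8 PSUs × 400) with
  categorical covariates from configurable marginals, income ratio from a
  truncated log-normal, HbA1c from a two-component (non-diabetic/diabetic)
  mixture so that conditioning strata are populated, and outcomes drawn from
  logistic models with configurable true coefficients (defaults set the true
  odds ratios in the 0.8–1.3 range typical of national utilization
  contrasts);
* a stratified **two-stage** sample: PSUs drawn with replacement (so the
  with-replacement variance estimator the package uses is exactly unbiased,
  second stage included), then respondents drawn equal-probability within
  two frames, with minority respondents oversampled threefold — producing
  unequal, exactly-known inclusion probabilities and hence exact
  Horvitz–Thompson weights;
* optional injected share disparities: an observed/target odds multiplier
  applied to one subgroup's outcome odds, with the realized census recorded
  as ground truth;
* default sample scale of 2 PSUs × 150 respondents × 15 strata × 3 cycles
  (≈ 13,500 rows), a desk-scale size at which the full pipeline, the
  2000-replicate calibration simulations and the 300-replicate coverage
  simulations all run in well under a minute each.

What the generator deliberately does **not** emulate: the four-stage
geography of the real design (two stages suffice to exercise strata, PSUs
and unequal weights), nonresponse and post-stratification adjustment of
weights, measurement error in self-reported prescriptions, and realistic
joint dependence between covariates beyond what the outcome models induce.
Passing tests therefore demonstrate that the estimators and classifiers are
correct *under a faithful complex design with known truth* — not that any
substantive disparity finding transfers to real data.

## Numerical choices

* IRLS working weights and probabilities are floored at $10^{-12}$
  ($10^{-300}$ inside logs) to survive extreme linear predictors without
  producing NaNs before the separation check fires.
* The XPT writer stores numerics as IBM hexadecimal floating point; IEEE
  doubles convert losslessly (56-bit fraction versus 53, at most 3 bits of
  alignment loss), so fixture round-trips are bit-exact.
* Kish effective sizes are rounded only at the final pseudo-count step of
  the exact test.
* Share partitions are validated to sum to 1 within $10^{-12}$ in tests;
  weighted-total identities in the cycle combiner hold to $10^{-9}$
  relative.

## Open decisions and how they were settled

* **Insurance priority.** The four insurance classes are reported from
  overlapping per-plan indicators; multiply-insured respondents are assigned
  by the priority private > Medicare > Medicaid > other non-private,
  consistent with private insurance serving as the regression reference
  class. "Uninsured" requires *every* plan flag to be explicitly negative;
  any unknown flag without a positive one yields a missing class. The
  priority order is an argument.
* **Adulthood boundary.** Survey ages are completed years, so "over age 20"
  is implemented as ≥ 20 by default with a strict (> 20) switch.
* **Significance gate direction.** Non-significant cells are Adequate and
  score-grading applies only to significant cells. The alternative reading
  (significant ⇒ adequate) would label exactly the well-established
  disparities as adequate and is rejected.
* **Other/unknown race-ethnicity** is retained as an analyzable level by
  default; dropping it is a filter away, and the provenance log records
  whichever was done.
* **Weight column choice** (interview vs examination weight in real data)
  is the caller's, via `survey_design()`; nothing is hard-coded.

## Limitations

Disparity classifications are descriptive, not causal: conditioning on a
clinical stratum controls case mix for that stratum only. The exact test
ignores target-share uncertainty (negligible for large target populations,
optimistic when target and recipient pools are comparable in size — use the
normal mode there). Replicate-weight variance methods (BRR, jackknife) and
weight calibration are out of scope. The equity approach reads one cell per
subgroup and does not model interactions; as the number of conditioning
factors grows, cells thin out and the heatmap loses power long before the
regression does.
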