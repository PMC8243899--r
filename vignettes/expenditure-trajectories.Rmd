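---
title: "Modelling end-of-life expenditure trajectories with eoltraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling end-of-life expenditure trajectories with eoltraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

How does healthcare spending evolve over the last five years of life? In
systems such as Japan's, where public medical insurance and long-term-care
(LTC) insurance coexist, a decedent's monthly claims can be anchored at the
date of death and read backwards: month 1 is the month of death, month 60 the
earliest month of the five-year window. Cohorts of this kind show strong
heterogeneity — some patients spend heavily throughout, others only in a
terminal surge — and the natural statistical frame for that heterogeneity is
group-based trajectory modelling (GBTM), a finite mixture of mean curves over
time with no within-group random effects.

`eoltraj` implements the full analysis pipeline: death-anchored panel
construction from long-format claims, the trajectory mixture model itself,
BIC-based model selection with a minimum-group-size rule, classification
adequacy diagnostics, multinomial logistic association of group membership
with patient factors, and cross-tabulation of trajectories across expenditure
categories. Because the claims databases such analyses run on are access
restricted, the package also ships a calibrated synthetic-cohort generator so
every stage can be exercised and tested end to end.

## The model

Let $y_{it}$ be the natural log of patient $i$'s expenditure in month-before-
death $t \in \{1, \dots, 60\}$, with zero amounts coded as $0$ on the log
scale (taking the customary zero-assignment convention literally; see
"Numerical choices" for the censored-normal alternative). Months are mapped
to a scaled time $s_t = -(t-1)/59 \in [-1, 0]$, so $s = 0$ at death; the
scaling keeps quintic powers numerically well conditioned. The model is

$$
f(y_i) \;=\; \sum_{g=1}^{G} \pi_g \prod_{t=1}^{60}
  \phi\!\left(\frac{y_{it} - \beta_g(s_t)}{\sigma}\right)\big/\sigma ,
\qquad
\beta_g(s) = \sum_{k=0}^{p_g} \beta_{gk}\, s^k ,
$$

with mixture weights $\pi$ on the simplex, per-group polynomial orders
$p_g \le 5$, and a residual SD $\sigma$ shared across groups and months (the
minimal model consistent with standard trajectory software defaults).
`gbtm()` maximises the likelihood by EM:

* **E step** (`gbtm_estep`): posterior membership probabilities by Bayes'
  rule, computed in log space with a per-patient log-sum-exp.
* **M step** (`gbtm_mstep`): because every patient shares the same time
  grid, each group's weighted polynomial regression collapses to a single
  $(p_g+1) \times (p_g+1)$ normal-equation solve, $\sigma^2$ is the pooled
  posterior-weighted mean squared residual, and $\pi$ is the posterior
  column mean. This makes a full EM iteration $O(nTG)$ and a 2000-patient,
  six-group quintic fit takes well under a second.

EM runs from multiple restarts. Restart 1 clusters per-patient summary
features — overall mean, OLS slope, and the means of the early, middle and
late thirds of the window — with k-means; later restarts jitter the feature
matrix before clustering. The segment means matter: trajectory groups that
differ mainly in *when* spending rises (late rise vs very late rise vs
progressive) are nearly indistinguishable by overall mean and slope, and
restarts initialised without segment features visibly converge to merged
local optima. The log-likelihood is asserted nondecreasing at every
iteration; convergence is declared when the relative change drops below
$10^{-8}$ (500 iterations cap), and the best converged restart wins. Ties in
the modal assignment break toward the lowest group index, so all outputs are
deterministic given the seed.

## Model selection and adequacy

`gbtm_grid()` fits every combination of $G \in \{2,\dots,8\}$ and a common
polynomial order $0\dots5$, discards candidates whose smallest estimated
group proportion falls below 5% (or that failed convergence), and picks the
best BIC among the admissible rest, using the trajectory-literature sign
convention $\mathrm{BIC} = \ell - \tfrac12 k \log n$ with $n$ the number of
patients (higher is better). Exhaustive per-group order search is
intractable ($6^8$ combinations at $G=8$), so the grid searches a common
order and, optionally (`refine = TRUE`), greedily lowers one group's order
at a time for as long as the BIC does not worsen. The common-order grid is
the selection baseline.

Adequacy of the chosen classification is judged by the standard four-part
battery (`adequacy_report()`):

* **APP** — average posterior probability of assignment per group,
  threshold 0.7;
* **OCC** — odds of correct classification,
  $\mathrm{OCC}_g = \frac{\mathrm{APP}_g/(1-\mathrm{APP}_g)}{\hat\pi_g/(1-\hat\pi_g)}$,
  threshold 5 (boundary values yield an `Inf` sentinel, not an error);
* **proportion agreement** — $|$assigned $-$ estimated$|$ per group, always
  reported raw, flagged at $\le 0.05$ (the 0.05 is this package's own
  documented convention; no universal numeric criterion exists);
* **98% confidence intervals** for $\hat\pi_g$ by parametric bootstrap:
  cohorts are simulated from the fitted model and only the weights are
  re-estimated (curves and $\sigma$ frozen, which also pins the group
  labels), then percentile intervals are taken. A bootstrap was chosen over
  a Hessian-based interval because the observed-information matrix is
  fragile exactly where these intervals matter, at small group weights.

`label_trajectories()` names groups with the field's vocabulary by a
deterministic rule: a curve with range below 0.8 log units is "persistent"
(high / medium-to-high / low by where its late-window mean sits in the span
of all fitted values, with cut points 0.85 and 0.45 of the span); a rising
curve is classified by the month, counted back from death, at which it first
crosses the midpoint of its own range — 37+ months is "early rise then high
persistent", 15–36 "progressive increase", 7–14 "late rise", and 6 or fewer
"low persistent then very late rise". The cut points were fixed once against
the shapes the labels describe and are exposed as arguments.

## Association with patient factors

`fit_trajectory_multinom()` regresses trajectory membership on patient
factors by maximum-likelihood multinomial logit (via `nnet::multinom`),
against the high-persistent group as reference. Model 1 uses age (continuous,
at death), sex, 6 service flags and 21 disease flags; Model 2 replaces the
disease flags with their count. Odds ratios carry Wald 95% intervals
($\exp(\hat\beta \pm z_{0.975}\,\mathrm{SE})$) and two-tailed p-values;
profile-likelihood intervals were deliberately not used, matching standard
software defaults for this model class. Apparent complete separation
(a coefficient beyond $\pm 15$ on the log-odds scale) is an error naming the
covariate; the pipeline pre-screens flags with empty outcome-group cells in
small cohorts and records the exclusions in its manifest.

## What the synthetic generator emulates

`default_calibration()` encodes the study conditions the package is
calibrated to, a Japanese decedent cohort (N = 16,084, deaths April 2014 –
March 2015, age at death 85.1 ± 7.5, 48.5% male):

* **Six total-expenditure groups** with weights
  (0.456, 0.261, 0.098, 0.064, 0.064, 0.057): high persistent flat at
  log-yen 12.6; medium-to-high persistent flat at 11.4; early rise then high
  persistent (cubic rising from 10.0 in the first year, then flat near
  12.4); late rise (flat 9.6, rising from roughly a year before death to
  12.3); low persistent then very late rise (flat 8.9, rising in the last
  half year); progressive increase (linear 9.3 to 11.9). The two rise
  shapes are least-squares quintic approximations of logistic ramps centred
  0.15 and 0.06 scaled-time units before death; the coefficients are frozen
  in the package so the generator curves stay inside the model family the
  fitter searches.
* **A four-group long-term-care variant** with weights
  (0.434, 0.311, 0.130, 0.125): low persistent, high persistent, late rise,
  progressive increase.
* **Zero inflation.** Per-patient-month zero probabilities (5% medical, 10%
  LTC) plus a patient-level LTC "never user" mass with per-group
  probabilities (0.20, 0.35, 0.40, 0.51, 0.55, 0.51), whose weight-averaged
  value 0.3187 reproduces the reported 5125/16,084 patients with zero LTC
  spending across all 60 months. Pure per-month zeroing cannot produce that
  whole-period mass, hence the patient-level component.
* **Sector substitution.** For never-users the LTC mean mass is folded into
  the inpatient mean, so a patient's *total* expenditure curve does not
  depend on LTC-use status. This mirrors the substitution between long-term
  care and acute care documented for this system, and it keeps the
  total-expenditure mixture identified by trajectory shape rather than by
  LTC-use status — without it, the never-user subpopulation of each group
  would itself act as a spurious latent class.
* **A shared acuity shock.** One Gaussian patient-month shock
  ($\sigma = 0.6$ log units) is shared across the four elementary
  categories, so a sick month is costlier everywhere and the log of the
  total is exactly Gaussian around a smooth group curve. Under independent
  per-category shocks the log of the summed amounts would follow a skewed,
  narrower distribution than any member category.
* **Group-linked covariates.** 21 disease and 6 service flags at the
  cohort's published baseline prevalences, with clinically motivated
  log-odds offsets (malignancy raised in late-rise, hematological malignancy
  in progressive-increase, tube feeding / neurodegenerative disease /
  dementia in high-persistent, hospice in late-rise). Because covariates are
  independent given the group, the implied multinomial-logit coefficient for
  covariate $k$ and outcome $g$ is exactly
  $\delta_{kg} - \delta_{k,\mathrm{ref}}$, which gives the association stage
  a closed-form truth to recover. Covariates do not feed back into amounts;
  the latent group is the sole driver of spending.
* The published Table-1 service list has nine medical-service rows but the
  regression models use six; the source never enumerates which six. The
  generator uses hospitalization, home medical care, ventilation, tube
  feeding, hospice and dialysis.
* Death months are uniform over April 2014 – March 2015 (the Methods-section
  window; the source's abstract cites 2016–17, a discrepancy we note and do
  not resolve), ages are normal truncated at 70, and amounts are simulated
  in yen so the fixed-rate USD conversion (92 yen per dollar,
  purchasing-power parity) is exercised in reporting.

**What the generator does not emulate** — and hence what green tests do not
establish about real data: claim line-item structure, DPC/per-diem payment
mechanics, dental claims, seasonal or calendar-time effects, within-group
heterogeneity beyond the shared shock (real cohorts have fatter tails and
patient-level frailty), covariate effects on spending conditional on group,
and measurement error in disease coding. The four-group LTC variant
deliberately carries *no* zero inflation: a 32% all-zero subpopulation is
itself a latent class, and the variant's purpose is to test recovery of the
four trajectory shapes, not zero-mass handling. Real LTC data would require
the censored or a two-part model.

## Numerical choices and degenerate inputs

* The zero-coded log transform is taken literally by default; a
  left-censored-at-zero normal likelihood (tobit EM with truncated-moment
  imputation in the M step) is available via `gbtm(..., censored = TRUE)`
  for users who prefer to treat zeros as censoring.
* `sigma = 0` is accepted by the generator as the documented noise-free
  limit; negative values are rejected.
* Amounts of exactly 1 yen log-transform to 0 and collide with the zero
  code; this is inherent to the convention and documented rather than
  "fixed".
* Currency conversion happens only in reporting layers; the trajectory
  model always consumes log-yen.
* Sample (n−1) SDs in descriptive tables; the single-patient SD is `NA`.
* Panel aggregation bins by calendar-month offset (claims are billed
  monthly); the death month is month 1 regardless of the day of death.
* Percentile ranks on the concentration curve are reported as $100k/n$
  rounded to one decimal; published Pareto percentiles based on other
  conventions will differ in the second decimal.
* Mixture-weight boundary cases: zero weights contribute $-\infty$ in log
  space and are handled by the log-sum-exp; an all-`-Inf` density row is a
  degenerate-parameter error.

## Problem sizes used by the test-suite and acceptance script

The structural-recovery checks run the full selection grid (G = 2..8, common
orders 0..5, 5% minimum group) on cohorts of 2000 patients with three EM
restarts per candidate; the headline proportion is recomputed on 5000
patients with ten restarts. Bootstrap-coverage checks use 50 cohorts of 300
patients with 150 bootstrap replicates, and the null-calibration check uses
20 simulated null cohorts of 400 patients. These sizes were chosen as the
smallest at which the binomial/bootstrap tolerances quoted in the tests are
meaningful; all scale linearly if increased.

## Known limitations

* Shared $\sigma$ across groups and months; group- or time-specific
  variances are not implemented.
* No non-normal outcome families (zero-inflated Poisson, censored-normal is
  the only alternative family), no time-varying covariates inside the
  mixture, and no standard errors for the curve coefficients.
* The common-order grid plus greedy refinement does not guarantee the
  globally best per-group order combination.
* Multinomial regression offers Wald inference only, with no
  multiple-testing correction (matching the analysis it mirrors).
* EM restarts reduce but cannot eliminate the risk of local optima; the
  restart log-likelihoods are kept in the fitted object so flat or
  multimodal restart profiles are visible.
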