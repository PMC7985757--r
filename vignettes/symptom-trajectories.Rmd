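---
title: "Modeling longitudinal symptom-burden trajectories with symtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling longitudinal symptom-burden trajectories with symtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symtraj)
```

## The problem

Patients with advanced cancer report symptom severity repeatedly over the
course of their care, most commonly on the Edmonton Symptom Assessment
System (ESAS): nine items — pain, tiredness, drowsiness, nausea, lack of
appetite, shortness of breath, depression, anxiety and wellbeing — each
scored 0–10. The sum of the nine items is the total symptom distress score
(TSDS), ranging 0–90. Averaging TSDS over a whole cohort hides the fact
that patients follow qualitatively different courses: some stay at low
burden, some deteriorate, some improve under treatment, and some carry a
high uncontrolled burden throughout. `symtraj` identifies such latent
subgroups with group-based trajectory modeling (GBTM), a finite-mixture
model in which each latent group follows its own polynomial mean
trajectory over time.

## The model

For patient $i$ with transformed scores $y_{it}$ at times $t$ (months
since diagnosis), the mixture likelihood is

$$L_i = \sum_{j=1}^{J} \pi_j \prod_{t} f_j(y_{it}),$$

where $\pi_j$ are membership probabilities (multinomial logit, last group
as reference) and $f_j$ is a censored normal (CNORM) density with group
mean $\mu_{ijt}$ and shared residual SD $\sigma$: normal between the
censoring bounds, with the lower-tail mass $\Phi((y_{\min}-\mu)/\sigma)$
attached to observations at or below $y_{\min}$ and the mirrored mass at
the upper bound. The group mean is

$$\mu_{ijt} = \beta_j^\top (1, u, u^2, \dots) + \alpha_j^\top w_{it},
\qquad u = t/10,$$

a polynomial of group-specific order 0–4 plus additive effects of binary
time-varying covariates $w$ (chemotherapy, radiotherapy, home care,
palliative care in the 0–7 days before an assessment). Maximizing
$\sum_i \log L_i$ directly over all parameters gives the maximum
likelihood fit; posterior membership probabilities follow from Bayes'
rule, and each patient is assigned to their maximum-posterior group.

### Why a transformed outcome

Raw TSDS is strongly right-skewed. The package works on the Box–Cox
transformed scale with $\lambda = 0.25$ and a +1 shift inside the power,

$$g(x) = \frac{(x+1)^{0.25} - 1}{0.25},$$

which maps 0 to 0, 15 to exactly 4, 80 to exactly 8, and 90 (the scale
maximum) to about 8.354. All modeling and reported trajectories use this
scale.

### Numerical choices

* **Optimizer.** Quasi-Newton (BFGS) on the full observed-data
  log-likelihood with the analytic score function, rather than classical
  EM: the censored terms make the M-step non-closed-form, while the score
  of the mixture (posterior-weighted per-group gradients, with
  inverse-Mills-ratio terms at censored points) is cheap and exact.
  Multiple starts (default 10; fewer in large ladders) guard against
  local optima; starts are a k-means split of per-patient mean outcome,
  perturbed per start. Convergence is declared at a relative
  log-likelihood change below `tol` (default 1e-6, `max_iter` 500); the
  optimizer runs in chunks and records the improvement path, which is
  non-decreasing by line-search construction.
* **Time scaling.** Months are divided by 10 before powering, so quartic
  terms over multi-year follow-up stay well conditioned
  ($72^4 \approx 2.7\times10^7$ would otherwise dominate the Hessian).
  Coefficients are reported on the scaled axis and the scale is recorded
  in the fit.
* **Censoring bounds.** Default bounds are 1 unit outside the observed
  range, making the censoring inactive — appropriate when the data show
  no floor/ceiling clustering. When a group mean sits near the
  transformed-scale ceiling (8.354), bounds should be placed at the
  natural scale limits `c(0, tsds_transformed_max())` so the ceiling mass
  is modeled rather than biasing the mean downward.
* **Label order.** After fitting, groups are relabeled by ascending
  time-averaged fitted trajectory, so group 1 is always the
  lowest-burden group. Ties in the posterior argmax go to the lowest
  group index.
* **Standard errors.** Observed information (numerical Hessian via
  `optimHess`) at the optimum; if it is numerically singular (typical
  for over-parameterized candidates visited during order step-down) a
  Moore–Penrose generalized inverse supplies wide but usable SEs.

## Preprocessing rules

`preprocess_cohort()` applies, in order:

1. **TSDS and imputation.** Sum of nine items; with 1–4 items missing
   (≤ 50%) the TSDS is the mean of present items × 9 (keeping the 0–90
   scale); with ≥ 5 missing the assessment is excluded.
2. **Same-day duplicates.** At most one assessment per patient-day; the
   higher raw TSDS wins, ties keep the first record in input order (the
   choice is immaterial downstream since tied records contribute the
   same score).
3. **Patient filters.** Patients with fewer than three surviving
   assessments, patients whose every recorded item score is zero
   (treated as data error), and patients missing the income quintile are
   excluded, with a per-reason log.
4. **Dataset assembly.** Time is days since diagnosis divided by 30.4375
   (365.25/12); only the first 30 assessments per patient enter the
   model; each assessment carries four service flags true when the
   service occurred in the closed window `[date − 7, date]` (day 0 and
   day −7 inclusive). Wellbeing is summed as scored, without reversal.

## Model selection

`select_model()` implements the iterative search: starting from one
group with a quartic trajectory, the number of groups grows while the
log Bayes factor — approximated as twice the difference of BIC values on
the convention $\mathrm{BIC} = \log L - \tfrac{k}{2}\log N$ ($N$ =
patients, higher is better) — exceeds 10. Then each group's polynomial
order is stepped down, sweeping groups left to right repeatedly, while
the group's highest-order coefficient is non-significant at
$\alpha = 0.05$ (Wald). Secondary criteria are advisory, not
auto-rejecting: group membership of at least 5% and the classification
adequacy thresholds

* AvePP (mean posterior among assigned patients) > 0.7,
* OCC $= \frac{\mathrm{AvePP}/(1-\mathrm{AvePP})}{\pi/(1-\pi)} > 5$,
* $|\pi_j - P_j| \approx 0$ (estimated probability vs assigned share).

The counting rule for $k$ is $(J-1)$ membership logits $+\sum_j
(\mathrm{order}_j+1)$ polynomial terms $+$ per-group covariate effects
$+1$ for $\sigma$; e.g. six groups with orders 444000 and no covariates
give $5 + 18 + 1 = 24$. $N$ is the number of patients, not observations
(both conventions exist in trajectory software; patients is the number
of independent likelihood contributions).

An exhaustive search over all order combinations is out of scope; the
ladder heuristic above is what the package commits to.

## Covariate modeling

A three-stage workflow mirrors common GBTM practice: (1) select the
unadjusted model; (2) regress assigned group on time-fixed baseline
covariates with `membership_model()` (multinomial logit, Wald tests);
(3) re-estimate jointly — time-varying covariates enter the group means
via `tv_covariates`, and any retained baseline covariates enter the
membership logits via `x_membership`. Because the literature the
procedure comes from is ambiguous about whether stage 3 re-estimates the
membership equation jointly or conditions on stage-1 shapes, both entry
points are exposed; the joint route is the default recommendation.

## The synthetic cohort generator

No public dataset carries the administrative linkage this analysis was
designed for, so `generate_cohort()` produces cohorts with the
statistical structure the model assumes, and `inject_artifacts()` adds
the pathologies the preprocessing targets. Defaults describe a
plausible metastatic breast cancer cohort: ~995 patients, six groups
(three lower changing quartic, three higher flat) with membership
probabilities (0.115, 0.099, 0.121, 0.246, 0.265, 0.154), residual SD
1.0 transformed units, a mean of 16 assessments per patient (first at
diagnosis, exponential gaps of mean 1.5 months rounded to 0.25-month
resolution), diagnosis dates spread over five calendar years with
administrative censoring at 72 months after the earliest diagnosis,
group-specific monthly death hazards (0.005–0.022) truncating the visit
stream, per-visit service flags with additive mean effects (−0.10 to
+0.35), 1% item missingness, 3.7% same-day duplicates, 20% of patients
truncated below three assessments, 0.5% all-zero patients and 0.3%
missing income. Where the emulated study reports totals (patients,
assessments per patient, duplicate counts, survival mix) the defaults
match them; visit spacing is unconstrained by any source and was fixed
once at a clinically plausible ambulatory cadence.

The latent trajectory value is drawn first, clamped to the transformed
scale, back-transformed, rounded to an integer 0–90 target and split
across the nine items by a capped multinomial. Only the sum is
meaningful; no attempt is made to reproduce real ESAS item-level
correlation, and ED visits are Poisson counts without temporal
clustering. The generator records the latent value per assessment: the
normality property of the generator is checked on it, because integer
rounding quantizes the observed score by up to ~0.12 transformed units.
Consequently, passing tests demonstrate correct recovery under the
generator's assumptions (shared polynomial means, normal noise,
independent visits), not robustness to real-data features such as
informative dropout, item-level missingness patterns correlated with
severity, or assessment schedules driven by disease state.

## Sensitivity analyses

* **Baseline median split.** Patients at or above the cohort median of
  the first assessment's raw TSDS (ties to the high side) are
  cross-tabulated against membership in the designated high-burden
  groups; Pearson chi-square, df 1, no continuity correction.
* **Death imputation.** Patients dying during follow-up receive monthly
  pseudo-assessments at the maximum transformed TSDS (8.354) from the
  death month to the end of follow-up, capped at 30 total assessments;
  the selected specification is re-fitted and the per-group maximum
  absolute trajectory difference on a shared grid is reported. The base
  dataset is never modified.

## A worked example

```{r example, fig.width = 7, fig.height = 4}
cfg <- simulation_config(n_patients = 300, seed = 7)
cohort <- simulate_study_cohort(cfg)
pre <- preprocess_cohort(cohort$assessments, cohort$patients,
                         cohort$services)
pre$data
table(pre$exclusion_log$reason)

fit <- fit_gbtm(pre$data, trajectory_spec(6, c(4, 4, 4, 0, 0, 0)),
                n_starts = 2, seed = 1)
fit
adequacy_diagnostics(fit)
plot_trajectories(fit)
```

On this scale (300 patients before filtering) the six-group fit takes on
the order of ten seconds. The acceptance script and test suite use 80
patients × 5 assessments for selection replicates, 200 × 10 for
parameter recovery and 500 patients for the study-scale emulation —
sizes chosen so each group still holds enough patients for stable
classification while whole ladders fit in seconds.

## Known limitations

* The shared residual SD across groups follows the standard GBTM
  formulation; heteroscedastic groups would be misfit.
* Dropout is treated as non-informative by the likelihood; the death
  imputation sensitivity probes, but does not model, informative
  missingness.
* The order step-down examines the highest-order term only, so a group
  can retain a quartic whose cubic is null.
* Quartic trajectories extrapolate badly outside the fitted time range;
  `predict_trajectory()` warns when asked to.
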