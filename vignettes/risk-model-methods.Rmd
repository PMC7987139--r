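---
title: "Partly conditional risk prediction for screening cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partly conditional risk prediction for screening cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenrisk)
```

## The estimation problem

Population mammography screening programs invite women aged 50–69 to a
screen every two years and, at each visit, record a small set of risk
factors that require no extra data collection: first-degree family
history of breast cancer, the history of benign breast disease (BBD,
grouped into a prior biopsy with unknown diagnosis, non-proliferative,
and proliferative disease), and radiologist-reported mammographic
features (mass, calcifications, asymmetry, architectural distortion, or
several of these at once). The question the package answers is: given
the profile recorded at a screen, what is a woman's probability of a
breast cancer diagnosis (invasive or DCIS) within the next
$\tau$ years, for $\tau = 2, 4, \dots, 20$?

Because BBD and mammographic features change over a woman's screening
life, a single baseline Cox model wastes the updated information, and a
time-dependent-covariate Cox model answers a different question (it
conditions on the *future* covariate path). The package implements the
*partly conditional* approach: every visit becomes a landmark, and the
model describes residual time to diagnosis from each landmark given the
covariates *measured then*.

## Model

Let $s$ index a woman's visits, $Z(s)$ her covariate vector at visit
time $s$, and $T$ her diagnosis time. Each visit with $s < T$
contributes one stacked record with residual time $T - s$ (or censoring
time $C - s$) and frozen covariates $Z(s)$. The hazard on the
residual-time axis $t$ is modelled as

$$\lambda(t \mid Z(s)) = \lambda_0(t)\, \exp\{\beta' Z(s)\},$$

and $\beta$ maximizes the stacked partial likelihood, treating a
woman's records as working-independent. All within-woman dependence
(her records share one event) is absorbed by a Huber sandwich
covariance clustered on the woman: $A^{-1} B A^{-1}$ with $A$ the
observed information and $B$ the outer product of per-woman sums of
score residuals. The naive inverse-information covariance is also kept;
on one-record-per-woman data the two agree.

Ties on the residual-time axis are handled by the Efron approximation
by default — stacking makes heavy ties possible in registry data even
though they are absent in continuous simulations — with Breslow
handling available (`ties = "breslow"`). Newton–Raphson with
step-halving iterates until the score norm falls below $10^{-8}$ (50
iterations maximum); the log partial likelihood is required never to
decrease. Age enters as a continuous linear term centered at 59.5
years; centering only relabels the baseline hazard (it refers to a
59.5-year-old with no risk factors) and leaves hazard ratios and
predicted risks unchanged, which the tests verify by refitting under a
shifted age scale.

Absolute risk uses the Breslow baseline cumulative hazard
$\hat\Lambda_0(t) = \sum_{t_k \le t} d_k / \sum_{j \in R_k}
\exp(\beta' Z_j)$ (with the Efron-consistent tie correction), giving

$$\widehat{\mathrm{risk}}(\tau \mid Z) = 1 - \exp\{-\hat\Lambda_0(\tau)
\, e^{\beta' Z}\}.$$

The exponential form rather than the product-limit form composes
cleanly with the step-function baseline; at screening-program event
rates (cumulative hazards below 0.1) the two differ by less than
$10^{-4}$. A horizon beyond the support of $\hat\Lambda_0$ is reported
at the last observed step and flagged `extrapolated`, never silently
extended.

## Internal validation

The cohort is split 60/40 *by woman* (seeded). The model is fitted on
the estimation side; every validation woman gets predicted risks from
her **baseline** (first) mammogram. Both halves of the
expected-to-observed comparison are computed in the validation
subcohort: the expected rate $E$ is the mean predicted $\tau$-year
risk, the observed rate is the Kaplan–Meier cumulative incidence at
$\tau$, and the ratio's 95% interval uses the standardized-ratio
(log-normal) form $\widehat{E/O} \cdot \exp(\pm 1.96/\sqrt{O})$ with
$O$ the observed event count (an exact-Poisson variant is available via
`ci = "exact"`). Discrimination at each horizon is the AUC over
case–control pairs — cases have an event by $\tau$, controls are
followed event-free at least $\tau$ years, and women censored
event-free before $\tau$ are excluded — with the Hanley–McNeil
standard error ($Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$). The AUC is
computed from midranks, so any strictly monotone rescaling of the
scores leaves it unchanged. Multiple horizons are reported without
multiplicity adjustment.

Two design points deserve emphasis. First, evaluating predictions at
the baseline landmark (rather than per-visit) matches the horizon-AUC
definition above and keeps one independent observation per woman;
per-visit dynamic evaluation is possible with the same functions by
passing stacked records as profiles. Second, inverse-probability-of-
censoring weighting for the AUC is deliberately out of scope: the
exclusion rule above is the primary definition, and the package
documents rather than hides its censoring sensitivity.

## The synthetic screening cohort

No public registry deposits individual screening histories, so the
package ships a generator whose defaults *are* the study conditions the
analysis assumes, and every statistical claim in the test suite is made
against it.

- **Entry and attendance.** Entry age is drawn from the program mix
  (52.97 / 21.46 / 19.01 / 6.56% across 50–54, 55–59, 60–64, 65–69,
  uniform within band). Visits are biennial; after each round a woman
  continues with probability 0.81 (death and drop-out folded together,
  since a screening registry cannot separate them), stopping at age 69.
  The continuation default was tuned once so that mean follow-up is
  ≈ 7.5 years, the figure the emulated program reports.
- **Covariates.** Family history (prevalence 13.86%) is fixed at entry.
  BBD starts from the program prevalences (74.64 / 21.72 / 3.20 /
  0.45%) and is absorbing and ordered — a per-round probability
  (0.8 / 0.4 / 0.08% by default) of acquiring a first BBD category,
  after which the category never regresses. Mammographic features
  follow a reversible persistence chain: a non-none feature repeats at
  the next screen with probability 0.95 and otherwise reverts to none,
  while feature-free women acquire category $c$ with probability
  $p_c(1-\rho)/p_{\mathrm{none}}$; this keeps the per-visit marginals
  exactly at the program prevalences (71.99 / 18.12 / 2.71 / 2.81 /
  1.04 / 3.33%) for any persistence $\rho$.
- **Why high persistence matters.** The partly conditional fit
  estimates, for each factor, an average association between the
  *landmark* value and the hazard over the following years. If features
  were re-drawn independently at every screen, a baseline calcification
  would carry no information two years later and the fitted hazard
  ratio would shrink far below the generating one — not an estimator
  defect but a genuine change of estimand. With $\rho = 0.95$ the
  frozen covariate still describes the hazard years later, the model is
  near-correctly specified at every landmark, and the fitted hazard
  ratios recover the generating values (a small residual attenuation,
  under half a robust standard error at 60,000 women, remains for the
  feature factors and is visible in the recovery experiments).
- **Events.** Given the covariate path, event times are drawn by
  inversion from the piecewise-constant hazard
  $\lambda_0 \exp\{\beta' Z(s)\}$ on each 2-year interval, with the
  generating $\beta$ equal to the published point estimates (family
  history 1.67; BBD 1.36 / 1.41 / 3.02; features 1.32 / 2.52 / 1.66 /
  2.07 / 1.86) and a zero age effect so recovery experiments have a
  known truth. Women without an event are censored at their last
  attended mammogram + 2 years. $\lambda_0$ is calibrated so the
  marginal incidence is 2.183 events per 1,000 woman-years (the
  published margin: 1,203 cases over 551,023 women-years); the analytic
  calibration divides the target by the mean relative hazard over the
  stationary covariate mixture and is exact when effects are null, with
  a simulation-bisection alternative for configurations far from
  stationarity.
- **What it does not emulate.** Calendar-period effects, breast
  density, genetic risk, recall/false-positive workflow, death as a
  competing risk, and interval- versus screen-detected labelling. Tests
  passing on this generator therefore show the *estimators* behave as
  claimed under the stated conditions, not that real screening data
  satisfy those conditions.

## Numerical and degenerate-input choices

- Visits within a woman must have strictly increasing ages and unique
  times; tied visit times are rejected, not merged.
- Blank mammographic-feature cells are schema errors (only explicit
  `"none"` is a category); missing family history or BBD is legitimate
  input removed by the exclusion stage, which logs one count per rule.
- A model level with no variation is dropped from the design with a
  record in `dropped_terms`; a level whose coefficient diverges
  (all/no events) is flagged `possible_separation` rather than
  silently reported.
- The log-minus-log proportional-hazards curves are compared on the
  central part of each level's event-time range (5th–90th percentile):
  the transform amplifies Kaplan–Meier noise in the tails.
- With zero observed events the E/O ratio is undefined and returned as
  `NA` rather than infinite.

## Problem sizes used by the checks

The acceptance experiments use one cohort of 60,000 women
(≈ 225,000 stacked records) for parameter recovery and split-sample
calibration, and 200 replicates of 20,000 women for the coverage study
— sizes chosen so each experiment finishes in minutes on a single core
while keeping the Monte-Carlo error of a hazard ratio near 10% and of
a coverage proportion near 1.5 points.

## Known limitations

- **Standardized-ratio CI coverage.** The Breslow–Day-type interval for
  E/O treats only $O$ as random. At registry scale ($O$ in the
  thousands and an estimation cohort several times larger) the
  sampling error of $E$ is comparatively small; at desk scale it is
  not, and the interval undercovers. In the package's own 200-replicate
  study the E/O interval covers 1.0 at the nominal rate at the 2-year
  horizon but falls below 90% at 10 and especially 20 years, where the
  baseline hazard's tail rests on the few women observed for nearly 20
  years. This is a property of the published interval form, faithfully
  implemented, and the main reason long-horizon calibration statements
  at these sample sizes should be read with the Monte-Carlo error of
  $E$ in mind.
- **Long-horizon discrimination and the age term.** Controls for the
  horizon-$\tau$ AUC must be followed event-free for $\tau$ years; at
  horizons near the maximum follow-up they are therefore exclusively
  women who entered the program young, while cases span all entry
  ages. The default generator sets the true age effect to zero (so
  recovery experiments have a known truth), which makes the fitted age
  coefficient pure sampling noise — and any nonzero value then
  separates late-horizon cases from controls by age alone, dragging
  the 18–20-year AUC toward (and below) 0.5 on unlucky draws even
  though the risk-factor signal is intact (removing the age term
  restores AUC ≈ 0.58 at 20 years in the package's own experiments).
  Horizons up to ~12 years are unaffected. With a genuine age effect,
  as in real cohorts, the age term carries signal rather than noise.
- **Small cells.** The proliferative-BBD level carries < 1% prevalence;
  at 20,000 women its Wald interval relies on a handful of events and
  occasional replicates are inestimable (flagged, excluded from
  coverage counts).
- **Estimand under covariate turnover.** With feature persistence well
  below 1, the landmark hazard is genuinely non-proportional over long
  residual times and a single coefficient is an average; the
  log-minus-log diagnostic and the persistence parameter let users
  explore this directly.
- The generator's women-years bookkeeping in the hazard-ratio table
  sums *stacked* residual time per level (each woman counted from every
  landmark), which is the quantity the stacked fit weights; it is not
  comparable to a woman-level person-years margin.
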