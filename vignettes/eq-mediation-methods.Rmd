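---
title: "Methods: counterfactual mediation with a latent employment-quality typology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: counterfactual mediation with a latent employment-quality typology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqmediate)
```

## The problem

Women report worse general and mental health than men, and they also work
disproportionately in poor-quality employment.  `eqmediate` asks how much of
the gender gap in two binary health indicators — poor self-rated health
(SRH, fair/poor versus good or better) and frequent mental distress (FMD, 14
or more mentally unhealthy days in the past 30) — is transmitted through
*employment quality* (EQ), treated not as a single scale but as a
six-category typology of employment arrangements (SER-like, Portfolio,
Inflexible skilled, Dead-end, Precarious, Optimistic precarious).

Two features make this statistically non-standard.  First, the mediator is
*nominal and latent*: it is measured only indirectly through 11 categorical
indicators of contractual and relational employment conditions, so it enters
the analysis via a latent class model.  Second, the decomposition must allow
*exposure–mediator interaction*: EQ may affect women's and men's health
differently.

## The model

### Step 1 — measurement

A `T`-class multinomial mixture over the 11 indicators, fitted by
survey-weighted EM ([fit_lca()]):

$$P(y_i) = \sum_{t=1}^{T} \pi_t \prod_{j \in \mathrm{obs}(i)}
  \theta_{t, j, y_{ij}},$$

with missing items marginalized by omission and weights entering as
log-likelihood multipliers (pseudo-maximum likelihood).  The measurement
model is deliberately unconditional — no covariates — so the meaning of the
classes is fixed before any structural modelling.

### Step 2 — classification error

Each respondent is modally assigned to the class $W_i$ with the highest
posterior probability.  The assignment is a noisy indicator of the true
class $X_i$; its error rates are summarized by
$$D_{ts} = P(W = s \mid X = t)
  = \frac{\sum_i w_i \, p_{it}\, 1[W_i = s]}{\sum_i w_i \, p_{it}},$$
computed once from the Step-1 posteriors (`classification_error_matrix()`).

### Step 3 — corrected structural model

Gender $A$ (0 = man, 1 = woman) affects class membership through a
multinomial logit with coefficients $\gamma$, and the outcome through a
logistic model with coefficients $\beta$ that includes class main effects
*and* gender-by-class interactions; both adjust for age band,
race/ethnicity, nativity and survey wave.  Rather than conditioning on the
error-prone $W$, the two regressions are estimated *jointly* under the fixed
measurement density $D$ (the maximum-likelihood three-step correction):

$$\ell(\gamma, \beta) = \sum_i w_i \log \sum_{t=1}^{T}
  P(X_i = t \mid A_i, C_i; \gamma)\; D_{t, W_i}\;
  P(Y_i \mid A_i, X_i = t, C_i; \beta)^{\,r_i},$$

where $r_i$ flags an observed outcome: respondents missing an outcome still
inform $\gamma$ but contribute nothing to $\beta$.  As the classes become
perfectly separated, $D \to I$ and the model collapses to ordinary
regressions on $W$ — a reduction the test suite verifies coefficient-wise.

### Effect decomposition

With $\mu(a, a^*) = E\!\left[Y(a, M(a^*))\right]$ estimated by g-computation
(standardizing over the pooled, survey-weighted confounder distribution of
the analytic sample):

* total effect $TE = \mu(w, w) - \mu(m, m)$;
* pure direct effect $PDE = \mu(w, m) - \mu(m, m)$ — the gender gap with the
  EQ distribution held at men's levels (a *disparity residual*);
* total indirect effect $TIE = \mu(w, w) - \mu(w, m)$ — the gap attributable
  to EQ (a *disparity reduction* achievable by equalizing EQ);
* pure indirect effect $PIE = \mu(m, w) - \mu(m, m)$; and
* mediated interaction $INTmed = TIE - PIE$.

$TE = PDE + TIE$ and $TIE = PIE + INTmed$ hold identically, and the package
asserts both to $10^{-12}$ on every fitted and every bootstrapped
decomposition.  Positive probability differences mean worse expected health
among women.  Odds ratios for TE, PDE and TIE are formed from the same
marginal counterfactual probabilities (not from coefficients), so each
printed probability difference and its odds ratio describe the same
contrast.

### Intervals

Respondent-level nonparametric bootstrap with bias correction
(`bc_bootstrap()`): rows are resampled with replacement carrying their
weights, the structural model is refitted, and per scalar effect the BC
interval takes bootstrap quantiles at
$\Phi(2 z_0 \pm z_{1-\alpha/2})$ with
$z_0 = \Phi^{-1}\!\big(\#\{\hat\theta^*_b < \hat\theta\}/B\big)$.
The reference analysis uses $B = 10{,}000$; tests use scaled-down $B$.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `T` | 6 | number of EQ classes |
| `n_starts` (LCA) | 20 | random EM starts; $\theta$ from Dirichlet perturbations of empirical frequencies, $\pi$ uniform |
| `tol` (LCA) | 1e-7 | absolute log-likelihood change stopping the EM |
| `grad_tol` (structural) | 1e-6 | scaled score norm declaring convergence |
| `coef_bound` | 20 | box bound on structural coefficients (logit scale) |
| `B` | 10,000 reference / scaled down in tests | bootstrap resamples |
| `alpha` | 0.05 | two-sided interval miscoverage |

## The synthetic-data generator

Real GSS microdata are not shipped; instead [default_config()] defines a
calibrated data-generating process with known ground truth:

* gender-specific class-membership distributions of
  `default_calibration()` (e.g. Portfolio: 4.6% of women vs 17.5% of men;
  Precarious: 21.5% vs 10.6%);
* class- and gender-specific outcome probabilities (e.g. poor SRH among
  Precarious women: 16.0%);
* confounder margins and the 53.5% share of women matching the analytic
  sample of 6367 wage earners;
* an 11-item measurement model (`default_theta()`) whose binary and
  3-category response profiles follow the qualitative character of the six
  types.

The $\gamma$ and $\beta$ coefficients are back-solved exactly by inverting
the multinomial and logistic links on the confounder-free reduced model;
confounder and wave coefficients are zero by default so the implied marginal
tables equal the calibration targets exactly, while the covariates still
flow through every downstream fit as adjustment terms.  The pooled class
prevalence is therefore *implied* by the gender-specific distributions and
the gender mix rather than being a separate target.  Confounders are drawn
independently of gender by default (they are mediator–outcome confounders in
the assumed causal structure); gender-specific margins can be supplied to
mimic observed race/nativity imbalances.  Weights default to 1; a mean-one
lognormal law exercises the weighted-likelihood path, since real survey
weights are not published at respondent level.  Missingness is MCAR per item
and outcome, consistent with the ignorable-missingness treatment in the
likelihood; [simulate_study_sample()] instead plants the calibrated
missingness pattern as exact counts (32 respondents with <2 observed
indicators, 22 missing age, 32 missing SRH, 71 missing FMD in a sample of
6421).

What passing tests on these data do **not** show: robustness to
informative missingness, to residual confounding, to measurement
non-invariance of the indicators across gender, or to complex survey design
(strata/clusters are ignored; weights are taken as given).

A brute-force oracle ([true_effect_oracle()]) computes the true effects by
direct simulation — draw confounders, draw the class under gender $a^*$,
draw the Bernoulli outcome under gender $a$ — and reports honest Monte-Carlo
standard errors.  Recovery tests compare pipeline estimates at $n = 20{,}000$
against the oracle at $n_{mc} = 20{,}000$ within three *combined* standard
errors, treating the estimator's sampling noise at equal $n$ as comparable
to the oracle's binomial noise.

## Numerical choices

* LCA response probabilities are floored at $10^{-6}$ and renormalized each
  M-step; mixing proportions at $10^{-10}$.  The induced bias is negligible
  at these floors and they prevent $\log 0$ on sparse cells.
* Zero cells of $D$ are floored at $10^{-8}$ only for the serialized fixed
  logits; the likelihood uses the exact matrix (a structural zero simply
  removes that class term).
* The structural likelihood is maximized by L-BFGS-B with the analytic
  score, coefficients box-bounded at ±20.  Near-separated cells (an almost
  event-free gender-by-class combination) otherwise walk their logit along
  an essentially flat likelihood direction; the bound truncates the walk at
  a cell probability of about $2\times 10^{-9}$ without affecting other
  coefficients, and a warning flags any coefficient beyond ±15.  Bound
  components are excluded from the score-based convergence check.
* Posterior ties in modal assignment break toward the lowest class index
  and are counted.
* Bootstrap refits start from the full-sample estimates and use a looser
  function tolerance ($10^{-8}$): the resulting effect error (~$10^{-4}$) is
  far below bootstrap quantile noise at any realistic $B$.
* The BC proportion is clamped to $[1/(B+1), B/(B+1)]$ so $z_0$ stays
  finite when the estimate falls outside the bootstrap range; an all-equal
  bootstrap distribution collapses the interval to a point with a warning.

## Design decisions

* **Pooled standardization.** Counterfactual means average over the full
  analytic sample's confounder rows (both genders), so all five effects
  refer to one common standard population and the printed identities hold
  exactly.
* **Marginal odds ratios**, for the reason above.
* **Fixed measurement in the bootstrap.** The Step-1 model and $D$ are
  computed once and held fixed across resamples.  Refitting the mixture in
  every resample invites label switching; the fixed-measurement interval
  conditions on the measurement step, which is the standard practical
  compromise for three-step estimators.
* **Modal (not proportional) assignment** feeds $D$.
* **One deterministic optimizer start** for the structural model, from the
  naive known-class regressions.  Because $D$ is close to identity in
  practice, this start is near the optimum and the observed-data likelihood
  is well identified; perturbed restarts remain available via `n_starts`.
* **Reference categories**: men; SER-like; age 30–50; White; US-born; wave
  2002 — the largest observed categories where no convention exists.
  Effect estimates are invariant to this choice.
* **Eligibility order**: the indicator rule (≥2 observed of 11) precedes
  the age rule; rows missing only an outcome are retained for the mediator
  model.  Rows missing confounders other than age are retained and would
  surface as encoding errors only if a category were unseen.

## Problem sizes used by the test suite

Unit fixtures use 300–3,000 respondents; the calibrated recovery experiment
uses $n = 20{,}000$ with 4 LCA starts; the oracle-equivalence check uses
$n = 5{,}000$; bootstrap behaviour is exercised at $B = 100$–$200$ on samples
of 700–1,500 and interval coverage on 200 replications of a bootstrapped
mean at $B = 999$.  These sizes keep the full suite to roughly ten minutes
on one core while leaving every statistical assertion at conventional
3-standard-error strictness.

## Known limitations

* No BCa acceleration constant (bias correction only), matching the
  reference analysis.
* No design-based variance: strata and clusters are ignored; the bootstrap
  resamples respondents i.i.d. with their weights.
* The three-step correction assumes the Step-1 measurement model is
  correct and the classification error homogeneous given the true class;
  covariate-dependent misclassification is not modelled.
* Cross-sectional identification: the decomposition is interpreted as
  disparity reduction/residual under intervention on EQ, not as causal
  effects of gender itself, and unmeasured mediator–outcome confounding
  remains possible.
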