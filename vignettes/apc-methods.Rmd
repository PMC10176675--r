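---
title: "Smooth Age-Period-Cohort modelling of visit counts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smooth Age-Period-Cohort modelling of visit counts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcvisits)
```

## The problem and the model

Annual GP-visit counts vary with age, calendar period and birth cohort,
but age = period − cohort exactly, so additive age/period/cohort effects
are not identifiable: any linear trend can be attributed to the three
axes in infinitely many ways. `apcvisits` therefore treats the APC
question descriptively. For person $i$ with birth year $C_i$, observed in
calendar year $t$, the annual count of episodes of care $y_{it}$ is
modelled as

$$
y_{it} \sim \mathrm{Poisson}(\mu_{it}), \qquad
\log \mu_{it} = \alpha + u_i + s(C_i, t)
  + \beta_1\,\mathrm{nilf}_{it} + \beta_2\,\mathrm{unemployed}_{it}
  \;[+\, \beta_3\,\mathrm{perinatal}_{it}], \qquad
u_i \sim N(0, \sigma_u).
$$

Assumptions, in order of importance:

* **Smoothness across domains.** A person aged 25 in 2006 resembles a
  26-year-old in 2006 more than a 45-year-old in 2006 or a 25-year-old in
  2016. The surface $s(C, t)$ encodes exactly this: adjacent cohort ×
  period cells borrow strength, giving usable small-domain estimates even
  where single cells hold few observations.
* **Time-invariant multiplicative frailty.** Unobserved health and
  health-seeking propensity enter as a person-level log-normal multiplier
  $e^{u_i}$, constant over the panel. Within-person time-varying health
  shocks are absorbed into the global surface — the model assumes no
  person-specific APC effects.
* **Additive covariate adjustment.** Labour-force status (and, for
  eligible strata, a peri-natal service indicator covering the interview
  year and the year before) shift the log rate additively; reference
  category employed, no peri-natal services.

Because of the A = P − C identity, the unpenalised (null-space) part of
the surface is exactly the non-identifiable linear APC span. The package
therefore only ever reports the *sum* $\alpha + s(C,t)$ — prediction and
contrast surfaces — never separated age, period or cohort trends.
Equivalently: predictions at any (C, t) are invariant to how the linear
span is attributed; single-axis trends are not estimable and are not
exposed by any function.

## Episodes of care and the analysis panel

Claims extracts carry one line per billed item, so multi-item visits and
multi-day treatment sequences would over-count contacts.
`collapse_episodes()` merges dates on the same or consecutive days
(`gap_days = 1`) into one episode of care; the coarser `gap_days = 30`
variant used for sensitivity analysis merges whole 30-day sequences. An
episode is attributed to the calendar year of its **start date** — the
rule is not dictated by the data format; start-date attribution is
deterministic and independent of processing order, which is why it was
chosen.

`build_panel()` retains a person-year only when the survey wave covering
it reports an employment status ("complete information"). The wave → year
coverage map is configurable; the default assumes biennial waves in even
years, each covering the wave year and the following year, so a person
answering in 2004 and 2008 but not 2006 contributes 2004–2005 and
2008–2009 but not 2006–2007. Persons with complete survey data and no
claims are genuine zero counts and stay in the panel. The terminal
incomplete extract year should be excluded via `year_range`.

## Basis, penalties, identifiability

$s(C, t)$ is a tensor-product P-spline: cubic B-spline bases (default 8
functions per margin) on equally spaced knots over the observed cohort and
period ranges, row-wise Kronecker product, and one second-order difference
penalty per margin expanded by the other margin's identity — anisotropic
smoothing, since there is no reason for cohort- and period-direction
roughness to share a scale. These are the conventional P-spline defaults;
8 × 8 keeps the surface flexible at panel scale (15 periods, ~36 cohorts)
while fitting in seconds. A sum-to-zero-over-data constraint is absorbed
into the design so the surface is orthogonal to the intercept: $\alpha$
is then interpretable as the log rate of the reference person at the
data-average of the surface. The joint penalty null space (bilinear
functions of C and t, i.e. the non-identifiable APC linear span plus the
cross term) is split into unpenalised columns; with smoothing parameters
pushed to infinity the fitted surface tends to exactly that plane.

## Estimation

The default backend maximises a Laplace-approximate marginal likelihood:

1. **Inner loop** — penalised IRLS (Newton) over all coefficients. The
   design is assembled once as a sparse matrix over
   [covariates | raw tensor basis | domain cells | persons]; each Newton
   step needs one sparse cross-product, the constraint transform applied
   at the Hessian level, and a Cholesky factorisation in which the
   person block is eliminated analytically through its diagonal Hessian.
2. **Outer loop** — extended Fellner–Schall updates of the two smoothing
   parameters and the random-effect SDs against the REML-type Laplace
   criterion (fixed effects integrated with a flat prior). Repeated
   same-direction updates get geometrically growing strides, which
   matters when a variance collapses towards zero (plain multiplicative
   updates creep). Convergence: relative criterion change below `tol`
   (default 1e-8) or stabilised parameters; `maxit` 200.
3. **Intercept refinement** — mode-based Laplace slightly overstates the
   intercept, because posterior modes of $u_i$ understate
   $E[e^{u_i} \mid y]$; at the scale of this design the bias is about
   +0.014 on the log scale, enough to push $\alpha$'s Wald interval off
   target. A final one-dimensional refinement maximises the *exact*
   marginal likelihood in the intercept direction, evaluated by adaptive
   Gauss–Hermite quadrature per person (15 nodes centred at the posterior
   modes). After refinement the intercept bias in simulations is within
   Monte-Carlo noise of zero. The person modes are kept at their
   pre-refinement empirical-Bayes values; the ~1% inconsistency this
   leaves in conditional fitted values is documented and immaterial to
   every downstream quantity.

The MCMC backend (JAGS; weakly-informative priors — Normal(0, 5) on
unpenalised coefficients, half-Normal(0, 2) on all SD parameters with the
smoothing parameters expressed as SDs, truncated slightly away from zero
for numerical stability of the varying-precision tensor prior) samples
the full posterior and is retained as a fidelity check: on small panels
its fixed effects agree with the Laplace backend to well within 0.05 on
the log scale. A further independent cross-check against a
tensor-spline GAMM fitted by `mgcv` is part of the test suite.

Degenerate cases behave exactly: with `sigma_u = 0` and no smooth the fit
reduces to the closed-form Poisson GLM (`alpha = log(mean count)` for the
intercept-only model), and its predictive density is the Poisson pmf.

## Predictive density and model comparison

`log_pointwise_density()` scores a person-year by integrating the Poisson
likelihood over the random-effect uncertainty: the person's Gaussian
posterior when they appeared in training (`person_known = TRUE`),
otherwise the population distribution $N(0, \sigma_u)$; domain intercepts
are handled the same way. Under the Laplace backend the fixed and smooth
coefficients are plugged in at their estimates and the integral uses
Gauss–Hermite quadrature (25 nodes; agrees with adaptive deterministic
quadrature to ~1e-7); under MCMC the density is averaged over posterior
draws. Cohort/period values outside the fitted rectangle are clamped to
the boundary so edge observations in cross-validation remain scoreable.

`kfold_elppd()` compares the pooling variants — smooth surface, partial
pooling ($v_{C,t} \sim N(0,\sigma_v)$, shrinking every domain to the
global mean rather than to its neighbours), complete pooling (flat), and
the combination — by k-fold cross-validated elppd. Folds are assigned at
the observation level, stratified by person so each person's rows spread
across folds and their intercept stays estimable from training data; the
same folds serve every model. The pairwise difference standard error is
$\sqrt{n \,\mathrm{var}(d_i)}$ over pointwise log-density differences.

## Prediction surfaces

`reference_surface()` evaluates, on a one-year grid over the observed
cohort × period rectangle clipped to the observed age range (no
extrapolation — requesting points outside is an error):

* **median person**: $\exp(\alpha + s(C,t))$, the rate of the reference
  person (employed, no peri-natal services, $u = 0$);
* **population mean**: the median-person rate times
  $E[e^u] = e^{\sigma_u^2/2}$ — always at least the median-person rate,
  with equality only at $\sigma_u = 0$, and sharing its domain ranking
  exactly (both are monotone transforms of the same linear predictor);
* **proportion with at most k visits**: the Poisson CDF integrated over
  the frailty distribution by Gauss–Hermite quadrature.

Point estimates are plug-in at the estimated coefficients; intervals are
pointwise equal-tailed 95% quantiles over 4000 draws from the uncertainty
representation (the Gaussian approximation, with $\sigma_u$ plugged in,
or the posterior sample). `contrast()` differences the median-person
surfaces of two independently fitted strata, combining their draws
independently — justified because the strata are fitted separately — and
uses distinct draw sub-seeds per fit so that equal control seeds cannot
induce spurious correlation.

## The synthetic-data generator

`simulate_panel()` draws from the assumed data-generating process with
known ground truth: uniform birth years (1950–1985), Normal log-frailty,
a chosen smooth surface (`builtin_surface()`: flat, linear or quadratic
in age, a cohort ridge, or a U-shape in period), biennial survey waves
over 2002–2016 with first-order Markov employment dynamics (defaults
mirror a male parental panel: ~94% employed, persistence 0.8), iid
Bernoulli peri-natal flags in the eligible stratum, and uniform wave
skipping (10%). A baseline of 3 visits/year and frailty SD 0.5 match the
scale of observed parental GP use. `panel_to_records()` inverts a panel
into claim lines whose episode structure survives collapsing — episode
starts spaced more than the gap plus the maximal claim-run length apart,
and clear of year boundaries — so `build_panel()` recovers the counts
exactly; `max_episodes_per_year()` gives the physical ceiling this
implies (10 episodes/year under the 30-day rule), beyond which counts are
truncated with a warning.

What the generator deliberately does **not** emulate: household
clustering and consent-to-linkage selection, real birth processes behind
the peri-natal flags, non-uniform attrition, item-code frequency
structure, or any age structure in cohort membership. Passing tests
therefore demonstrate correctness of the machinery under the model's own
assumptions — not robustness to the selection effects a real linked
panel would carry.

## Numerical choices and limitations

* Problem sizes in the test suite: parameter recovery uses 100 replicates
  of 2000 persons × 15 years; model-ranking uses 20 replicates of 1000
  persons under 5-fold cross-validation — sizes at which one replicate
  fits in a few seconds on one core.
* Wald/Gaussian intervals condition on the selected smoothing and
  variance parameters; smoothing-parameter uncertainty is not propagated
  (the MCMC backend does propagate it).
* The Fellner–Schall update is a fixed-point scheme for the REML score
  with the weight-derivative terms neglected; its optimum can differ
  negligibly from the exact Laplace-REML optimum.
* Ties at a variance boundary ($\sigma_v \to 0$ when the smooth absorbs
  all domain structure) are handled by bounding precisions at 1e10 —
  i.e. the component is effectively removed, reported as a near-zero SD.
* `pmin(eta, 30)` guards the inner loop against transient overflow; no
  converged fit in the test suite is near that bound.
* All randomness (simulation, folds, interval draws, MCMC) flows through
  explicit seeds, and the global RNG state of the caller is always
  restored.
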