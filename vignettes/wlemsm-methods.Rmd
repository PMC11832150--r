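---
title: "Working life expectancy from panel-observed multi-state models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Working life expectancy from panel-observed multi-state models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wlemsm)
```

## The model

`wlemsm` models late-career work histories as a continuous-time Markov chain
over a small labelled state space.  The study configuration distinguishes
full-time work (30+ h/week), part-time work (10--29 h/week), not in work
(<10 h/week), and death, which is absorbing; collapsing full- and part-time
into a single "working" state gives the three-state configuration used for
total working life expectancy (WLE).  Every ordered pair of alive states is
an allowed instantaneous transition -- in particular, recovery from "not in
work" back into work -- and every alive state can transition to death.

Transition intensities are Gompertz, i.e. log-linear in age, with
multiplicative covariate effects:

$$q_{rs}(a, z) = \exp\!\big(\log q^{(0)}_{rs} + b_{rs}\,(a - 50) + \beta_{rs}^{\top} z\big),$$

so $q^{(0)}_{rs}$ is the baseline intensity at age 50 (1/year), $b_{rs}$ the
age slope (per year), and $\exp(\beta_{rs,c})$ the hazard ratio of covariate
$c$ on transition $r \to s$.  The age origin is fixed at 50: this makes
baseline intensities interpretable at the start of the pre-retirement window
and conditions the optimisation well.  Covariates are baseline-fixed; there
are no time-varying covariates in this version.  Occupational class or
education can enter either as additional additive indicator covariates or by
stratified fitting (a loop of independent fits per stratum, sharing all
machinery); additive is the default because it borrows strength across
strata, while the stratified route reproduces fully cross-classified models.

## Piecewise-constant approximation

The time-inhomogeneous chain is approximated by freezing the generator
$Q(a, z)$ within age bands (default width 1 year, covering ages 50--110),
evaluated at the band midpoint.  Interval transition probability matrices
are then ordered products of matrix exponentials,
$P(a_1, a_2) = \prod_k \exp(Q_k \Delta_k)$.  Whether the generator should be
evaluated at band midpoints or left edges is not determined by any external
convention; the midpoint is second-order accurate where the left edge is
first-order, and the residual discretisation error is quantified directly: a
test compares 1-year bands against a 0.01-year fine grid (agreement better
than $10^{-3}$ per matrix entry over ages 50--75) and verifies the error
shrinks monotonically through band widths 2, 1, 0.5, 0.25.  Ages beyond the
last band reuse the last band's intensities.

## The interval-censored panel likelihood

Panel data give states only at questionnaire waves; transition timing
between waves is unobserved, while deaths are exactly dated through register
linkage.  Each consecutive observation pair of a subject contributes:

* **alive at both waves**, states $r$ at $a_1$ and $s$ at $a_2$:
  $\log P(a_1, a_2)[r, s]$;
* **exactly dated death** at $a_d$: the event-time density
  $\log \sum_{m} P(a_1, a_d)[r, m]\, Q(a_d)[m, \mathrm{death}]$ over alive
  states $m$ -- the canonical treatment of an exactly observed absorbing
  transition in panel-observed Markov models;
* **censor set** $S$ at $a_2$ (state known only up to a set, e.g. "alive"):
  $\log \sum_{s \in S} P(a_1, a_2)[r, s]$.

A mid-sequence censor set equal to *all* alive states carries no information
when death is absorbing (paths through death cannot re-enter the alive
block), so such rows are absorbed by spanning the flanking interval; a
*partial* mid-sequence censor set would require a forward-algorithm
factorisation that this version does not implement and is rejected with a
clear error.  Encoding a missing wave as an all-alive censor set is
therefore exactly equivalent to dropping the row.

Subjects observed once contribute no likelihood terms but do enter the
entry-state distribution used for marginal expectancies.

## Estimation

The likelihood is maximised by BFGS on the flattened unconstrained parameter
vector (intensities enter on the log scale, so positivity is free), using
analytic scores: per band segment, the generator is eigendecomposed
($P = V e^{D\Delta} V^{-1}$, LAPACK `dgeev`) and directional derivatives of
the matrix exponential are evaluated through the Loewner (divided-difference)
matrix on the eigenvalues, contracted with forward and backward vectors of
each interval.  Eigenvector matrices with condition number above $10^8$ fall
back to scaling-and-squaring Pade exponentials with block-matrix
directional derivatives.  Generator spectra lie in the closed left half
plane; roundoff excursions of eigenvalue real parts above zero are clipped
so extreme parameter draws cannot produce exploding probabilities.

After BFGS, the observed information is computed by central finite
differences of the analytic score (step $10^{-4}$, overridable) and a few
Newton polishing steps sharpen the optimum.  Convergence is declared when
the optimiser reports success and the gradient max-norm falls below `gtol`
(default $10^{-3}$).  A tighter nominal threshold such as $10^{-6}$ is
attainable on well-conditioned problems -- the polish step typically lands
near $10^{-6}$ or below -- but at log-likelihood magnitudes of order $10^4$
a hard $10^{-6}$ requirement sits at the edge of double-precision
termination noise, so it is not the default definition of convergence;
`gtol` is a control parameter and the achieved gradient norm is always
reported.  The covariance of $\hat\theta$ is the inverse negative Hessian;
how singular information matrices are handled is described at the end of
this section.

Crude-rate starting values (observed wave-pair counts over person-years at
risk, covariate effects at zero) anchor the optimisation; transitions never
observed start at $\log 0.001$ with a warning.  The Gompertz panel
likelihood can be multimodal in $(\log q^{(0)}, b)$ for sparsely observed
transitions, and the zero-slope start occasionally sits in an inferior
basin, so by default the model is fitted from two deterministic starts --
slopes at zero and slopes at a demographically typical $+0.1$/year -- and
the higher optimum is kept.  The parameter space is bounded at
scientifically absurd values ($\log q^{(0)} \in [-20, 3]$,
$b \in [-0.7, 0.7]$, $\beta \in [-8, 8]$, all configurable): sparse cells
can have a *monotone* likelihood whose supremum sits at an infinite slope
or a zero rate (the Gompertz analogue of separation in logistic models),
and the box stops those ridge runaways while leaving interior optima
untouched.  Parameters estimated at a bound are reported with a warning,
convergence is judged on the gradient projected onto the feasible
directions, and unidentified (zero-curvature) directions of the information
matrix are given very large variances rather than the zero variance a
Moore--Penrose pseudo-inverse would imply.  Fits are deterministic given
the data and settings.

## Occupancy and working life expectancy

State occupancy from age 50 is
$\pi(u) = \pi_0^{\top} P(50, u)$, computed on a 0.25-year grid to a horizon
of 75 -- the oldest age at which anyone is observed in work in the
motivating design -- so every expectancy is horizon-truncated at 25 years.
Both settings are configurable; a step-refinement test bounds the trapezoid
integration error below $10^{-4}$ years.  WLE for a state subset is the
trapezoidal integral of its summed occupancy.

The expectancies are *marginal*: the start-age distribution $\pi_0$ is the
empirical distribution of observed states among subjects of the requested
covariate profile whose first observation falls in the entry band
$[50, 52)$ -- two years, matching the wave spacing.  An empty stratum falls
back to the pooled entry distribution with a warning.

Confidence intervals follow the parametric simulation recipe: 500 draws of
$\theta$ from $N(\hat\theta, \widehat{\mathrm{Cov}})$, recomputation of the
expectancies per draw, and 2.5th/97.5th percentiles.  The point estimate can
fall outside a percentile CI in pathological draw sets; this is flagged in
the result rather than hidden.  Draw covariances that are not positive
semidefinite are repaired to the nearest PSD matrix (eigenvalue clipping)
with a warning; draws yielding non-finite expectancies are dropped and
counted, and more than 1% dropped aborts the run.  For exposure contrasts
(strain minus no strain) the package reports *paired-draw* difference CIs:
the same parameter draws are used for both profiles and percentiles are
taken of the per-draw differences.  This removes common parameter noise from
the contrast and is the package's chosen interpretation of a
difference-significance statement; it is documented as such rather than as
the only possible construction.

## The synthetic cohort generator

Because the motivating study's registry-linked microdata cannot be
redistributed, the package ships a generator whose defaults emulate the
study design, giving every pipeline stage a ground truth:

* entry age $\sim N(56, 5)$ truncated to $[50, 75]$, rounded to 2 decimals;
* biennial waves; waves per subject drawn from 2..7 with weights
  (2666, 2741, 3492, 1252, 1142, 1539) -- the published follow-up
  distribution;
* 55.7% women; working at entry, full-time with probability 92.9% (men) /
  87.5% (women);
* job-strain prevalence 15.7% (men) / 21.2% (women);
* exact trajectory simulation of the time-inhomogeneous chain by thinning
  against a per-band dominating rate (band-maximum total exit intensity,
  valid because each Gompertz intensity is monotone within a band);
* the observation operator records the latent state at wave ages, discards
  everything between waves, and dates deaths exactly; deaths after the last
  scheduled wave are unobserved (the registry window closes with follow-up);
  a wave tied with the death age at 2-decimal resolution is superseded by
  the death record;
* optional non-informative per-wave dropout (off by default), with a switch
  to record missed waves as all-alive censor sets instead of truncation, and
  an entry-wave offset distribution for refreshment-style late entry
  (degenerate at zero by default).

The default *true* parameters are constructed, not published values (no
intensity estimates exist to copy): baselines and slopes were chosen once so
that, under the design above, total WLE at 50 for men without strain is
about 13.5 years and a strain hazard ratio of 1.35 on both work-to-not-in-work
exits shortens working life by roughly half a year to a year -- the
qualitative magnitudes reported for the motivating cohort.  They are
documented as illustrative and are not presented as estimates of any real
population.  The job-strain coder implements both defensible readings of a
median-split on averaged Likert items -- the demand/control quadrant rule
and the single demand-minus-control score rule -- with strict "above the
median" in both; the rule is a required explicit argument with no silent
default, because the verbal description of such coders does not determine
the rule.

What the generator does **not** emulate: survey sampling weights and the
two-stage recruitment design, calendar-time effects (everything depends on
age only), item-level psychometrics beyond the strain coder, informative
dropout (available only as an explicit stress-test switch), and state
misclassification.  Passing the recovery suite therefore shows that the
estimator inverts its own data-generating process at realistic sizes and
noise -- not that real questionnaire data meet the Markov, Gompertz, or
ignorable-dropout assumptions.

## Problem sizes used in validation

The test suite validates parameter and WLE recovery on 50 replicate cohorts
of 3000 subjects (the default scenario), requiring each true parameter
inside its 95% Wald interval and the true total WLE inside its 95%
percentile interval in at least 90% of replicates -- a binomial tolerance
band around the nominal 95%.  The null-effect check (paired difference CI
covering zero) uses 30 replicates of 1000 subjects.  These sizes were chosen
as the smallest at which coverage statements are meaningfully testable;
unit tests use cohorts of a few hundred subjects, with a higher-rate variant
of the scenario where every transition must be observed for identifiability.

## Known limitations

* Panel-observation likelihoods identify intensities only as well as the
  wave spacing allows; short spells between waves are invisible, and with
  few observed events for a transition the Wald machinery degrades (wide or
  invalid intervals, flagged by warnings).
* The model is Markov in age: no duration dependence (semi-Markov), a
  single absorbing state, no misclassification layer.
* Percentile CIs inherit the asymptotic-normality approximation of the MLE;
  entry-distribution sampling noise is not propagated into the CIs.
* Mid-sequence partial censor sets are not supported (see above).
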