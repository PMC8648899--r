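---
title: "Modelling radiation carcinogenesis with targeted and non-targeted effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling radiation carcinogenesis with targeted and non-targeted effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tentemix)
```

## The model

Ionizing radiation damages tissue through two mechanisms: *targeted effects*
(TE), the direct consequences of ionizing tracks traversing cell nuclei, and
*non-targeted* or bystander effects (NTE), damage in cells that were never
traversed, triggered by signals released from hit cells. At the low fluences
relevant for deep-space travel most cell nuclei are never traversed by a
heavy-ion track core, so NTE can dominate the response and make the
dose–response curve strongly concave at small doses.

`tentemix` models the latent mean tumour intensity per animal at dose $D$
(Gy) as

$$M(D) = B + N\,(1 - e^{-sD}) + T D$$

where $B$ is the background yield, $T$ (Gy$^{-1}$) is the linear TE slope,
$N$ is the plateau to which the NTE contribution saturates once all
susceptible cells respond, and $s$ (Gy$^{-1}$) is the NTE saturation rate.
There is no cell-killing downturn term: the model is intended for the
space-relevant dose range (up to a few Gy), where a linear TE term is
adequate for the APC^(1638N/+)^ mouse intestinal tumorigenesis system the
package emulates.

### Count variability: the weighted negative binomial

Tumour counts per mouse are both *underdispersed* (variance/mean < 1, e.g.
low-dose γ-ray groups) and *overdispersed* (high-dose Si groups) relative to
Poisson, depending on dose. A single classical count distribution cannot do
both, so counts follow a *weighted negative binomial* (WNB): a negative
binomial with mean $M$ and dispersion $r$, reweighted by
$(M + kq)/(M(1+q))$,

$$P_{WNB}(k) = \frac{(1+rM)^{-Y} r^k M^{k-1}\,\Gamma(Y)\,(M+kq)}
{\Gamma(1+k)\,\Gamma(1/r)\,(1+q)}, \qquad Y = k + \tfrac1r .$$

Its mean is $\mu = [M + q(1 + M(1+r))]/(1+q)$ and its variance/mean ratio
tends to $1/(1+q)$ as $M \to 0$ (underdispersion) while growing without
bound for large $M$ when $r > 0$ (overdispersion). The radiation-induced
*excess* yield subtracts the background:
$\mu_{rad}(D) = [N(1-e^{-sD}) + TD]\,(1+q(1+r))/(1+q)$.

All pmf computation is in log space through `lgamma`; the $M^{k-1}$ factor
at $k = 0$ is cancelled analytically against $(M + kq)$, so small $M$ is
safe. At $r < 10^{-8}$ an analytic weighted-Poisson branch replaces the
negative binomial core, because the difference
$\log\Gamma(k + 1/r) - \log\Gamma(1/r)$ loses precision when $1/r$ is
enormous; the fitting bounds keep $r \ge 10^{-6}$, safely away from the
branch. Random draws use inverse-CDF sampling over a pmf table extended
until the residual tail mass is below $10^{-12}$ (hard cap $10^6$).

### Background constraints

$B$ and $q$ are not free parameters. Both are pinned to the observed control
moments — mean 3.279 and variance 2.625 tumours per unirradiated mouse —
leaving only $r$ to determine them. The mean relation inverts exactly
($B_{sol}$, `b_solution()`); the variance relation has two roots in $q$, of
which only one is positive, and that root has a singularity in positive $r$,
so fitting uses the smooth approximant

$$q_{sol\_A} = 500\,\bigl(1 - \exp[-\exp(1.33 + 26.85 r - 20.95 r^2 +
1843.14 r^3)/500]\bigr)$$

composed into $B_{sol}$ (`q_approx()`, `b_approx()`). The exact numeric root
(`solve_q_exact()`, bracket $[10^{-8}, 10^4]$ with sign-change scan and
`uniroot` polish) is kept as a validation oracle. Measured accuracy of the
approximant: the background mean is reproduced exactly at all $r$ (algebraic
identity); the recovered background variance is 2.658 at $r = 0.047$ (1.3%
above the observed 2.625), drifts to about 6% at $r = 0.107$, and to roughly
20% at $r = 0.208$ where the approximant saturates at $q = 500$. These
regression bounds are asserted in the test suite. Both observed moments are
configurable so synthetic studies can use their own backgrounds.

## Fitting

`fit_wnb_model()` maximizes the joint WNB log likelihood over all radiation
types at once under a *sharing scheme*: a partition, per parameter, of the
types into groups sharing one value. The selected scheme of the mouse study
(`default_scheme()`) keeps $s$ common to all types, $T$ and $r$ common to
the sparsely ionizing group (γ, H, He, C, O) and separate for Si and Fe, and
$N$ separate for every type — 14 free parameters for 679 mice. Scheme
variants are ranked by AICc ($-2LL + 2k + 2k(k+1)/(n-k-1)$) with
`compare_schemes()`.

Constraints and numerics:

* All parameters are non-negative; optimization works on the log scale with
  box bounds ($r \ge 10^{-6}$, others $\ge 10^{-8}$).
* The particle-group $T$ is constrained to be at least the γ-group $T$.  By
  default this is enforced *jointly*: each particle group's $T$ is
  reparameterised as $T_\gamma + \delta$, $\delta \ge 0$, inside one
  simultaneous fit.  A two-stage mode (fit γ alone, freeze the bound) is
  available via `t_constraint = "two_stage"`, since the study description
  admits either reading.
* Multi-start: initial values are log-uniform over $[10^{-3}, 10^2]$ for
  $T$, $N$, $s$ and $[10^{-3}, 1]$ for $r$.  All starts are screened with a
  capped L-BFGS-B run, and the three leaders are polished to a $10^{-10}$
  relative tolerance on the log likelihood.  The production default is 2000
  starts; the test suite uses 6–25, which is sufficient because the
  screened landscape has few basins.
* The gradient of the log likelihood is analytic (chained through the
  background derivations $q(r)$ and $B(r)$), verified against central
  finite differences in the tests.  This makes one fit of the full design a
  few seconds rather than minutes.

Control animals enter the likelihood with $M = B$. Because $B$ and $q$
derive from a *group's* $r$, the controls must follow some group: the
package uses the reference (γ) group, which in the selected scheme also
covers the other sparsely ionizing types. This choice is configurable via
the scheme's `reference_type`.

## Radiation quality metrics

For each ion relative to γ rays the package computes, on a default grid of
50 log-spaced doses from 1 mGy to 2.54 Gy:

* **RER** (radiation effects ratio): $\mu_{rad}(D, ion)/\mu_{rad}(D, γ)$ at
  the *same* dose — always defined for this model.
* **RBE**: the iso-effect dose ratio $D_γ/D$ where
  $\mu_{rad}(γ, D_γ) = \mu_{rad}(ion, D)$.  Inverting the γ response uses
  the closed form with the principal Lambert W branch: with
  $Q_1 = T[1+q(r+1)]$ and $Q_2 = [(-(r+1)N + v)q + v - N]$,
  $D = (Q_1 W[e^{-sQ_2/Q_1} N s/T] + Q_2 s)/(Q_1 s)$.  A bracketed
  root-finding route must agree to $10^{-8}$ relative and serves as the
  permanent cross-check.  The W argument is non-negative for admissible
  (non-negative) parameters, so no branch ambiguity arises.

Both metrics agree asymptotically at very low doses (NTE-dominated) and very
high doses (TE-dominated); at intermediate, space-relevant doses RBE exceeds
RER for the fitted heavy-ion parameter sets. That inequality is a property
of these parameter values, not of the model family, and the package does not
assert it universally.

The Lambert W implementation is the package's own (`lambert_w0()`: series or
asymptotic initial guess plus Halley iteration, capped at 80 steps), written
for reliability across the full argument range the inverse response
produces, and validated against an independent implementation and the
defining identity $w e^w = x$ in the tests.

## Uncertainty: likelihood-region parameter clouds

Confidence intervals for parameters, dose–response curves, metrics, and
mixture predictions all come from one object: a *parameter cloud* of random
free-parameter combinations whose joint log likelihood is within
$\Delta LL$ of the maximum (`sample_cloud()`). The default
$\Delta LL = 1.92$ is half the 95% $\chi^2_1$ quantile — the
profile-likelihood convention; a joint region
($\Delta LL = \chi^2_{0.95, k}/2$) is available by passing a different
`delta_ll`, and this choice is surfaced prominently because it changes the
interval widths. Intervals are the min/max of each functional over the
cloud (a percentile mode can be had by summarizing `cloud$free` directly).

Proposal mechanics: a random walk over the acceptance region, stepping from
the last retained vector with Gaussian steps on the optimizer scale
(equivalently multiplicative log-normal perturbations of the natural
parameters), with the step direction shaped by the inverse Hessian of the
log likelihood at the optimum (from central differences of the analytic
gradient, eigenvalue-floored at $10^{-4}$ of the largest curvature). The
shaping matters: the $s$ direction is nearly flat above the fitted value —
the data only constrain saturation below the lowest tested dose of 0.05 Gy —
and an unshaped star sampler centred on the optimum provably fails to reach
the low-$s$ end of the region. The step size is adapted in batches toward a
10–40% acceptance rate, and the whole procedure is seeded.

## Mixtures: IEA versus SEA

For a mixture of ions delivered in fixed dose proportions $f_j$, *simple
effect additivity* (SEA) sums each component's effect at its own dose. SEA
is only valid for linear responses; for the concave NTE responses here it
badly overestimates. *Incremental effect additivity* (IEA) instead solves

$$\frac{dE}{dD} = \sum_j f_j\,\mu_{rad,j}'\bigl(F_{inv,j}(E)\bigr),
\qquad E(0) = 0,$$

advancing the mixture effect $E$ using each component's slope at its
*effect-matched* dose. The integration uses `deSolve::ode` (lsoda, relative
tolerance $10^{-8}$, absolute $10^{-10}$). At $E = 0$ the inverse is
degenerate but well-defined ($D_j = 0$ exactly), so no special
regularization is needed. For one component IEA collapses to that
component's own response, and when all components share a single linear
response IEA equals SEA — both identities are tested to integrator
tolerance.

The packaged Mars-mission mixture (`mars_mixture()`) uses the estimated
940-day mission doses in Gy — H 0.311, He 0.109, C 0.029, O 0.029, Si
0.022, Fe 0.019, total 0.519 — with the packaged best-fit parameters. At
the full mission dose IEA predicts about 4.7 excess tumours per mouse while
SEA predicts about 12.3, a ≈2.6-fold overestimate; the exact values are
computed, not quoted, by `scripts/acceptance.R` and the test suite.
Component doses are delivered proportionally along the dose ray
(simultaneous exposure); sequential scheduling is out of scope.

## The synthetic-data generator

The raw per-mouse tumour counts of the motivating experiment are not
public, so the package ships a generator (`apc_study_design()`,
`generate_dataset()`) that emulates the experiment's design: eight arms
(controls, γ, H, He, C, O, Si, Fe) with the recorded arm sizes (679 mice
total), LETs, and dose ranges, with tumour counts drawn from the WNB at the
packaged best-fit parameters (`apc_study_params()`). Only arm totals and
dose ranges are recorded for the original experiment; the per-dose-group
allocation here — an even split of each arm over a short documented dose
list spanning the recorded range, always including a 0.05 Gy group where
that dose was tested — is an explicit approximation, chosen once and kept.

What the generator does *not* emulate: tumour latency, survival,
inter-litter heterogeneity, dose-group imbalances of the real experiment,
or any deviation of real counts from the WNB form. Passing
parameter-recovery tests therefore demonstrates internal consistency of the
estimation machinery under the model's own assumptions — not fidelity of
the model to real mice.

## Problem sizes used in the tests

The test suite runs the full estimation pipeline at reduced but honest
sizes, chosen as the package's own defaults for routine verification:
parameter recovery uses 20 replicate synthetic studies of the full 679-mouse
design with 25 random starts per fit and likelihood clouds of at least 600
members; the production-scale settings (2000 starts, clouds above 7500)
are plain arguments away. Bias is judged against its Monte Carlo standard
error across replicates, and cloud coverage of the generating truth is
required in at least 90% of replicates per parameter.

## Known limitations

* The WNB likelihood surface is nearly flat in $s$ above ~50 Gy$^{-1}$ for
  designs whose lowest dose is 0.05 Gy; point estimates of $s$ are
  accordingly unstable even when the fit is excellent, and its upper
  confidence limit often runs to the optimizer bound.  Interpret $s$
  through its lower limit and the fitted curve, not its point value.
* The q-approximant saturates at 500, so for $r \gtrsim 0.2$ the implied
  background variance drifts above the observed value (measured ~20% at
  $r = 0.208$); the exact solver reports whether a positive root exists at
  all in that regime.
* Min/max cloud envelopes are conservative estimators of the region's
  extremes and converge from inside as the cloud grows; very small clouds
  understate interval widths.
* Dose–fluence conversion assumes unit tissue density (1 g/cm³), making the
  constant 0.1602 Gy·µm²/keV exact by definition rather than calibrated.
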