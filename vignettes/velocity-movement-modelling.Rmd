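---
title: "Velocity-based movement modelling with behavioural change points"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Velocity-based movement modelling with behavioural change points}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`veloseg` links telemetry data to environmental drivers through the
animal's *velocity* rather than its occupancy. Let `mu` be the (unknown)
movement path sampled at a regular resolution of `dt` hours, so that
`v_t = (mu_{t+1} - mu_t) / dt` is the velocity vector in km/h at step `t`.
Velocity is regressed on the local *gradients* of `p` spatially gridded
covariates — "potential" drivers: a positive coefficient means the animal
tends to move up-gradient (toward higher covariate values), a negative one
down-gradient, and a coefficient near zero means that covariate does not
direct movement. Categorical or site-based drivers enter through
distance-to-target layers, whose gradients point along the shortest path to
the target, so attraction to a central place (a rookery, say) appears as a
negative coefficient on the distance-to-site gradient — equivalently a
positive coefficient on movement toward the site when the sign convention
of the planted simulations is used.

Behaviour is not constant in time. The trip is partitioned into `K`
contiguous segments with segment-specific coefficient vectors:

    v_t ~ N( X(mu_t) beta_{k(t)}, sigma^2 I_2 ),

where `X(mu_t)` is the 2 x p matrix whose j-th column is the j-th
covariate's gradient at the current location, `k(t)` is the segment
containing step `t`, and one noise variance `sigma^2` (km/h)^2 is shared by
all segments and both axes. Assuming the two velocity components are
conditionally uncorrelated (directional drift, if any, belongs in explicit
drift columns, available via `drift = TRUE`), the bivariate model stacks
into a single univariate regression: all x-components above all
y-components, `2(T-1)` rows in total. Both components of a step always
share one segment.

## Priors and defaults

* `beta_k ~ N(mu_beta, Sigma_beta)`, independently per segment. Defaults
  `mu_beta = 0`, `Sigma_beta = 100 I` — diffuse on the scale of km/h per
  unit gradient, letting the data dominate.
* `sigma^2 ~ InvGamma(q, r)` with `q = 3`, `r = 20`: prior mean
  `r/(q-1) = 10` (km/h)^2 and prior variance 100, again diffuse. The shape
  must exceed 1 so the prior mean exists.
* Change-point locations: discrete uniform over all admissible ordered
  configurations, where admissible means strictly increasing with every
  segment at least `min_seg` steps long (default 5 — each segment must
  support its own p-dimensional regression, so p plus a little slack). The
  number of admissible m-point configurations has the closed form
  `choose(S + 1 - 2g - (m-1)(g-1), m)` for `S` steps and min gap `g`, which
  supplies the prior normalizer that variable-dimension moves need.
* The number of interior change points `m = K - 1` is Poisson(`lambda`),
  default `lambda = 1`. We place the prior on `m` rather than `K` so a
  single homogeneous segment stays in the support. For a single foraging
  trip of a central-place forager (one outbound/return switch expected),
  a prior mean of one change point is the natural choice; for longer
  records scale `lambda` with the expected number of behavioural switches.

## Path imputation

Fixes are irregular and noisy, so the velocity series is never observed
directly. A continuous-time correlated random walk — position integrating
an Ornstein–Uhlenbeck velocity with decay `ou_decay` (1/h) and volatility
`ou_scale`, isotropic Gaussian location error `obs_sd` km (optionally
scaled per error class) — is fitted by maximum likelihood. Numerical
choices, made once:

* Exact discretization of the integrated-OU transition for arbitrary time
  gaps (closed-form mean and covariance); Euler stepping is never used
  because irregular gaps are the norm, and `expm1` guards the small-decay
  limit.
* The likelihood is computed by Kalman filtering per axis (the axes share
  parameters); the initial state is a diffuse position prior (variance
  1e4 km^2) centred on the first fix and the stationary zero-mean velocity
  distribution.
* Optimization runs L-BFGS-B on log-parameters from five fixed starts
  seeded by crude data scales — CTCRW likelihoods can be multimodal in
  decay/scale — and keeps the best; asymptotic standard errors come from
  the numerical Hessian. Infeasible parameter corners return `-Inf` rather
  than propagating NaNs.
* `M` joint path realizations are drawn on the regular grid by forward
  filtering over the union of fix and grid times followed by backward
  sampling, vectorized over realizations; degenerate (noiseless)
  conditionals are handled by eigenvalue-clamped matrix square roots. With
  `obs_sd = 0` the draws interpolate the fixes exactly.

The fitter integrates over path uncertainty by composition: the `M` paths
(default 30) are drawn once, their designs precomputed, and each MCMC
iteration conditions on one pool member chosen uniformly at random —
multiple-imputation logic that keeps the path sampler out of the inner
loop.

## Covariates

Gradients are precomputed on the grid by central differences (one-sided at
edges) and bilinearly interpolated along paths; per-point spline
differentiation would dominate runtime since designs are rebuilt for every
pooled path. Missing cells are filled beforehand by exact thin-plate
radial-basis interpolation (`r^2 log r` kernel plus an affine term, fitted
on at most 5000 observed cells), which reproduces affine surfaces exactly.
Two time slices bracketing a trip's mean observation time are blended with
weights inversely proportional to the time gaps. The gradient of a
distance layer is undefined at the target itself; the target cell gets the
zero vector (the symmetric choice). Steps whose location falls outside a
raster's extent are dropped from that path's likelihood with a recorded
count — extrapolated gradients are untrustworthy.

## Sampling the partition

With `K` fixed, the sampler alternates conjugate Gibbs draws of each
segment's `beta` (Gaussian) and of `sigma^2` (inverse gamma,
`InvGamma(q + N/2, r + SSE/2)`) with symmetric discrete random-walk
Metropolis moves of each interior change point (window `tau_window`,
default 10 steps; proposals violating ordering or the minimum gap are
rejected outright, and the uniform location prior cancels).

With `K` random, the partition is treated as a point process whose points
are `(tau_k, beta_k)` pairs; the first segment is anchored at the grid
start and never born or dies. A continuous-time birth–death process runs
for virtual time `T0 = 1` per sweep: births arrive at rate `lambda_b`
(default: the Poisson prior mean, the standard convention), with the new
change point uniform on the feasible free times and the new coefficients
drawn from an empirical Gaussian *birth distribution* — per-time mean and
covariance of `beta(t)` from a preliminary fixed-`K` fit (default `K = 3`),
the covariance scaled by a tuning constant `c`. Each removable point dies
at the rate that exactly reverses a birth (posterior-kernel ratio times the
birth density, computed in log space), which makes the stationary law the
posterior regardless of `c`; `c` only affects mixing. A birth splits a
segment at the new point, the right part taking the newborn coefficients; a
death merges a segment into its left neighbour, whose coefficients survive
— exact mirrors of one another. `sigma^2` stays global and untouched by
births and deaths. `K` is capped at `K_max` (default 50) for memory
safety; posterior mass at the cap indicates misspecification. Because the
spacing constraint is enforced in both the birth support and the prior
normalizer, detailed balance holds on the constrained space; the test suite
verifies the stationary law against brute-force enumeration on a toy
problem.

The full iteration is: choose a pooled path; run one birth–death sweep;
Gibbs `sigma^2`; Gibbs `beta`; Metropolis `tau`. The Gibbs/Metropolis
refreshes are not required for correctness but dramatically improve mixing.
Convergence should be checked on the stored chains (`write_chains()`;
batch-means Monte Carlo standard errors via `velm_mcse()`).

## Model comparison

Under path imputation the likelihood is a complete-data quantity, so the
deviance information criterion uses the missing-data form

    DIC = -4 E_{theta,mu}[ log f(v | theta, mu) ] + 2 E_mu[ log f(v | theta_bar, mu) ],

with both expectations estimated from the stored joint draws and the
plug-in `theta_bar` taken as the per-time posterior mean `beta(t)` — well
defined even when `K` varies, unlike segment-indexed means — together with
the posterior-mean `sigma^2`. The mean and plug-in deviances are exposed so
alternative weightings can be recomputed. For fixed-`K` comparisons,
`BIC = -2 log Lhat + k(K) log n` with `n = 2(T-1)` and
`k(K) = Kp + (K-1) + 1`: segment coefficients, interior change points
(counted as free parameters — a documented choice) and the shared variance.
`all_subsets()` fits every nonempty covariate subset and ranks by DIC.

## Population level

Per-animal posterior-mean `beta(t)` trajectories (means, not draws — the
posterior spread is reported alongside but not clustered) are thinned
(default 1 in 100) to temper temporal autocorrelation, pooled across
animals, and clustered with full-covariance Gaussian mixtures fitted by EM
for 1–8 components, the winner chosen by BIC. Restricting to the
full-covariance family keeps the search one-dimensional (in the component
count) and testable. Components are relabelled 1..G by decreasing mixing
weight, which both matches the "most common regime first" reading and
breaks label switching; exact assignment ties go to the most prevalent
cluster. Per-animal time budgets over regimes (trips merged per animal,
rows summing to 1) feed a Gini classification tree (minimum leaf 3, depth
at most 3) whose resubstitution accuracy is the headline subgroup metric; a
cross-validated accuracy is reported next to it. Thinning reduces but does
not remove serial correlation in the pooled rows; the procedure follows the
stated 1-in-100 rule without claiming independence.

## The synthetic-data generator

`sim_scenario()` defines the study conditions; its defaults are a
central-place foraging trip: 500 one-hour steps on a 9-km grid (the
resolution of typical monthly ocean covariates), an active home-distance
gradient whose coefficient flips from +2 to −2 km/h at mid-trip, an
inactive Gaussian-bump covariate so selection has something to reject,
velocity noise `sigma^2 = 0.5 (km/h)^2`, exponential sampling gaps of mean
2 h, and 0.3 km Gaussian location error. Tracks are simulated forward at
the analysis resolution (the model is defined discretely at `dt`, so no
finer integrator is needed); steps that would leave the grid are redrawn,
then noise-shrunk, with a recorded retry count. What the generator does
*not* emulate: heavy-tailed Argos error classes (Gaussian error only, with
per-class scale hooks in `ctcrw_params`), movement barriers such as
coastlines, temporally varying covariate fields, and within-regime
autocorrelated residuals. Passing tests therefore demonstrate correctness
of the machinery under the stated conditions, not robustness to those real-
data complications. `sim_population_betas()` plants population regimes
directly in coefficient space (20 animals, three regimes, two subgroups
with different regime usage by default) to exercise the population
workflow without refitting every animal.

## Problem sizes and test design

The shipped tests run the sampler at deliberate desk scale: single-track
fits use 500–4000 iterations over pools of 6–30 imputed paths; recovery
and selection checks use 10–50 simulated replicates at `T` = 120–500; the
enumeration check runs 30,000 birth–death sweeps on an 8-step toy. These
sizes keep the whole suite to a few minutes while leaving the Monte Carlo
error well inside each check's tolerance; all tolerances are stated in
Monte Carlo standard errors or absolute probability differences, never
tuned to a particular draw.

## Known limitations

* **Imputation smooths sharp behavioural switches.** When the true
  velocity reverses abruptly, the fitted CTCRW (whose OU velocity is very
  persistent within regimes) rounds the corner over a window set by the
  estimated decay, and the change-point model honestly fits a short
  transition segment there. With imputation in the loop the posterior mode
  of the segment count can land one above the planted value even though the
  change-point location itself is recovered; credible-interval coverage for
  `beta(t)` is essentially unaffected. Fitting the known path removes the
  effect, isolating it to the imputation stage.
* Posterior `sigma^2` from imputed paths is attenuated relative to the
  generating value (smoothed paths under-disperse velocities); with known
  paths it is recovered.
* One shared `sigma^2` across segments and axes; no per-axis or
  autocorrelated residuals (by design, matching the model above).
* The BDMCMC prior on the segment count is known to be sensitive to model
  departures — smoothly varying true coefficients will drive `K` upward to
  approximate the trend; inference on `beta(t)` is much more stable than
  inference on `K`.
* No land-barrier handling: path realizations are not rejection-sampled
  against geography (an optional post-hoc filter hook on the pool is the
  natural extension point).
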