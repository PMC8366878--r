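---
title: "Modelling rotor-swept-zone entry risk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling rotor-swept-zone entry risk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the geometry,
the observation model, the hierarchical model and its sampler, what the
synthetic-data generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## 1. Geometry: zones as yaw-independent cylinders

Every volume in the analysis is a vertical cylinder in a local
east–north-up frame:

* the **rotor-swept zone** (RSZ) of a turbine has radius equal to the rotor
  radius (plus an optional `rsz_buffer`, default 0 m) and spans the minimum
  to maximum blade height. The minimum blade height is the registered
  maximum tip height minus the rotor diameter. For the two turbine models
  emulated by the generator this gives 50.5 m radius over 30.5–131.5 m,
  and 38.5 m radius over 42–119 m;
* the **inner** and **outer curtailment cylinders** take their radii
  (defaults 150 m and 350 m) from the curtailment criteria and span
  hub height ± half the criterion height (defaults 200 m and 400 m),
  clipped at ground level — a cylinder cannot extend below ground, and at
  an 80-m hub the default inner cylinder becomes 0–180 m.

Cylinders are yaw-independent on purpose: rotor orientation varies with
wind and is not recorded, so the sweep is taken as the full circle.
Boundaries are closed (a point exactly on the wall is inside); the choice
is arbitrary but must be fixed for the entry-time mathematics to be exact.

Geographic coordinates are projected with an equirectangular tangent-plane
projection about the centroid of the turbine layout
(`x = R·Δλ·cos(φ₀)`, `y = R·Δφ`, `R = 6,371` km). Over a facility extent
of a few kilometres this differs from a true geodesic projection by far
less than a metre, which is negligible against 1-Hz sampling of a bird
moving at 8–20 m/s. Altitudes are metres above local ground; when real
data supply altitudes above sea level, per-turbine ground elevations are
subtracted (`altitude_ref = "sea_level"`).

**Time to collision** is the smallest `t ≥ 0` at which the straight-line
extrapolation of the current position and velocity enters the RSZ, found
by solving the horizontal circle-crossing quadratic and intersecting the
resulting interval with the altitude band. The real detection system's
trajectory predictor is proprietary and undocumented; constant-velocity
linear extrapolation from a backward finite difference of the last two
track points is this package's documented stand-in. An independent
brute-force oracle (stepping the ray at 0.01 s) confirms the closed form
in the test suite.

## 2. From tracks to Bernoulli trials

A flight track is a time-ordered sequence of 1-Hz positions with an
eagle-classification confidence. Processing applies, in order:

1. **Confidence gate.** A track participates only if its maximum point
   confidence reaches the classification threshold (default 0.90).
   Gating at track level rather than per point avoids fragmenting a track
   whose confidence fluctuates around the threshold.
2. **Deduplication.** When two monitoring units track the same bird
   simultaneously (time ranges overlap, matched positions within 50 m),
   each matched time bin keeps the point from the unit nearer in 3D line
   of sight, and the survivors merge into one track. Pairs are resolved in
   (unit id, track id) order, so the result is deterministic, and the
   operation is idempotent.
3. **Approach detection.** An approach is an occasion on which a track
   occupies a turbine's inner curtailment cylinder at one or more points.
   "Within 150 m" could be read as pure horizontal distance, 3D line of
   sight, or inner-cylinder membership; the package defaults to
   inner-cylinder membership (horizontal ≤ 150 m *and* altitude within hub
   ± 100 m), because the 150-m figure enters the analysis as the inner
   cylinder's radius. `approach_mode = "horizontal_only"` gives the other
   reading; the choice moves only high- or low-flying edge cases.
4. **Entry outcome.** `y = 1` if any point of the whole track lies inside
   the approached turbine's RSZ. Since the RSZ is geometrically contained
   in the inner cylinder under the default criteria, every entry is
   necessarily an approach. A track near *k* turbines contributes *k*
   independent trials; in the study conditions about 91.5% of tracks
   approach a single turbine, so the residual pseudoreplication is left
   uncorrected, as in the source analysis. The month key of an approach is
   the calendar month of its first in-cylinder point.

Tracks are not interpolated between samples: the data are discrete 1-Hz
observations, and the synthetic generator guarantees its labels are
decidable at that resolution (see Section 5).

## 3. The hierarchical model

With approaches aggregated per observed turbine–month cell (`n` trials,
`k` entries — an identical likelihood, one binomial term per cell), the
model is a two-way random-effects ANOVA on the logit scale:

```
logit p[t,m] = mu + alpha_t + beta_m + gamma_tm,
alpha_t ~ N(0, s2_turbine), beta_m ~ N(0, s2_month), gamma_tm ~ N(0, s2_cell)
```

Priors are uniform: `mu ~ U(-10, 10)` and each *variance* (not SD)
`~ U(0, 25)`, honouring the "uniform for means and variances" convention
literally; both ranges are configurable and are vague on the logit scale
(±10 logits is far beyond any plausible entry rate). Main effects are
included by default (`include_main_effects = FALSE` gives the
interaction-only reading, a single random effect per turbine–month
combination). No sum-to-zero constraints are imposed; identifiability of
`mu` against the effect means is left to the hierarchical priors, which
with 110 turbines pins the decomposition well but means individual effects
should be interpreted through the cell probabilities, not in isolation.

**Sampler.** Adaptive random-walk Metropolis-within-Gibbs over blocks
(`mu`; all `alpha` elementwise; all `beta`; all `gamma`; variances). The
three effect blocks are updated with vectorised elementwise
accept/reject — each turbine's proposal interacts only with that turbine's
cells, so a whole block costs one pass over the observed cells. Variance
components are drawn exactly from their full conditional, which under a
uniform-on-variance prior is an inverse-gamma truncated to the prior
support (sampled by inverse CDF); for dimensions below three, where that
conditional's shape parameter is non-positive, a Metropolis step on the
log scale is used instead. Step sizes adapt toward a 20–50% acceptance
band during burn-in only and are frozen afterwards, so the kept draws come
from a fixed-kernel chain and detailed balance holds. Chains start from
dispersed values: `mu` at the empirical logit rate ± jitter, effects at
0 ± 0.3, variances near the middle of their support. Each chain's RNG is
seeded deterministically from the configuration seed, so a fit is
bitwise-reproducible.

Defaults (3 chains × 5,000 iterations, burn-in 500, thin 2 → 6,750 kept
draws) follow standard practice for this model class. Convergence is
monitored with the classic Gelman–Rubin statistic
`sqrt(((n-1)/n·W + B/n)/W)` on the grand mean, the variances and every
cell probability, with R̂ < 1.1 as the acceptance bar, plus an
autocorrelation-based effective sample size. A caution from the test
fixtures: with very few months (≤ 4) the month-variance conditional is
heavy-tailed and `mu` trades off slowly against the month effects, so R̂
on `mu` can sit above 1.1 at default lengths; at the study's 11 months and
110 turbines the default schedule converges comfortably (max R̂ ≈ 1.02).

## 4. Summaries: the reference average and probability of direction

The reference is the facility-wide probability of entry,
entries/approaches. Its published credible interval shows it was treated
as carrying posterior uncertainty, so the package computes it *per draw*
as the approach-count-weighted mean of the cell probabilities — the model
analogue of the empirical ratio — and reports the empirical scalar
alongside. (The count-weighted mean, not an unweighted one, is what
matches the empirical definition; for a single cell of data the two
coincide and the posterior matches the conjugate Beta oracle.)

Group summaries are unweighted means over observed cells: a turbine's mean
is the mean of its cell probabilities over the months in which it was
observed, a month's over the turbines observed in it ("mean", not
"weighted mean", is the stated operation; `weighted_groups = TRUE` is
available). The probability of direction of a quantity is the share of
draws in which the reference average strictly exceeds it; exact ties count
as not-greater, so in the fully degenerate case (all cells identical) pd
is 0 for everything — a documented artefact of the strict inequality.
Classification uses pd > 0.95 (safer) / pd < 0.05 (riskier) by default,
with 0.90/0.10 available for map colouring. Credible intervals are
equal-tailed 2.5/97.5 percentiles of the pooled post-burn-in draws.

No multiplicity adjustment is applied across the ~1,200 cells: the
hierarchical shrinkage is the only control, as in the source analysis.
The null-calibration property test (all true effect SDs 0) verifies that
fewer than 10% of cells are flagged under these thresholds.

## 5. What the synthetic generator emulates — and what it does not

The generator reproduces the *study conditions*: 110 turbines (44 with
101-m rotors, 66 with 77-m rotors, all hubs at 80 m) on a jittered grid,
11 months from May 2018 with monitoring installed in four waves
(40/30/20/10% of turbines starting in months 1, 3, 9 and 11), 10,000
approaches allocated across observed cells by a multinomial over
log-normal intensities (eagles do not visit all turbines equally often;
the log-normal is an assumption, configurable via `intensity_sdlog`), and
8.5% of tracks approaching two turbines. Ground-truth cell probabilities
come from the model's own generative structure with defaults
`mu = logit(0.295)` (the study's overall rate), `sigma_alpha = 0.25`,
`sigma_beta = 0.10` (months varied little), `sigma_gamma = 0.5`.

Entry/no-entry is decided *first*, from `p_true`, and each 1-Hz track is
then constructed to match its label: a straight-ish chord of the 360-m
circle around the target turbine flown at 8–20 m/s with a gentle
sinusoidal cross-track wiggle. Entering passes cut through the RSZ at
blade altitude with enough interior chord that at least one 1-Hz sample is
guaranteed inside; non-entering passes keep a > 5 m clearance outside the
RSZ at all altitudes while still dipping into the 150-m cylinder. Building
paths to match labels (rather than letting entries emerge from path
dynamics) makes the generator's per-cell counts an *exact* oracle for the
geometry pipeline, which the round-trip tests require. The 600-m grid
spacing guarantees a track confined within 360 m of its target can never
stray into a neighbouring turbine's approach cylinder, so the oracle holds
track by track. Two-turbine tracks bridge grid-adjacent turbines with a
heading constrained toward the partner, which keeps the bridge at least
~250 m from either rotor axis.

The generator is geometrically plausible, not behaviourally realistic: no
thermalling, wind response, terrain (flat ground throughout) or diurnal
structure, and confidences are simply drawn in [0.90, 1). Passing tests
therefore demonstrate that the pipeline's geometry, bookkeeping and
inference are correct under known ground truth — not that the model
captures real eagle behaviour.

## 6. Numerical choices and degenerate inputs

* Binomial log-likelihood uses a guarded `log1p(exp(x))` (linear beyond
  x = 35) to avoid overflow.
* Variance draws are clamped to `[1e-10, upper]`; constant chains make the
  Gelman–Rubin denominator zero, which returns 1 with a warning rather
  than NaN.
* All-0 or all-1 responses fit but warn that the posterior sits at the
  prior boundary.
* Altitudes in `[-10, 0)` m are clipped to 0 with a warning (sensor
  noise); below −10 m is an error. Tracks with fewer than two points are
  dropped and counted.
* Registered blade-tip heights routinely differ from
  hub height + rotor radius by up to a metre (tip heights come from
  obstruction databases), so the consistency check warns at 1.5 m, not at
  centimetre level.
* A turbine-month with zero approaches is excluded from the observed-cell
  set and from all summaries; a group with no observed cells is dropped
  with a warning.

## 7. Scale of the shipped test problems

The test suite exercises two fixtures chosen as representative problem
sizes: a small study (12 turbines × 4 months, 400 approaches) for unit
tests, and the full study-scale conditions (110 × 11, 10,000 approaches,
default MCMC schedule) for the end-to-end round-trip, recovery, coverage
and null-calibration properties. The full fixture simulates in ~20 s and
fits in ~10 s, so the complete suite runs in about two minutes.

## 8. Known limitations

* The curtailment trajectory predictor is linear; the deployed system's
  predictor is unknown, so simulated trigger *times* (not the geometric
  entry outcomes) are approximations.
* Whether the real curtailment cylinders are ground-clipped is not
  documented; the package clips them, which only matters for hubs below
  half the cylinder height.
* The RSZ radius is taken as the physical rotor radius plus a configurable
  buffer defaulting to 0; the deployed system's buffer distance is not
  published.
* One season of data cannot separate month effects from year-specific
  weather; the month effect is a calendar-month effect of that study year.
* Covariates (weather, topography), temporal autocorrelation within
  tracks, and observation-level random effects are out of scope.
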