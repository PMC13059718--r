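---
title: "Methods: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the modelling assumptions behind `ferrodyn`, the
rationale for every default value, and the numerical choices made in the
implementation. Quoted numbers are recomputed by
`scripts/acceptance.R` and by the test suite; nothing here is asserted
without a corresponding computation in the package.

## 1. The model

Two state variables: the population size `n`, measured as a fraction of
full confluence, and the average lipid ROS per live cell `r` (arbitrary
reporter-calibrated units).

$$\frac{dn}{dt} = \alpha\, n \left(1 - \frac{n}{K}\right) - \beta\, n\, \sigma(r),
\qquad
\frac{dr}{dt} = a\, \alpha \left(1 - \frac{n}{K}\right) - b\,r + c\,r$$

with the Hill death switch

$$\sigma(r) = \frac{r^h}{r_0^h + r^h}.$$

The structural assumptions are:

- **Logistic growth.** Without death, `n` grows logistically toward the
  carrying capacity `K`.
- **Division-coupled ROS production.** New lipid ROS is produced in
  proportion to the per-capita division rate `alpha (1 - n/K)`, with `a`
  units of ROS per division. This is the load-bearing coupling: crowded,
  slowly dividing populations generate little lipid ROS, which makes
  density protective.
- **Linear clearance and autocatalysis.** ROS is cleared at rate `b` per
  molecule; Fenton-type autocatalysis regenerates it at rate `c`. The
  model requires `b > c` so the net clearance `b - c` is positive and `r`
  stays bounded. Only the difference `b - c` enters the dynamics.
- **Threshold death.** The per-capita death rate is `beta` gated by the
  sigmoidal switch `sigma`, which is 0 at `r = 0`, 1/2 at the threshold
  `r0`, and saturates at 1. A hard-threshold variant
  (`switch_form = "step"`) is kept for comparison with the idealised
  threshold picture; all analysis defaults to the smooth Hill form.
- **Cumulative dead count.** A third quantity
  `D(t) = \int_0^t beta * n * sigma(r) ds` is integrated alongside the
  state. It models a dead-cell dye that marks each cell once, so the count
  accrues and never decreases.

On the `n = 0` axis the ROS equation decouples and `r` relaxes to the
extinction-line level `a*alpha/(b - c)`; with the canonical values below
this is 2.5.

## 2. Canonical parameters and their rationale

```{r}
model_params()
#> alpha     K  beta     a     b     c    r0     h
#> 0.050 1.000 0.045 0.500 0.030 0.020 1.200 4.000
```

The defaults are a package calibration, chosen once, against the
qualitative phenotypes the model is meant to reproduce, not against any
numerical dataset:

- `alpha = 0.05 /h`: a doubling time of roughly 14 h at low density,
  typical of fast-growing cell lines.
- `K = 1`: confluence is already a fraction, so the carrying capacity is 1
  by construction.
- `beta = 0.045 /h`: maximal death slightly slower than maximal growth, so
  death above threshold dominates growth only where the switch is
  substantially engaged.
- `a = 0.5`, `b = 0.03 /h`, `c = 0.02 /h`: net clearance
  `b - c = 0.01 /h` gives ROS dynamics slower than growth (a ~100 h
  relaxation scale) and an extinction-line ROS level of
  `a*alpha/(b-c) = 2.5`.
- `r0 = 1.2`, `h = 4`: the threshold sits between the quasi-steady ROS
  level of a confluent population (low) and the extinction-line level 2.5,
  with a switch steep enough to behave like a threshold but smooth enough
  for stable integration and fitting.

This set was required to satisfy, simultaneously: (i) bistability with a
resistant state at `(K, 0)` and a sensitive state at low `n`/high `r`
(computed: `(0.206, 1.985)`); (ii) untreated populations grow to
confluence from all three seeding densities; (iii) with the death
threshold lowered to 40% of control, populations seeded at low and medium
density die while high density survives; (iv) raising ROS production
(galactose-like) enlarges the sensitive basin. These four constraints are
verified in `tests/testthat/test-acceptance.R` and recomputed by
`scripts/acceptance.R`.

### Seeding densities and treatment multipliers

- `seeding_fractions()` maps low/medium/high seeding to initial confluence
  fractions `LD = 0.10`, `MD = 0.22`, `HD = 0.48`. Plated cell counts
  translate to area fractions only approximately; these are package
  calibrations placing LD/MD inside and HD outside the sensitive basin of
  the inhibitor-treated model.
- GPX4 inhibition is modelled as a threshold multiplier, default
  `r0 * 0.4`: with less GPX4 activity, less lipid ROS suffices to kill.
- A galactose medium switch (forced OXPHOS) is modelled as a production
  multiplier, default `a * 1.8`.
- Restricted growth space (same cells, half the area) is modelled as
  doubling the initial confluence fraction (`space_factor = 2`), capped
  just below `K`.
- Graded dosing per percent confluence uses
  `dose_to_r0_multiplier(d) = exp(-0.8 d)`. The decay constant is chosen
  so that the two standard transfer doses bracket the fate boundary: the
  high-density dose (0.79 ng/%) maps to a multiplier of 0.53, mild enough
  that a high-density population survives while a low-density one dies,
  and the low-density dose (1.8 ng/%) maps to 0.24, strong enough that
  death is the only long-term fate.

The directions of all multipliers are biologically grounded; their
magnitudes are package defaults.

## 3. Observation model

The measured channels are linked to the state by
`observation_model(ros_scale = 0.5, ros_baseline = 0.1)`:

- `confluence_pct = 100 * n`;
- `lipid_ros_ratio = ros_baseline + ros_scale * r` — the ratiometric
  reporter is assumed affine in per-cell ROS, with `ros_baseline` the
  oxidized/reduced ratio of an unstressed cell;
- `dead_per_confluence = D(t) / n(t)` — cumulative dead counts normalised
  to confluence.

Because the observation map is affine, `a` and `ros_scale` are confounded
(only their product is identified); `fit_spec()` refuses to free both.

## 4. Synthetic noise model

Per replicate, `generate_dataset()` perturbs the noiseless observables
with:

- multiplicative log-normal noise on confluence (`sigma = 0.05`), capped
  at 100%;
- additive zero-truncated Gaussian noise on the reporter ratio
  (`sigma = 0.05`);
- Poisson dead-cell counts, `counts ~ Pois(500 * D(t))` (500 expected
  counts per unit cumulative dead area), divided back by the noisy
  confluence — so the dead observable inherits both counting noise and
  confluence noise, as it does in practice.

Sampling is every 2 h for 72 h (37 time points), 3 replicates, matching
the standard live-cell-imaging cadence. All randomness derives from the
scenario seed; setting all noise SDs to zero returns exactly the
noiseless observables.

## 5. Numerical methods

- **Integration** (`simulate_model`): `deSolve::ode` with `lsoda`,
  `rtol = 1e-8`, `atol = 1e-10`. The cumulative dead count is integrated
  as a third state. Tiny negative excursions are clipped at zero; a clip
  larger than 1e-6 raises a warning. Agreement with the closed-form
  logistic and exponential-decay limits is ~2e-8 relative (recomputed in
  the acceptance run, tolerance 1e-6).
- **Fixed points** (`find_fixed_points`): damped Newton iteration with the
  analytic Jacobian from a 20x20 grid of starts plus the axes and the
  closed-form boundary candidates; converged roots deduplicated at 1e-5
  and accepted only if `|rhs| < 1e-8`. Classification uses the eigenvalue
  real parts with a +/-1e-9 zero band; eigenvalues inside the band are
  reported as `unclassified` rather than guessed.
- **Basins** (`compute_basins`): the full grid (default 60x60 over
  `r` in `[0, 4 r0]`, `n` in `[1e-3, 1.1 K]`) is integrated
  simultaneously with a fixed-step batched RK4 (`dt = 0.25` h, far below
  the fastest model timescale of ~10 h; horizon 2000 h). Final states are
  matched to attractors within tolerance 0.02 in scaled
  `(r/r_max, n/K)` coordinates; unmatched nodes are labelled unresolved,
  never silently assigned. The adaptive-solver path (`attractor_of`) is
  the oracle the grid labels are tested against (100% agreement at 100
  random states in the acceptance run). These grid defaults resolve both
  canonical attractors in well under a minute on one CPU.
- **Fitting** (`fit_timecourses`): bounded Levenberg-Marquardt
  (`minpack.lm::nls.lm`, `maxiter = 200`) on a log-scale internal
  parameterisation (all parameters except `ros_baseline`, which may be
  zero). `multistart` (default 16) jittered starts centred on the
  canonical defaults, the first start unjittered; the best final RSS wins,
  and the spread of estimates among near-optimal starts is reported as
  `dispersion`. Initial states per condition are inferred from the first
  observed time point (confluence/100 and the inverse observation map)
  unless supplied.
- **Weights**: per-observable inverse pooled replicate variance. At each
  (condition, time) the across-replicate variance is computed, pooled over
  time, and floored at the 10th percentile of the positive per-time
  variances so exact replicates cannot produce infinite weights; with a
  single replicate the observable's overall variance serves as the scale.
  This puts confluence (units of percent) and the reporter ratio (units
  of ~1) on comparable footing.

Recovery performance with these choices, recomputed by the acceptance
run: noiseless generate-and-refit recovers `alpha`, `K`, `beta`, `r0` to
better than 1e-6 relative; with the default noise model the worst median
relative error over 20 seeds is about 8%; a joint control/inhibitor fit
with a condition-specific threshold recovers the direction of the
contrast in 20/20 seeds with a median estimated threshold ratio of 0.40
(truth 0.40).

## 6. Image rendering and dead-cell exclusion

`render_frame()` paints ellipse-shaped cells (semi-axes 6-10 px on a
512x512 frame) with at most 30% overlap per cell until the live and dead
area fractions hit their targets (the last cell is trimmed to land
exactly); requests beyond the 0.8 packing limit error. Live cells carry
reduced intensity 1 and oxidized intensity `ros_baseline + ros_scale * r`;
dead cells carry dead-marker signal and an elevated oxidized halo, so
failing to exclude them biases the live ratio upward. All channels get 2%
multiplicative log-normal noise. The ground-truth label image rides along
as an attribute.

Measurement (`dead_mask`, `live_cell_measurement`) thresholds the
dead-marker channel (Otsu by default, manual override available), dilates
by a discrete disk (default radius 3 px — pixels with
`dx^2 + dy^2 <= radius^2`), and removes the dilated mask from the
coverage mask. Ratios are sum-then-divide (channel sums within the live
mask), which is robust to zero-intensity pixels; an empty live mask flags
the ratios as undefined rather than returning infinities. In the
acceptance run the round trip recovers live confluence within 0.9
percentage points absolute and the live ratio within 0.01% relative.

## 7. Limitations

- The model is a two-variable mean-field caricature: no spatial structure,
  no single-cell heterogeneity, no explicit GPX4/glutathione biochemistry.
  Treatments act as constant parameter multipliers from time zero.
- The affine observation map and the noise magnitudes are conventions, not
  measurements; `a`/`ros_scale` confounding is inherent to that choice.
- Basin labels are defined relative to a finite horizon and tolerance;
  states extremely close to the separatrix can legitimately remain
  unresolved (about 0.1% of the default grid).
- The renderer produces schematic frames for validating the measurement
  pipeline, not realistic microscopy (no focus drift, shading, or
  segmentation ambiguity).
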