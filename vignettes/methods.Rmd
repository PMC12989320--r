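---
title: "Models and numerical methods in imrtdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in imrtdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`imrtdose` models the IMRT planning loop — anatomy and beam geometry in,
predicted dose out, feasibility verified by fluence re-optimization — on
seeded synthetic phantoms. This vignette explains the models, the defaults
and why they were chosen, the numerical choices, and what the package's
tests do and do not demonstrate.

## Coordinate and grid conventions

All volumes live on one canonical grid per case: isotropic spacing
(2 mm by default), voxel indices 0-based in world formulas, voxel center at
`origin + index * spacing`. Masks are resampled with nearest-neighbor
interpolation (they must stay binary); doses and channels trilinearly.
Resampling preserves the outer voxel-face extent within one voxel and clamps
boundary samples to the voxel-center hull, so constants are preserved
exactly. Volumes are stored as NIfTI with the spacing and origin in the
affine; values are written as float64 so write/read round trips are
bit-exact. Plans are one JSON document per case (beam angles, isocenter,
SAD, prescriptions, OAR weights, beam-model tables); DICOM-RT is out of
scope.

## Beam geometry and the dose engine

A beam is (gantry angle, isocenter, SAD); beams are coplanar (the couch
angle exists in the plan schema as a hook but the engine rejects nonzero
values). The source sits at `iso + SAD (cos g, sin g, 0)`; beam's-eye-view
(BEV) axes are `u = (-sin g, cos g, 0)` and `v = z`. Trigonometry uses
`sinpi`/`cospi`, which are exact at multiples of 90 degrees — this is what
makes the engine's 90-degree rotational equivariance hold to float
precision, a property the tests rely on.

The engine is a fluence-convolution broad-beam (FCBB) model:

```
dose(x) = F(u(x), v(x)) * PDD(d_rad(x)) * (SAD / t(x))^2
```

- `F` is the fluence after 2D convolution with an isotropic Gaussian
  penumbra kernel, sigma 3 mm at the isocenter plane, truncated at 4 sigma
  and discretely normalized. No published kernel accompanies the FCBB
  formulation we target, so a single Gaussian is the minimal faithful
  penumbra model; sigma is configurable.
- `PDD` is a synthetic 6 MV-like percentage-depth-dose: linear build-up from
  the surface to `d_max = 15` mm, then `exp(-0.005 (d - d_max))`, tabulated
  at 1 mm and linearly interpolated. It is a documented stand-in for machine
  commissioning data and fully configurable (the table travels inside the
  plan JSON).
- `d_rad` is the radiological depth: the line integral of density from the
  source, computed by midpoint-rule ray marching with nearest-neighbor
  density lookup. Exact per-voxel traversal (Siddon-style) would be the
  textbook choice, but a per-ray voxel walk is far too slow in interpreted
  code at 10^5 voxels; midpoint marching vectorizes over all voxels at once.
  The default step equals the grid spacing (2 mm), giving depth errors well
  below 1 mm against dense quadrature on binary phantoms — about 0.5% of
  dose through the PDD slope, inside every tolerance used downstream. The
  standalone `radiological_depth()` defaults to a finer 0.5 mm step.
- The inverse-square factor is implemented and ON by default; the broad-beam
  formulation we follow does not state it, so it is a flag
  (`beam_model(inverse_square = )`). Divergence is a full perspective
  projection with SAD 1000 mm, the standard linac value.
- Dose is computed only inside the body and is 0 outside, matching how beam
  traces are rendered clinically.

Apertures are *conformal*: every target voxel is projected through the
source onto the isocenter plane, rasterized (2 mm fluence pixels by
default), and dilated by a 5 mm isotropic disk margin. For plans with a
simultaneous integrated boost the aperture conforms to the union of all
target volumes. Disjoint target lobes produce disjoint aperture components.

For optimization the engine is assembled once per case into a sparse
influence matrix per beam (bilinear BEV interpolation weights times
depth-dose and inverse-square factors) plus symmetric convolution factors,
giving the exact adjoint `A^T` — verified in the tests by the inner-product
identity to 1e-6 relative. Optimization beamlets default to 5 mm (coarser
than the 2 mm beam-trace pixels) to bound the problem size.

## The three input channels

- *Prescription*: per-voxel prescription of the highest-dose covering
  target, divided by the maximum prescription `dp_max`. Scale-free by
  construction (invariant under uniform prescription scaling).
- *Avoidance*: OAR voxels 1, body 0.1, outside 0; overlapping OARs take the
  maximum weight. Target/OAR overlaps are resolved by
  `overlap_policy`: the default `target_priority` removes overlap voxels
  from the avoidance set (they keep the 0.1 body value, since the PTV is
  part of the body and the stated rule gives non-OAR body voxels 0.1 —
  assigning 0 instead is available via `body_weight`), prioritizing
  coverage; `oar_priority` relabels them as OAR, the patient-specific
  adjustment that trades target coverage for sparing when a tumor abuts a
  critical structure. Weights are per-OAR configurable and should be kept
  consistent between training and inference.
- *Beam trace*: per beam, the unit-fluence conformal aperture is convolved
  and pushed through the engine; each per-beam dose is divided by its own
  maximum, then the sum is divided by the number of beams. The per-beam
  max-normalization is an interpretation: summing raw unit-fluence doses and
  dividing by N does not guarantee a map that peaks near 1, whereas
  max-normalized beams overlapping at the target do. It also makes the
  channel exactly invariant under beam duplication, a property the tests
  pin down.

## Synthetic phantoms and label doses

The generator draws, per seed: a convex ellipsoidal body (semi-axes 80–95%
of the half-extent), a spherical target (8–18 mm radius on clinical-size
grids, shrunk proportionally on smaller ones so it always fits, center
sampled in the inner ellipsoid), a simultaneous-integrated-boost case with
probability 0.25 (boost nested at 40–60% of the primary radius, primary
prescription 75–90% of the boost), one to three OARs (spheres or capped
cylinders, overlapping the target at rate 0.2, placement redrawn
deterministically until nonempty inside the body), 7–25 coplanar beams
(equispaced from 0 degrees, or sorted-uniform random), and prescriptions
spanning 4–79.2 Gy. Everything is a pure function of the seed
(`sample.kind` fixed by `set.seed` defaults of R >= 3.6). Density is binary
(1 inside the body): the pipeline deliberately takes no CT/density channel,
so heterogeneity corrections are out of scope; a density grid hook exists in
the engine signature.

Label doses are produced by planning FMO through the same engine: one-sided
quadratic penalties (underdose below / overdose above the per-voxel
prescription inside targets; quadratic-above-zero on OAR voxels outside
targets; quadratic above `dp_max` on the body for hot-spot control), each
term normalized by its structure's voxel count and by `dp_max^2` so the
objective — and therefore the optimizer — is invariant under joint scaling
of dose and prescriptions. Default weights (100 under / 30 over / 5 OAR /
10 body) were set so that unconflicted phantoms reach target D95% within
5% of prescription, which the tests check on seeded cases. The solver is
spectral projected gradient with Barzilai–Borwein steps and monotone
backtracking, deterministic from zero-fluence initialization, with an exact
line search along the first projected direction (dose is linear in the step
there); stopping at relative objective change < 1e-6 or `max_iter`.

Cohorts derive per-case seeds as `(seed + 99991 i) mod 2^31-1` and split
floor(n·f) cases to train and validation (train gets at least one case),
remainder to test.

## Reference-guided optimization (feasibility probe)

Given a reference dose (typically a prediction), the optimizer minimizes
underdose below the reference in targets, overdose above it everywhere, and
a small symmetric misfit everywhere in the body, over non-negative
beamlets. The symmetric term (weight 1 against 100/10 for the one-sided
terms) is what makes the objective zero *iff* the dose equals the reference
on the body, so references generated by feasible fluences are exactly
recoverable — the pipeline's headline self-consistency property, checked as
gamma(3%/2 mm, 10% LDT) >= 99% on ten seeded 64-cube phantoms. The
threshold-driven clinical engine this stands in for is not reproduced; any
sound reference-guided FMO serves the feasibility-probe role, and the
structure weighting beyond "use the prediction as reference" is this
package's choice, surfaced in `objective_config()`.

## The dose-regression network

No deep-learning framework is assumed: the predictor is a compact voxel-wise
regression network written in plain matrix algebra. A *fixed* encoder turns
the three channels into per-voxel features — each channel at native
resolution, Gaussian-smoothed at sigmas 2/4/8/16 mm (separable, zero-padded)
for isotropic context, plus a central-difference gradient magnitude for
edge/penumbra structure (18 features). A trainable head (two hidden ReLU
layers of width 64) maps features to dose normalized by `dp_max`; negative
outputs are clipped at inference and out-of-body voxels are zero. Training
minimizes the mean Huber loss (delta = 1, the scale at which normalized-dose
residuals switch from quadratic to linear treatment) with Adam on voxel
minibatches (default 8192), cosine learning-rate decay, and checkpoint
selection on validation loss; it is deterministic given the seed. The label
normalization by `dp_max` mirrors the prescription channel; predicting
normalized rather than absolute dose is this package's convention, chosen so
one model serves prescriptions spanning 4–79.2 Gy.

What this architecture shares with encoder–decoder CNNs used for clinical
dose prediction is the receptive-field structure (multi-scale context in,
voxel-wise dose out) and the loss; what it gives up is learned convolution
kernels and long-range asymmetric context. On phantoms whose dose is largely
determined by the three channels this is sufficient (the features separate
voxels essentially uniquely — a random-forest oracle fits the 2-case pool to
5e-5); on real patients with heterogeneous anatomy it would underfit
modulation that CNN features could capture. Passing tests here therefore
demonstrate the pipeline's internal consistency and the learnability of the
channel-to-dose mapping, not clinical-grade prediction accuracy.

## Evaluation metrics

- Gamma: per-voxel
  `min_r sqrt(((E(x+r) - R(x)) / (3% · max R))² + (|r| / 2 mm)²)` over a
  displacement lattice of step `dta/10` within `3 · dta`, evaluated dose
  trilinearly interpolated, reference-maximum (global) normalization, 10%
  low-dose threshold applied on the reference. Because any displacement
  beyond `dta` already has gamma > 1, the lattice within `dta` fully
  determines the passing rate; the wider radius only refines gamma *values*
  above 1 (capped at 3). The implementation processes offsets sorted by
  radius with an active-set early exit and matches exhaustive brute-force
  search and an independently written Python/numpy implementation to within
  0.1 percentage points on random fields. Which dose acts as reference is an
  assumption surfaced in `report_cohort()`: the second-named dose of each
  comparison.
- `Dx%`: descending sort, value at rank `ceiling(x/100 · n)` — exact on
  integer oracles; DVH curves are consistent with it within one bin.
- MAPE: `100/n Σ |Dx%(pred) − Dx%(ref)| / Dp`, per-case prescribed dose in
  the denominator.
- Reports emit D2%, D5%, D50%, D95% per ROI, covering both near-max and
  coverage conventions.

## Problem sizes used by the tests

The test suite runs everything end to end at reduced sizes chosen as this
package's desk-scale defaults: unit tests on 8–32 cube grids; the recovery
property on ten 64-cube phantoms with 9 beams and 500 optimizer iterations;
the end-to-end study on 128 phantoms at 32 cubes (100 train / 8 validation /
20 test, labels from 60-iteration planning FMO, 8 training epochs), which
reports the mean gamma passing rate between predictions and
prediction-guided optimized doses on the held-out cases. The 64-cube default
grid (12.8 cm cube at 2 mm) is the generator's production setting; larger
clinical grids are a documented parameter, not a tested configuration.

## Known limitations

- Binary density only; no CT channel, no heterogeneity corrections — by
  design of the input encoding.
- Coplanar beams; arc delivery and couch rotations are not modeled.
- No MLC sequencing or machine-constraint final dose: "feasible" means
  non-negative fluence through the FCBB engine.
- The phantom generator emulates plan-parameter ranges (beam counts,
  prescriptions, SIB, overlap geometry), not anatomical realism; no claim is
  made that its shape distribution matches any clinical cohort.
- Gamma search is lattice-based; sub-lattice minima below `dta/10`
  resolution are not found (both the oracle and the implementation share
  this convention).
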