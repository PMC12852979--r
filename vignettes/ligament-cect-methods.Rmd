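---
title: "Models and methods behind ligamentCECT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ligamentCECT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ligamentCECT couples two measurements of the same ligament sample: a
tensile viscoelastic characterization before and after a controlled 16%
overstrain, and contrast-enhanced micro-CT of agent diffusion into the
tissue. This vignette records the models, the conventions chosen where the
field has no single standard, the numerical decisions, and what the
synthetic validation does and does not establish.

## Mechanical model

Stress is engineering stress, force over the elliptical cross-section
`pi * width * thickness / 4` (mm², so N/mm² = MPa). Strain is referenced to
the *zero-load length*, defined operationally — as on tensile testing
devices — as the clamp-to-clamp length at which stress first reaches a
0.05 MPa preload during slow loading. `findZeroLoadLength()` locates that
crossing on the loading limb and refines it with a local quadratic
regression of stress on length (restricted to stresses below four times
the preload); this suppresses the single-sample noise sensitivity of a raw
threshold crossing while remaining exact for a quadratic toe. Inputs with
fewer than 12 samples fall back to linear interpolation between the
bracketing samples.

**Young's modulus** is the least-squares slope of stress versus strain over
the 4–8% strain window of the 8%-strain ramp. The window excludes the toe
region (modelled as quadratic over the first 2% strain); the lower edge at
4% is a package convention, configurable via `modulusWindow`. Fits with
R² < 0.5 are flagged `lowQuality`.

**Stress relaxation** during the 600 s hold is fitted by nonlinear least
squares (Levenberg–Marquardt, `minpack.lm`) to

σ(t) = σ_eq + A₁ e^(−t/θ₁) + A₂ e^(−t/θ₂),  t = 0 at the ramp end.

Amplitudes are bounded below by zero; time constants by small positive
floors. Initialization is data-driven (tail mean for σ_eq, the initial
drop split 60/40 between the two terms, θ = (2, 100) s) with a fallback
multi-start grid θ₁ ∈ {1, 3, 10} s × θ₂ ∈ {60, 120, 300} s; the best
converged sum of squares wins and the θ₁ < θ₂ ordering is enforced by a
post-fit swap. Convergence tolerances are 1e-12 (ftol/ptol), 300
iterations per start. Degenerate inputs are handled explicitly: a constant
hold returns amplitudes of zero with time constants at initializer
defaults and a `degenerate` flag; a fitted A₂ below 1e-4 of the stress
scale sets `theta2Unidentifiable`, since the slow time constant is then
unconstrained by the data.

**Phase shift.** Strain and stress over each sinusoidal segment are fitted
by linear least squares to `a + b sin(2πft) + c cos(2πft)` after
discarding the first cycle as transient; γ is the lag of stress behind
strain, `atan2`-derived and wrapped to (−90°, 90°). The linear basis makes
the estimate invariant to time origin and additive offsets, and exact for
noiseless sinusoids at any sampling phase.

**Yield** on the overstrain ramp is declared where the tangent modulus — a
moving least-squares slope over a 1% strain window — first falls below 70%
of the pre-damage linear modulus. The 70% threshold and window are
conventions (`yieldThreshold`, `yieldWindow`), chosen to detect a yield
point on smooth curves without physical failure; the crossing is then
refined by fitting a continuous two-line hinge
`σ = a + b·ε + c·max(0, ε − brk)` in a ±3-window neighbourhood and
reporting the optimal breakpoint, which recovers a bilinear kink exactly.
A ramp whose tangent never drops below threshold returns a no-yield flag
rather than a value.

**Damage parameters** compare the post-overstrain repeat of the 8% test
with its pre-damage counterpart: D_σ = 1 − σ_peak,post/σ_peak,pre (peaks
taken as the fitted σ(0) of each relaxation fit, which is far more noise
robust than a raw maximum), D_ε = 1 − σ_eq,post/σ_eq,pre, and
λ_ε = (L0_post − L0_pre)/L0_pre from the preload-determined zero-load
lengths. These forms are package conventions chosen for their
interpretability (normalized stress reductions and residual strain); all
three enter the report and can be redefined upstream of
`damageParameters()` if a different convention is preferred.

## Uptake model and CT processing

Bulk partition at timepoint t is
`(mean HU of tissue at t − mean HU of native tissue) / bath HU`, with the
bath referenced to water (0 HU after calibration) so the bath itself has
partition 1. Subtracting the native-scan tissue mean isolates
contrast-induced attenuation; it is the physically consistent choice when
a native scan exists and can be disabled (`subtractNative = FALSE`).
Partitions may exceed 1 for charge-attracted agents. The nominal immersion
timepoints index the scans; no co-registration between timepoints is
attempted because only bulk means are used.

`fitUptake()` fits `Partition(t) = Pmax [1 − exp(−t/τ)]` by bounded
Levenberg–Marquardt. The initializer sets Pmax₀ to the last partition and
τ₀ to the earliest (interpolated) time the series reaches 63.2% of Pmax₀,
with a small fallback grid of τ starts. At the fitted τ the curve passes
through 63.2% of Pmax by construction of the model — this identity is used
as a self-check in the test suite. A two-parameter fit requires at least
three timepoints.

HU calibration maps the water-tube ROI mean to 0 and the air ROI mean to
−1000 voxelwise; a calibrated volume must keep its water ROI within
±15 HU (class validity). Tissue segmentation follows the standard recipe:
k-means with k = 2 on intensities over the whole volume (centres estimated
on a 200k-voxel subsample for large grids, then all voxels assigned to the
nearest centre — deterministic given the recorded seed), tissue = the
higher-mean cluster, then per-slice morphological closing and opening with
a radius-10 disk, boundary shrink by 10 pixels and removal of components
under 2000 pixels. "Smoothing by 10 pixels" is genuinely ambiguous as a
phrase; closing-then-opening with a radius-10 disk is this package's
reading, and radius, shrink and minimum area are all arguments so smaller
phantoms can use proportionate values. The water tube's footprint is
excluded before morphology.

Structural segmentation clusters each slice's tissue attenuations with
k = 3, renumbers labels by ascending cluster mean (making label order
invariant to initialization), and takes fascicles as tissue minus the top
cluster — a set difference on masks, since the downstream use is a
fascicle mask. With two well-separated tissue populations the optimal
three-cluster solution splits the majority (fascicle) population and
leaves the IFM as the top cluster, which is why the set-difference rule is
robust; the per-slice cluster means of the lower two clusters pool to the
fascicle mean. A slice with a single attenuation value is assigned
entirely to the top cluster (no structure below it); clustering that
degenerates on more than 10% of slices aborts with the slice list.
Slice-averaging in groups of ~10 (`averageSlices()`) exists for
visualization only; statistics always use raw voxels.

## Statistics

Paired control/damaged comparisons use the Wilcoxon signed-rank test with
zero differences dropped and average ranks for ties. For n ≤ 25 the
p-value is exact: the null distribution of the positive-rank sum is built
by dynamic programming over doubled ranks (integral even with mid-ranks),
which equals full enumeration of the 2^n sign assignments; the two-sided p
is `min(1, 2 min(P(W ≤ w), P(W ≥ w)))`. The exact route was chosen because
the paired design has n = 11, where normal approximations are at their
worst; beyond n = 25 a tie-corrected normal approximation takes over.
Spearman correlations use average ranks, an exact permutation p (all n!
permutations) for n ≤ 8 and the t approximation above. The correlation
screen crosses every biomechanical parameter with {Pmax, τ} per agent,
pooling control and damaged groups except for damage-specific parameters
(D_σ, D_ε, λ_ε, yield strain/stress), which exist only in the damaged
group. Significance is declared at p < 0.05 per test with no multiplicity
correction by default, mirroring the small-cohort reporting convention;
`adjust = "BH"` enables Benjamini–Hochberg.

## What the synthetic data emulate — and what they do not

The generators' defaults are the study conditions the package validates
against: healthy-group means E = 70.10 MPa, (A₁, θ₁, A₂, θ₂) =
(0.88 MPa, 2.56 s, 0.49 MPa, 137.18 s), peak/equilibrium ratio 1.80, phase
shifts (4.13, 3.27, 3.08, 2.95)° at (0.1, 0.5, 1, 2) Hz, yield strain
0.12; a damage effect scaling stress by 22.13/70.10 (a 68% modulus
reduction) with residual strain 0.04; uptake (Pmax, τ) = (0.81, 0.82 h)
for iodixanol and (2.49, 5.38 h) for the cationic nanoparticle, with
between-ligament lognormal spreads matching the reported standard
deviations; regional attenuations 603 HU (fascicles) and 795 HU (IFM)
with 22 HU reconstruction noise at 16.99 µm voxels; cohorts of 11
ligaments (6 ACL, 5 PCL), two paired subsamples each.

Generator design choices worth knowing:

- **Segment independence.** The Prony hold starts at σ_eq + A₁ + A₂
  regardless of the ramp's end stress; a toe+linear ramp with slope E and
  the tabulated relaxation parameters are not jointly consistent with a
  single stress curve, and since every analysis operates on its own
  protocol segment the generator favours exact per-segment truth over
  cross-segment continuity. The small ramp-end/hold-start discontinuity is
  deliberate.
- **Toe and preload consistency.** The ramp toe is quadratic over the
  first 2% strain with an offset chosen so that stress at zero strain
  equals the 0.05 MPa preload — making the generator's strain reference
  identical to the analyzer's operational zero-load length, pre and post
  damage. The post-damage curve, scaled by (1 − d), carries its own offset
  so the redetermined zero-load length lands exactly at
  L0(1 + residual strain).
- **Yield stress is derived.** The truth fixes the yield strain; the yield
  stress follows from the curve (slope E up to yield, 30% of E beyond).
  Specifying both independently would be inconsistent with any single
  pre-yield slope.
- **A single damage fraction.** Post-damage stress scales uniformly by
  (1 − d), so D_σ = D_ε = d in simulation. Real tissue shows D_σ ≠ D_ε
  (transient amplitudes degrade more than equilibrium stress); the
  single-d model cannot reproduce that split and the package makes no
  claim that it can — it is sufficient to validate the estimators.
- **Sinusoid dwell.** Cycle counts are not part of the stated protocol;
  the generator holds each frequency for at least 80 s (minimum 10
  cycles) so that, at 100 Hz sampling, every frequency contributes a
  comparable number of samples to the phase fit — phase precision scales
  as √(2/N), and short high-frequency segments would otherwise dominate
  the error budget. Holds are sampled at 20 Hz (resolving θ₁ ≈ 2.6 s),
  ramps at 500 Hz, re-zeroing at 200 Hz.
- **Phantom geometry.** Fascicle cross-sections are rejection-packed
  circles, diameters drawn from 50–500 µm clipped to ≥ 3 voxels, placed
  large-first with ≥ 1 voxel of IFM gap, giving ~65% fascicle area — the
  realistic regime in which fascicles are the majority phase. Uptake adds
  `(μ_region − baseline)(1 − e^(−t/τ))` per region with the IFM amplitude
  larger, and the implied bath attenuation is the area-weighted
  equilibrium gain divided by Pmax, so the phantom's bulk partition
  converges to Pmax by construction. X-ray physics (beam hardening,
  scatter, partial volume) and anisotropic or radially graded diffusion
  are *not* modelled; passing phantom tests therefore demonstrates the
  correctness of the estimators and the segmentation recipe, not
  robustness to scanner physics or to the biological variability that
  defeats clustering on some real samples.

## Problem sizes and numerical tolerances in the validation suite

Zero-noise forward-model/fitter consistency is required to 1e-3 relative
(achieved at machine precision for most parameters). Noisy recovery uses
2% of peak stress on mechanics (50 seeds, median ≤ 5% per parameter) and
0.03 partition noise for uptake (500 replicates per timepoint grid at the
nanoparticle truth, median ≤ 5%). Segmentation is validated at Dice ≥ 0.99
on noiseless phantoms and ≥ 0.90 at 22 HU noise over 10 seeds on
128×128×64–128³ grids; regional means are checked against a 3σ sampling
bound that propagates the water/air reference noise through the
calibration. The exact Wilcoxon implementation is checked against
brute-force enumeration for n ≤ 11 and against 10,000 simulated null
cohorts (empirical type-I error ≤ 0.055 at nominal 0.05). Cohort
simulations in tests use 2–11 ligaments; these sizes were chosen as the
smallest that exercise the statistical structure (pairing, pooling rules,
exact-test granularity at n = 11).

## Known limitations

- The uptake τ of a fast-diffusing agent is weakly identified by a grid
  with only one timepoint below τ (the iodixanol grid at τ ≈ 0.8 h):
  the Cramér–Rao bound already exceeds 5% relative error at 0.03 noise,
  so between-sample τ spread there reflects measurement design, not
  fitting deficiencies.
- Damage parameters inherit the identifiability of the relaxation fits;
  for nearly elastic samples (A₁ + A₂ ≈ 0) D_σ degenerates toward D_ε.
- The manual-ROI path reproduces region statistics but not the judgment
  of a human operator; it exists to make "manual" selections scriptable
  and auditable.
- Real CT volumes enter through `readVolumeSeries()`/`huCalibrate()`, but
  the pipeline orchestrator simulates its cohort; wiring a measured study
  table through the stage functions is the intended use for real data.
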