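# ligamentCECT

Structural and functional evaluation of ligament microdamage by combining
tensile viscoelastic testing with contrast-enhanced micro-CT (CECT), as a
tested, reproducible R pipeline. It is aimed at researchers quantifying
soft-tissue microdamage: sprain-level overloads alter a ligament's
viscoelastic response long before any visible tear, and contrast-agent
diffusion imaged by micro-CT offers a non-destructive window on the same
tissue.

## What it computes

**Biomechanics** (from time/displacement/force traces of a
preconditioning → re-zeroing → 8% ramp → 600 s relaxation → sinusoid
protocol, with a 16% overstrain for the damaged group):

- Young's modulus *E* — least-squares slope of stress vs strain over the
  4–8% window of the 8%-strain ramp (stress = force / elliptical area,
  strain referenced to the zero-load length at a 0.05 MPa preload);
- two-exponential (Prony) stress relaxation
  σ(t) = σ_eq + A₁·exp(−t/θ₁) + A₂·exp(−t/θ₂), θ₁ < θ₂, with the
  peak-to-equilibrium ratio (σ_eq + A₁ + A₂)/σ_eq;
- phase shift γ of stress behind strain under 0.5%-amplitude sinusoids at
  0.1, 0.5, 1 and 2 Hz (linear least squares on a sin/cos basis);
- yield point on the 16% overstrain ramp (tangent-modulus drop below 70%
  of the linear modulus, refined by a two-line hinge fit);
- damage parameters D_σ = 1 − σ_peak,post/σ_peak,pre,
  D_ε = 1 − σ_eq,post/σ_eq,pre, and residual strain λ_ε from the shift of
  the zero-load length.

**Quantitative CECT** (from micro-CT stacks at several immersion
timepoints): Hounsfield calibration from water/air reference ROIs, k-means
(k = 2) tissue segmentation with morphological clean-up, and the bulk
partition — tissue attenuation gain normalized to bath attenuation —
fitted to first-order uptake kinetics

    Partition(t) = Pmax · [1 − exp(−t/τ)]

where Pmax is the equilibrium partition and τ the diffusion time constant
(the time to reach 63.2% of Pmax).

**Structural CECT**: per-slice k-means (k = 3) on attenuation separates
nanoparticle-rich interfascicular matrix (IFM, the top cluster) from
fascicles (tissue minus the top cluster), with regional statistics,
manual-ROI support and Dice evaluation against ground truth.

**Statistics**: exact Wilcoxon signed-rank tests for paired control/damaged
comparisons and Spearman correlation screening of biomechanics against
uptake parameters (pooled across groups, damaged-only for damage-specific
parameters), at p < 0.05.

**Synthetic data**: generators for tensile traces, diffusion series, 3D CT
phantoms (packed fascicles in IFM, water-tube reference, known raw scale)
and full paired cohorts with ligament-level random effects — every
generator a pure function of (parameters, seed), with ground truth
returned, so each analysis stage can be validated against known truth.

## Worked example

```r
library(ligamentCECT)

## a damaged-group tensile test with realistic noise, then full analysis
g  <- genTensileTest(protocol = defaultProtocol("damaged"),
                     noiseSd = 0.06, seed = 7)
an <- analyzeTensileTest(g$test)
an$modulus
#> ModulusResult: E = 70.51 MPa over strain [0.04, 0.08] (R2 0.9940)
an$relaxation
#> RelaxationFit: sigmaEq 1.711 MPa, A1 0.849 (theta1 2.582 s), A2 0.4893 (theta2 139.5 s), ratioPE 1.782
an$sinusoid[["0.1"]]
#> SinusoidFit 0.1 Hz: gamma = 4.221 deg, amplitude 0.3497 MPa (R2 0.9430)
an$damage
#> DamageMetrics: Dsigma 0.680, Depsilon 0.683, lambdaEpsilon 0.0350, yield (0.1197, 7.904 MPa)

## nanoparticle uptake kinetics
ds <- genDiffusionSeries(2.49, 5.38, agentTimepoints("Ta2O5-cNP"),
                         noiseSd = 0.03, seed = 7)
fitUptake(ds)
#> PartitionFit: Pmax = 2.461, tau = 5.162 h (rmse 0.0311, n = 5)
```

The modulus, relaxation amplitudes/times and phase shift recover the
generator's healthy-group settings (E = 70.10 MPa, A₁ = 0.88 MPa,
θ₁ = 2.56 s, A₂ = 0.49 MPa, θ₂ = 137.18 s, γ₀.₁ = 4.13°) within the noise;
D_σ ≈ 0.68 reflects the simulated overstrain scaling the post-damage
stress by 1 − d = 22.13/70.10, and the uptake fit recovers
(Pmax, τ) = (2.49, 5.38 h) from five noisy timepoints.

A full paired cohort with report, comparisons and manifest:

```r
res <- runPipeline(runConfig(seed = 1, nLigaments = 11, outDir = "run1"))
subset(res$comparisons, parameter == "E")
#>   parameter  W       pValue  n exact
#> 1         E 66 0.0009765625 11  TRUE
```

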