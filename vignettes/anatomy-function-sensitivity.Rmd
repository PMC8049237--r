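---
title: "Methods: linking shape modes to simulated cardiac function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking shape modes to simulated cardiac function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cardiosense)
```

This vignette is the package's account of its science: the models it
implements, the assumptions behind them, the parameters that matter, and the
design decisions taken where the method left choices open. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The question and the pipeline

Cardiac anatomy is efficiently encoded by a statistical shape model (SSM):
rigidly align a cohort of meshes in point correspondence, apply PCA to the
node displacement fields, and describe every heart as the mean shape plus a
weighted sum of orthonormal deformation modes. The package asks how much of
the variation in *simulated* electromechanical function each shape mode
explains. The pipeline is: generate (or load) a cohort → align → fit the
SSM → synthesise extreme single-mode anatomies → simulate one beat per mesh
with identical physiological parameters → extract functional phenotypes →
discard phenotypes with little anatomical dependence → correlate modes with
phenotypes → emulate each phenotype with a Gaussian process and decompose
its variance with Sobol' indices → locally perturb the non-shape parameters
on the average mesh. Because all simulations share material properties,
initial conditions and boundary conditions, any variation in output is
attributable to anatomy alone.

## The synthetic anatomy generator

The generator stands in for an imaging cohort so the full analysis is
testable offline. The template (`build_template()`) is an idealised
biventricular mesh: each ventricle a thick-walled truncated-ellipsoid cup
(LV: endocardial semi-axes 28/28/48 mm, 10 mm wall; RV: 34/22/44 mm,
flattened, 5 mm wall), discretised on an apicobasal × circumferential ×
transmural grid whose hexahedral cells are split through their centroids
into 12 tetrahedra (apex wedges into 3, by a face-compatible prism split).
The two cups are disconnected bodies; activation therefore needs a stimulus
in each, which the default apical-endocardial stimulus rule provides. The
apicobasal grid is power-graded (exponent 0.75) and the azimuthal count
reduced to ~3/4 of the equatorial circumference over the grid spacing —
both choices keep apex elements well-shaped (minimum scaled Jacobian ≈ 0.1
at the default resolution) so that node jitter never inverts elements.

Five independent zero-mean Gaussian latent factors deform the template:
global scale, sphericity (long-axis rescaling), wall thickness,
whole-heart orientation, and a Gaussian-windowed inward bulge of the basal
septum (window restricted to apicobasal Z > 0.8). Scale and sphericity act
as a single anisotropic diagonal scaling about the heart centroid, and wall
thickness rescales the transmural offset with the endocardium fixed; each
factor therefore contributes a rank-one displacement field, which is what
makes the noiseless recovery tests exact (a two-factor cohort has exactly
rank-2 displacements, and fitted PCA modes span the generator fields to
machine precision). On top of the factors, iid per-node Gaussian jitter
(default 0.4 mm) stands in for the local anatomical variability the factors
do not model.

The factor gains (0.4, 1, 4.4, 36 degrees, 210 mm per unit latent value)
were calibrated once so that a unit latent value produces a comparable
whole-mesh RMS displacement for every factor, and the default latent SDs
(0.035, 0.028, 0.021, 0.014, 0.0105) then shape the aligned cohort's
variance spectrum like a small healthy-adult cohort: the first two modes
carry roughly half to three-quarters of the variance and ~90% is reached
around mode 9 (the orientation factor is absorbed by the rigid alignment,
as it should be). The price of desk scale is that absolute anatomical
amplitudes are smaller than a real CT cohort's volume spread — the jitter a
coarse mesh tolerates bounds the total variance budget. What the passing
tests show is therefore structural (recovery, orthogonality, ranking,
census), not that the generator reproduces clinical volumetric
distributions.

## The electromechanical surrogate

The reference workflow runs reaction-eikonal electrophysiology and 3D
finite-element mechanics on ~1 mm meshes — thousands of core-hours per
beat. The surrogate keeps the causal structure at 0D:

* **Activation** is the exact multi-source shortest-path time over the mesh
  edge graph, edge traversal time = length / conduction velocity (CV). An
  edge belongs to the fast endocardial conduction (FEC) layer iff both
  endpoints are endocardial with apicobasal Z ≤ 0.7 (boundary inclusive);
  FEC edges use `cv_fec` (default 2.0 mm/ms), the rest `cv_myo` (default
  0.5 mm/ms). In the local sensitivity battery the FEC velocity is treated
  as a fixed ratio to the myocardial CV — the standard scaled-conductivity
  view of an FEC layer — so perturbing `cv_myo` rescales every edge and
  activation times obey the eikonal 1/CV law exactly; `cv_fec` perturbs the
  ratio alone.
* **Mechanics** is a thick-wall sphere per ventricle: inner radius from the
  cavity volume, outer radius from the conserved wall volume, cavity
  pressure P = 2σ·ln(r_out/r_in) with σ the sum of an isotropic exponential
  passive stress a(e^{b(λ−1)}−1), λ = (V/V₀)^{1/3}, and a tanh active
  stress T·tanh²(s/τ_c)·tanh²((t_dur−s)/τ_r) (s = time since trigger +
  electromechanical delay), scaled by a linear length-dependence factor
  max(0, 1 + ld(λ−1)) — the Frank–Starling analogue that lets ejection
  terminate gracefully. The unloaded volume V₀ is set per anatomy so the
  passive law balances the prescribed end-diastolic pressure at the imaged
  volume: the 0D analogue of unloading to a stress-free reference, and the
  reason the model starts each beat in exact diastolic equilibrium (which
  in turn makes the isovolumic phases exactly volume-conserving).
* **Coupling** is one trigger per ventricle: the mean activation time of
  its nodes. A 0D model has no spatial stress field; this is the documented
  limitation of the surrogate's EP→mechanics pathway.
* **Circulation**: ideal-diode valves with forward resistances; ejection
  into a three-element Windkessel (characteristic resistance, peripheral
  resistance, compliance; systemic for the LV, pulmonary for the RV);
  filling from a constant preload. Atria and pericardium are not modelled;
  the preload pressure is their stand-in.

Default parameters (see `tanh_stress_params()` and `circulation_params()`
for units) are calibration choices that put the template LV ejection
fraction in a physiological band (50–65%) and the activation span inside
the normal QRS range; they live in config objects, never inline. Explicit
Euler with dt = 0.1 ms integrates the state; the suite checks that halving
dt moves every mechanical phenotype by < 0.5%, that a beat conserves volume
to < 1e−3 mL, and that |dV/dt| is exactly 0 with both valves closed (the
diode logic yields the four beat phases without a separate phase machine).
A beat whose state becomes non-finite or non-positive is *flagged*
incomplete and excluded downstream — cohorts never abort on a failed case,
and completion censuses report finished/total percentages per cohort.

## Phenotypes

Per ventricle: ESV (minimum volume), SV = EDV − ESV, EF, V1 (volume at peak
outflow), EF1 (first-phase ejection fraction, 100(EDV−V1)/EDV), ESP
(pressure at outflow-valve closure — closure rather than a flow-derived
end-systole definition, a documented choice), dP/dt extrema (centred
differences, one-sided at the ends), PeakP and its time, ET (outflow valve
open→close), ICT (activation trigger→valve opening), IRT (valve
closure→inflow reopening), and tsys, defined here as ICT + ET. Per case:
QRS (activation span over both ventricles), AT1090 (nearest-rank 10th→90th
percentile activation interval — the percentile convention is ours), and AT
(LV activation span). EDV is the mesh's cavity volume computed by the
divergence theorem on the closed endocardial surface, not a trace readout.

## Sensitivity analyses

* **Normalised-range filter**: (max − min)/|mean| over completed cases,
  discard strictly below 0.2. The absolute value keeps the statistic
  meaningful for negative-valued phenotypes (dPdtmin).
* **Correlation**: Pearson by default (Spearman available); the per-mode
  summary is the mean ± SD of |R| across phenotypes.
* **Emulation**: one GP per phenotype; anisotropic squared-exponential
  kernel with a nugget, outputs standardised before fitting,
  hyperparameters by L-BFGS-B on the log marginal likelihood. Training uses
  leave-one-out over the observed cases with all synthetic cases always in
  training; the returned emulator is refit on all data with the
  hyperparameters of the split with the smallest left-out squared error
  ("best-scoring" selection; mean-MSE selection would be the obvious
  alternative and the LOO table is returned so users can apply it).
* **Sobol'/Saltelli**: the design stacks A, B, AB_i and BA_i blocks —
  exactly (2D+2)·N evaluations. Base matrices come from a randomised Halton
  sequence (Cranley–Patterson rotation), a low-discrepancy choice that
  makes the Ishigami S1 errors at N = 4096 an order of magnitude smaller
  than plain Monte Carlo; beyond 20 inputs the base sample falls back to
  pseudo-random uniforms. S1 uses the Saltelli (2010) estimator averaged
  over both radial blocks, ST the Jansen estimator, and the
  "multifactorial" share is max(0, 1 − ΣS1). Input ranges default to the
  per-mode [min, max] of the observed cohort weights (raw mm scale;
  SD-standardised weights are available via `ssm_weights(units = "sd")` —
  whether to standardise is genuinely open, so both are exposed).
* **Local sensitivity**: SC = (x₀/y₀)(y₊−y₋)/(x₊−x₋) at ±10%; by
  construction SC = 1 for a linear response through the origin, 2 for a
  quadratic, 0 for a constant, and −(1/1.1 − 1/0.9)/0.2 ≈ −1.01 for the
  1/x response of activation times to conduction velocity. Parameters in
  scope: both CVs, the two peripheral resistances, both preloads, peak
  tension, and the passive scale a. Scenario deltas
  (100(y_mod − y_base)/y_base) cover discrete model swaps generically.

## Numerical and formatting choices

Vertex indices are 0-based on disk (VTK convention) and 1-based in memory
(R convention). The legacy ASCII VTK writer emits POINTS, CELLS,
CELL_TYPES, CELL_DATA (tags, fibre and sheet VECTORS) and POINT_DATA with
the four UVC lookup tables in the order rho, phi, Z, V, using shortest
round-trip number formatting; the −10 sentinel marks points outside the
ventricular myocardium. Cell tag integers (LV = 1, RV = 2) are a package
convention, configurable per mesh via `meta$tags`. The scaled Jacobian uses
the Verdict/CUBIT normalisation (regular tetrahedron = 1, repeated-vertex
elements score 0 with a warning). Mean wall thickness is wall volume /
endocardial area — an approximation, documented as such. PCA mode signs
are fixed by making each mode's largest-magnitude coordinate positive.
CSVs are comma-separated, '.' decimal, UTF-8, header mandatory, missing
phenotypes as empty fields.

## Problem sizes

The default template resolution is 6 mm (≈ 2,000 nodes, ≈ 9,000
tetrahedra); the test suite and the acceptance script mostly use 8 mm
(≈ 800 nodes), cohorts of 10–19 cases, Saltelli N of 256–4096, and GSA over
the first 9 modes — sizes chosen so the full pipeline runs in minutes on a
single core while every structural property (exact recovery, conservation,
convergence, census arithmetic) is still exercised at full strength.

## Limitations

The surrogate has no 3D stress field, no fibre architecture, no atria or
pericardial boundary conditions, and a one-trigger EP→mechanics coupling,
so absolute phenotype values are indicative rather than predictive; the
analyses the package exists for compare *variation across anatomies* under
identical parameters. The generator's five factors plus iid jitter cannot
reproduce the full richness of real anatomical covariance (valve planes,
outflow tracts, atrial topology), and passing recovery tests on synthetic
cohorts demonstrates correctness of the machinery, not validity on clinical
data. Currents-based diffeomorphic registration is out of scope: the SSM
requires meshes in exact point correspondence, which the generator
guarantees by construction.
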