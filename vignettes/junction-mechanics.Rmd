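---
title: "Quantifying junctional mechanics and RhoA signaling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying junctional mechanics and RhoA signaling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctionmech)
```

This package collects the computational procedures used to study contractile
RhoA--non-muscle-myosin-II (NMII) signaling at the epithelial zonula adherens
(ZA) and its relaxation by the RhoA antagonist SRGAP1: an ODE model of the
junctional signaling network, viscoelastic fitting of laser-ablation recoil,
FRAP recovery fitting, line-scan quantification of junctional fluorescence,
and motility summaries of nuclear tracks. Each estimator is a small,
self-contained S3 model object; a synthetic-data module generates every input
with known ground truth so the whole pipeline can be validated without any
microscope.

## The junctional signaling network

The network couples six species: RhoA, ROCK1, NMIIA, Rnd3, p190B RhoGAP and
SRGAP1. Abundances are dimensionless junctional amounts; the model treats
cortex-localized protein as active, so "concentration" means localized,
signaling-competent protein. Every dynamic species follows

$$\frac{dX_i}{dt} = b_i + \sum_{j \in \mathrm{stim}(i)} w_{ji}\,
H(X_j) \;-\; X_i\Big(d_i + \sum_{j \in \mathrm{rep}(i)} w_{ji}\, H(X_j)\Big),
\qquad H(x) = \frac{x^n}{K^n + x^n},$$

a pairwise stimulation/repression rate law with saturating Hill responses.
Repression acts multiplicatively on first-order removal, which keeps
trajectories non-negative for any non-negative initial condition and is the
standard way such double-negative motifs produce bistability. SRGAP1 is
exogenous: it has no production or removal dynamics and either stays at its
initial value or follows a linear ramp (`forcing = list(t_ramp, rate)`),
because the experiments it mirrors manipulate its level directly.

The default architecture (see `build_default_model()`) is: RhoA → ROCK1,
ROCK1 → NMIIA and NMIIA → ROCK1 (the cortical-anchoring positive loop);
ROCK1 ⊣ Rnd3, Rnd3 → p190B, p190B ⊣ RhoA (the double-negative branch);
SRGAP1 ⊣ RhoA orthogonal to all of it.

### Default parameters

The published account of this network fixes the architecture and the ramp
protocol (ramp onset at *t* = 200 model-time units, slope 0.0075 per time
unit, all species initialized to 1 except SRGAP1 at 0) but not a rate-law
parameterization, so the default parameter set here is this package's own,
chosen once to satisfy the qualitative behaviour the architecture is known
to produce and then pinned:

* Hill coefficient *n* = 4 and threshold *K* = 0.5 on every edge, except
  *K* = 0.85 on RhoA → ROCK1. The higher threshold makes ROCK1 require
  near-fully-active RhoA, so during a slow SRGAP1 ramp the active branch
  collapses (saddle-node) while RhoA is still clearly above the midpoint
  between the branches — the graded-decline-then-switch shape, rather than
  a smooth fade.
* Basal production 1.0 for RhoA and Rnd3 (species present by default),
  0.05 for the feedback-recruited species; removal 1.0 everywhere.
* Interaction strengths 1.0 (RhoA → ROCK1), 0.35 (NMIIA → ROCK1),
  1.5 (ROCK1 → NMIIA), 8 (ROCK1 ⊣ Rnd3), 1.5 (Rnd3 → p190B),
  5 (p190B ⊣ RhoA), 5 (SRGAP1 ⊣ RhoA). The weak NMIIA → ROCK1 edge is
  deliberate: the ROCK1/NMIIA loop must not be self-sustaining without
  RhoA input, otherwise SRGAP1 could never switch the network off.

With SRGAP1 = 0 this model is bistable: a high state (RhoA ≈ 1.0,
ROCK1/NMIIA high, Rnd3/p190B suppressed) and a low state (RhoA ≈ 0.17,
antagonists dominant). The inactive state remains stable all the way down to
SRGAP1 = 0, so in the hysteresis sweep the up-switch level is reported as 0:
once switched off, the network does not recover by removing SRGAP1 alone —
consistent with a strongly hysteretic toggle. All parameters are overridable
through `srgap_network()` or a JSON config.

### Numerics

Integration uses `deSolve::ode` (lsoda, stiff-capable), relative tolerance
1e-8, absolute 1e-10, with the ramp discontinuity handled by splitting the
integration at the onset. Steady states are declared at ‖dX/dt‖ < 1e-9
(chunked integration, cap *t* = 1e5); fixed-point scans start from all
corner combinations of {0.05, 1.5} per dynamic node (32 starts), cluster
endpoints at 1e-4 Euclidean tolerance, and verify each candidate by
residual norm (< 1e-8) and the eigenvalues of a central-difference Jacobian.
Regime classification calls a time point "switched-inactive" once RhoA is
below the midpoint between branch reference levels and never recrosses;
`bistable_switch_levels()` locates the folds by bisection on frozen-SRGAP1
steady states, detecting loss of the active branch as coalescence with the
branch reached from the inactive basin (a midpoint-crossing criterion would
misread the smooth pre-fold decline as the switch).

## Kelvin--Voigt recoil fitting

After a junction is cut, the vertex distance relaxes as
$L(t) = L_0 + A(1 - e^{-kt})$: the Kelvin--Voigt (spring ∥ dashpot) response.
The initial recoil velocity $v_0 = Ak$ indexes tension; *k* reflects the
elasticity/viscosity ratio. Choices that matter:

* $L_0$ is fixed from the pre-ablation frame, not fitted — on a 5-point
  curve a free offset is strongly correlated with *A*.
* *t* = 0 is the ablation instant. The reference acquisition has a 12 s gap
  between the pre-ablation frame and the first post-ablation frame with the
  cut somewhere inside it; the first post-ablation frame is placed at a
  configurable 12 s (then 8 s intervals), the conservative end of that gap.
* Fits use bounded Levenberg--Marquardt with a log-linearized start; a flat
  curve returns $A = 0$, $v_0 = 0$ with *k* flagged unidentifiable rather
  than erroring (with no recoil there is no rate to estimate).
* The per-condition fit is on the pointwise mean of ≥ 12 junctions, as in
  the reference protocol; per-junction fits are also exposed. Initial
  recoils are normalized to the same-experiment control mean before
  conditions are compared across experiments.

## FRAP fitting

Normalization is $\mathrm{FRAP}(t) = (F(t) - F(0)) / (F(i) - F(0))$ with
$F(i)$ the mean of the (default 3) pre-bleach frames and $F(0)$ the first
post-bleach frame, so recovery starts at exactly 0 and full recovery maps
to 1. The fit is the one-phase association model
$\mathrm{FRAP}(t) = M_f\,(1 - e^{-\ln 2\, t/t_{1/2}})$ with $Y_0$ fixed at
0; $M_f$ is the plateau (mobile fraction), the immobile fraction is
$1 - M_f$ by construction. Note the decaying exponent: a published rendering
of this formula shows a positive exponent, which cannot describe a recovery
that plateaus at $M_f$; the decaying form is implemented. Bleach-depth QC
flags series below 70% depth (the protocol's achieved depth). No
acquisition-photobleaching or reference-ROI correction is applied by
default, since the reference protocol describes none.

## Line-scan image quantification

Profiles are sampled perpendicular to the junction (20 um long, averaged
over 30 parallel 1-px-spaced lines, bilinear interpolation, 1-px steps).
Readouts:

* **Gaussian peak** (E-cadherin, RhoA, ROCK1, SRGAP1, cortactin): fit of
  amplitude, center, width and a constant baseline; the reported value is
  the amplitude *over* the fitted baseline. A windowed background — the
  mean of the two 5-px windows starting just past 10 px on either side of
  the maximum — is reported alongside but not subtracted again, avoiding
  double subtraction. Whether the original analysis fitted a baseline or
  aggregated background windows by mean is not stated anywhere; both are
  configurable, and the defaults (baseline term + mean aggregation) are
  recorded here.
* **Band AUC** (F-actin, NMIIA, which form two parallel perijunctional
  bundles): sum of background-subtracted intensities over ±10 px around
  each band center, centers found as the two highest-prominence local
  maxima within 3 um of the scan center (falling back to one).
* **Co-localized readout** (pY421-cortactin at the cortactin peak):
  background-subtracted target intensity at the reference channel's fitted
  peak position, plus the target/reference ratio.
* **Junction/cytoplasm ratio** (GFP-AHPH biosensor for GTP-RhoA): mean
  intensity in a 20-px-wide band along the junction polyline over the mean
  of a user-supplied cytoplasm mask; the masks must not overlap.

Apical orientation of stacks is explicit metadata, never inferred.
Batch summaries refuse fewer than 25 junctions per condition (IF) or 60
(AHPH) unless forced, mirroring the reference sampling minima.

## Motility

MSD is time-averaged per track over overlapping windows, then
ensemble-averaged, with lags capped at 25% of track duration — the
estimator that makes the most of 30--40 nuclei tracked over 6 h. The
summary fit is a power law $\Gamma \tau^{\alpha}$ on log-log axes evaluated
at 6 h (the original fit model is unstated; the power law subsumes the
diffusive case $\alpha = 1$, $\Gamma = 4D$, and a linear $4D\tau$
alternative is provided). Relative MSD divides fitted 6-h values
condition/control per experiment. Wound-margin displacement is the mean
signed advance along the wound axis between margin polylines interpolated
onto a common along-margin grid.

## Synthetic data

Generators emit exactly what the fitters consume, with ground truth and the
seed recorded: recoil curves on the 12 s + 8 s frame schedule; FRAP traces
with 3 pre-bleach + 57 post-bleach frames at 5 s and 75% default bleach
depth; junction images with Gaussian cross-section bands (one or two,
±1 um offset) over uniform background with optional Poisson photon noise
and Gaussian read noise; persistent-random-walk tracks (drift + optional
OU-correlated velocity + diffusion) at 35 nuclei × 6 h; rough wound
margins with a set mean advance. Noise defaults (σ = 0.05 um for recoil,
σ = 0.03 normalized units for FRAP, Poisson for images) sit in each
fitter's identifiable regime and mirror standard microscopy noise
structure.

What the generators do *not* emulate: point-spread-function blur, uneven
illumination, junction curvature and intersections, tracking errors,
photobleaching during acquisition, and cell-cell heterogeneity beyond the
parameter spread the user injects. Passing round-trip tests therefore
demonstrates estimator correctness and calibration, not robustness to
every real-microscopy artifact.

## Problem sizes and validation design

The test-suite and acceptance runs use 200 Monte-Carlo replicates for the
recoil and FRAP recovery studies, 15 replicates per amplitude for the
Poisson-noise image study, 1000 tracks for the diffusion calibration, and
the 32-corner grid for the fixed-point scan — sizes at which Monte-Carlo
error is comfortably below the tolerances being checked while the whole
suite stays fast. The acceptance script reruns all of it from scratch from
a single seed; the CLI pipeline is run twice per check and compared
byte-for-byte.

## Known limitations

* The network model's parameter set is a stand-in consistent with the
  published architecture and protocol, not a fit to data; quantitative
  switch levels are meaningful only relative to this parameterization.
* Model time and concentration units are dimensionless; no mapping to
  physical units is attempted.
* Recoil's sub-interval ablation instant is unknowable from the frame
  schedule alone; absolute *k* and $v_0$ shift slightly with the assumed
  delay (normalized comparisons are insensitive to it).
* The junction quantifiers assume the ROI actually crosses a junction;
  there is no automatic junction detection.
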