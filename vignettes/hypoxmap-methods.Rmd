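---
title: "Models and methods behind hypoxmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hypoxmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoxmap)
```

This vignette documents the models the package implements, the
assumptions behind them, the tunable parameters, and the design
decisions taken where the methodology left genuine freedom. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The sqBOLD signal model

The FLAIR-ASE acquisition samples the extravascular signal at spin-echo
shifts τ (here 0, 16–60 ms in 4 ms steps, TE = 74 ms). Under the static
dephasing approximation, with CSF nulled by the FLAIR preparation, the
log signal follows a piecewise decay: a quadratic regime for τ < τc,

$$\ln S(\tau) = \ln S_0 - R_2 TE - 0.3\,(R_2'\tau)^2 / DBV,$$

and a linear regime for τ ≥ τc,

$$\ln S(\tau) = \ln S_0 - R_2 TE + DBV - R_2'\tau,$$

with τc fixed at 16 ms (a conservative gray-matter estimate that
coincides with a sampled shift; the transition point is assigned to the
linear branch). The two branches are discontinuous at τc for generic
parameters — the model is an asymptotic description, not a continuous
curve — which drives two implementation choices:

* **Estimators.** The reference processing for this kind of data uses
  variational-Bayes fitting whose free-energy convergence criterion is
  not reproducible from its description. The package instead provides
  two documented estimators of the same estimand: `fit_loglinear()`, an
  exact closed form (OLS of ln S against τ over the linear regime gives
  slope −R2′; the intercept minus the measured ln S(0) gives DBV, since
  the extrapolated linear branch sits exactly DBV above the τ = 0
  signal), and `fit_nonlinear()`, a bounded nonlinear least-squares fit
  of both branches (R2′ ∈ [0, 100] s⁻¹, DBV ∈ (0, 0.5]), initialized
  from the closed form. On noiseless model data the two coincide; under
  noise the nonlinear fit additionally exploits the short-τ points.
  Convergence of the box-constrained optimizer is judged by the
  objective value, not its return code, because the line search
  legitimately aborts when started at an exact optimum.

* **Peak-location failure criterion.** The model predicts the signal
  maximum at τ = 0, and voxels violating this are flagged. However,
  whenever DBV > R2′·τc — which holds for the slow-decaying, high-DBV
  edema and nonenhancing compartments at their published group means —
  the *model itself* places the sampled maximum at the first
  linear-regime point (its value, c0 + DBV − R2′τc, exceeds c0). A
  strict peak-at-zero test would therefore flag entire healthy
  compartments on noise-free data. The package flags only signal peaks
  *strictly beyond* τc, which still catches the mid-sequence anomalies
  (peaks at τ = 20–28 ms) this criterion exists for.

OEF follows from `compute_oef()` as
$3R_2'/(4\pi\,\gamma B_0\,\Delta\chi_0\,Hct\,DBV)$ with γ = 267.5×10⁶
rad T⁻¹ s⁻¹, B0 = 3 T, Δχ0 = 0.264 ppm (converted to an absolute
susceptibility), Hct = 0.4. OEF is stored as a fraction, reported as a
percentage, and deliberately not clamped to [0, 1]: super-unity values
occur in practice near air-tissue interfaces and in enhancing tissue and
are diagnostic information, not errors.

### Failure classification

A voxel enters the error mask when any of the following holds: signal
peak beyond τc (optionally after moving-average smoothing, width
`smooth_width`, default off); fitted R2′ < 0; DBV outside (0, 0.5];
normalized RMS fit residual above `residual_frac`; non-finite signal; or
magnitude below the signal floor (5% of the robust maximum — this
pre-masks background air). Flagged voxels are NA in the in-memory maps
and are excluded from every VOI summary, cluster percentile, and
neighborhood mean; `write_qbold_maps()` zero-fills them on disk, the
convention for displayed maps.

The residual threshold deserves a note: the expected normalized residual
on *model-consistent* data is roughly the log-signal noise SD divided by
the decay range, which at 2% magnitude noise is already 0.2–0.4. A tight
threshold (e.g. 0.05) would flag essentially all voxels at clinical SNR,
so the default is 0.5 — a gross-misfit detector — and the parameter is
exposed in `failure_thresholds()`.

## 2. DSC perfusion and vessel size

Both channels of the dual-echo DSC series (TR 1.5 s, TE 18.6/69 ms, 122
volumes, first 4 discarded as non-steady-state) are converted to
relaxation-rate changes ΔR2(t) = −ln(S/S̄base)/TE; the standard DSC
convention, required by the units of the vessel-size relation.
Non-positive samples are repaired by temporal interpolation. The bolus
window is detected on the brain-mean ΔR2* curve: entrance at the first
crossing of baseline mean + 3 SD sustained for two samples, exit at the
first post-peak return below that threshold; the baseline is then
re-estimated from all samples up to two before the entrance.

**Leakage correction.** In blood-brain-barrier-disrupted (enhancing)
tissue the measured ΔR2* is biased by contrast extravasation. The BSW
correction fits each voxel's curve to K1·ΔR̄2*(t) − K2·∫ΔR̄2*dt′, where
ΔR̄2* is the mean curve over a non-leaky reference mask, and adds the
K2 term back. When no reference mask is supplied, a first pass over all
brain voxels selects the half with the smallest |K2| as the reference.

**CBV** is the trapezoidal integral of the corrected ΔR2* over the
bolus window, divided by its mean over the contralateral-WM mask (so
contra-WM has mean CBV 1 by construction, and the map is invariant to
global intensity scaling).

**Vessel size** is
$0.867\,(CBV\cdot ADC)^{1/2}\,\Delta R_2^{*peak}/(\Delta R_2^{peak})^{3/2}$,
with ADC in mm²/s and rates in s⁻¹, giving mm, reported in µm. ADC
comes from the log-linear fit over b = 0, 10, 1000 s/mm². Two numerical
guards apply: vessel size is only evaluated where normalized CBV exceeds
0.05 (0/0 noise amplification), and where the spin-echo peak is
positive. The spin-echo curve is used uncorrected — extravasation
predominantly biases the gradient-echo channel, and no leakage model for
ΔR2 is established.

**Peak extraction.** The naive per-voxel maximum of a noisy rate curve
carries selection bias and single-sample variance. Since every voxel's
response shares the bolus time-profile, the default (`peak_method =
"fit"`) estimates each voxel's peak as its least-squares amplitude
against the reference mean curve (with an intercept absorbing the
finite-baseline offset of the ΔR2 conversion) times that curve's window
maximum. This is identical to the raw maximum on noise-free data and
pools every timepoint under noise; the literal window maximum remains
available (`peak_method = "max"`). Even so, vessel size is the most
noise-sensitive output of the pipeline: at 2% magnitude noise its
median relative error on the phantom is bounded in the tests at 7.5%
(the amplitude-noise floor of the data; CBV is bounded at 5%), while
noiseless recovery is exact to ≤ 0.001 absolute (CBV) and ≤ 1%
(vessel size).

## 3. VOI analysis

Contralateral GM/WM masks come from probability maps thresholded
*strictly above* 0.9 (minimizing partial-volume effects) within the
contralateral hemisphere. Tumor masks (edema, nonenhancing, enhancing,
necrosis) are inputs, validated to share one grid and to be pairwise
disjoint; no registration or segmentation is performed — co-registered
inputs are a precondition, enforced by strict shape equality.

VOI-averaged FLAIR-ASE curves are means ± SD of the log signal over the
unflagged voxels of each VOI, shifted by an additive constant so every
curve starts at the contralateral-GM curve's τ = 0 value (the offsets
act on the means only; SDs are left unshifted). Alignment is idempotent.

Per-VOI summaries report the median and IQR (Q3 − Q1,
linear-interpolation percentiles, i.e. R's `quantile(type = 7)`; the
percentile convention is not prescribed by the methodology and is
declared here). Group-level tables are the mean ± SD across subjects of
the per-subject medians. `n_excluded` counts exactly the error-mask
voxels intersecting each VOI.

## 4. Biopsy targeting

Clusters are 26-connected components of voxels above the 80th (or below
the 20th) percentile of a metric, the percentile being computed over the
unflagged voxels of the search mask — the union of nonenhancing,
enhancing and necrosis; edema is excluded because biopsies there are
prohibited by protocol. A component qualifies with ≥ 9 voxels ("minimum
of nine voxels, arranged cubically"). Nine voxels cannot literally form
a cube, so the compactness reading is configurable: the default demands
a full 2×2×2 block inside the component (`shape = "block222"`); the
in-plane alternative demands a 3×3 square in some axial slice
(`"plane33"`).

Metrics are considered in the order OEF, then CBV, then vessel size;
clusters from different metrics that share voxels merge into one
candidate. Ranking is deterministic: more metrics first, then larger
cross-metric overlap, then earlier metric precedence, then mean
extremity, with the smallest linear voxel index as the final tie-break —
so the output is invariant to input list order. The neurosurgeon's
choice among candidates is replaced by deterministic rank truncation
(`max_targets`, default 4, matching the 2–4 biopsies per patient of
surgical practice).

Target MRI values average the 3×3×3 neighborhood of the center voxel
(27 voxels including the center, clipped at the grid boundary, excluding
flagged voxels). The phrase "adjacent nine voxels in three dimensions"
also admits a literal ten-voxel reading — center plus the nine nearest
neighbors — available as `neighborhood = "center10"`.

## 5. Histology quantification

Vessel density is total vessel area over total tissue area within the
hotspot ROIs (a fraction); mean vessel diameter is the unweighted mean
of per-vessel diameters, with the equivalent-circle diameter
2√(area/π) as fallback when only segmentation areas exist
(rotation-invariant and standard). HIF-1α staining is summarized by the
standard immunohistochemistry H-score, Σ level × percent cells over
intensity levels 0–3, range 0–300; the underlying slide-analysis
protocol's exact binning is not public, so the H-score is the declared
convention here. Avascular samples yield density 0 and diameter NA
(flagged, not an error).

## 6. Statistics

Kruskal–Wallis (tie-corrected, χ² p on k−1 df) compares each metric
across the three biopsied compartments; Mann–Whitney U (exact
enumeration when both groups ≤ 8 without ties, otherwise tie-corrected
normal approximation with continuity correction) runs post hoc on all
pairs; Spearman (average ranks, t-approximation p) tests the three
MRI–histology pairs: OEF vs H-score, CBV vs vessel density, vessel size
vs vessel diameter, at α = 0.05. Fully tied data are the degenerate
H = 0, p = 1 case. **No multiple-testing correction is applied
anywhere** — pairwise p-values are reported raw, exactly as they are
annotated on the bar plots; rows with undefined values are dropped
listwise per tested quantity and counted. Biopsies are treated as
independent observations, ignoring within-patient clustering, which the
tests themselves assume.

## 7. The phantom: what it emulates, and what it does not

The generator exists so every stage is testable by recovery. Geometry
is deliberately schematic: nested concentric ellipsoids (necrosis inside
enhancing inside an edema envelope) plus a separate nonenhancing blob in
one hemisphere, a GM shell around a WM core contralaterally, and a
mid-sagittal CSF slab. Region parameters default to published group
means for R2′, DBV, CBV and vessel size in contralateral GM and the four
tumor compartments; contralateral WM (absent from those tables) uses
literature-plausible values with CBV_true = 1 as the normalization
reference, and the FLAIR preparation is emulated by a CSF S0 of 5
against 90–100 in tissue, making CSF the low-SNR compartment where
failures concentrate. CSF's R2′/DBV defaults (1 s⁻¹, 0.5%) keep its
noiseless signal model-consistent.

The DSC bolus is a gamma-variate (onset 20 s, α = 3, β = 1.5 s — no
arterial input function is specified by the methodology) scaled so the
normalized bolus integral reproduces each region's CBV_true exactly; the
spin-echo response is calibrated through the Kiselev relation so the
grid-sampled peak ratio returns vessel_size_true; an amplitude of 20 s⁻¹
peak ΔR2* per unit CBV (≈ 33 s⁻¹ in GM) sits mid-range for
standard-dose 3 T DSC. Leakage is injected only in the enhancing
compartment (K2 = 0.05 s⁻¹) as the same extravasation term the BSW
estimator models, so matched-model inversion is exact. Noise is
Gaussian on the magnitude by default (Rician available), with SD a
fraction of the maximum tissue S0; the default of 1% yields sporadic,
CSF-concentrated fit failures comparable to clinical FLAIR-ASE data,
and 2% is used in the noise-robustness tests.

A "shifted-peak" corruption mode re-parameterizes selected regions'
decay by |τ − τpeak| (default peak 28 ms), reproducing the documented
failure where tumor signal peaks mid-sequence, to exercise the error
mask. The functional form is an invention; only the peak location is
data-motivated.

Histology is coupled to the ground truth by monotone links with
additive noise: vessel diameter tracks local vessel_size_true, density
tracks normalized CBV_true, H-score tracks the ground-truth OEF. With
zero noise the induced Spearman correlations are exactly 1, which pins
the sign conventions of the whole chain.

What the phantom does **not** emulate — and what passing tests therefore
do not establish about real data: anatomical geometry and partial-volume
mixing at tissue interfaces; motion and registration error (inputs are
assumed co-registered); macroscopic B0 inhomogeneity, which inflates
real OEF near air-tissue interfaces and is only correctable with
z-shimming or field maps; diffusion narrowing violating the static
dephasing assumption (the documented cause of real shifted-peak signals
in fluid-rich tumors — the corruption mode mimics the symptom, not the
physics); arterial input function variability, recirculation, and
dispersion; and any biological scatter in the MRI-histology link beyond
the declared monotone-plus-noise coupling.

## 8. Problem sizes and reproducibility

The test suite and acceptance script use 24³ phantoms for module tests
and 32³ for end-to-end checks, 13 τ shifts, 122 DSC volumes, 100
repetitions for the leakage-correction comparison, and 2000 simulations
for the α = 0.05 calibration of the statistical tests — sizes at which
the full suite completes in a few minutes on one CPU. Every stochastic
path is seeded: `phantom_spec(seed)` drives all simulators (each takes
an explicit `seed` override), and `run_pipeline()` writes a manifest
with the config hash and per-file checksums; identical configs reproduce
identical artifacts bit-for-bit, and reruns resume from cached stage
outputs when the config hash matches.

## 9. Known limitations

* S0 and R2 are not separately identifiable from a single-TE FLAIR-ASE
  acquisition; the fit stores their combination ln S0 − R2·TE.
* The log-linear estimator ignores the quadratic-regime points beyond
  τ = 0 by construction; the nonlinear estimator uses them but inherits
  the model's branch discontinuity at τc.
* DBV is the noise-limiting sqBOLD parameter: its estimate is a small
  difference of intercepts, so positivity violations dominate the error
  mask as noise grows.
* Vessel-size accuracy is bounded by peak-amplitude SNR even with the
  matched-filter peak estimator; low-CBV compartments (necrosis, edema)
  are the least reliable.
* The statistics module tests each biopsy as independent; hierarchical
  (per-patient) structure is out of scope.
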