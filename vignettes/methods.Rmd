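---
title: "Methods: multimodal detection of whole-brain tumor burden against a fluorescence ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal detection of whole-brain tumor burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorburden)
```

## The problem

Conventional anatomic MRI under-detects infiltrative, non-enhancing
glioblastoma, and amino acid PET sees some of what MRI misses — but neither
modality can be validated across the *whole* brain by surgical sampling. In
the preclinical design this package analyses, tumor cells are transduced
with the tdTomato fluorescent protein, so after in vivo T1-weighted
(gadolinium-enhanced), T2-weighted and amino acid PET imaging, the excised
brain can be sliced, optically cleared, and imaged ex vivo: the fluorescence
defines a voxel-wise ground truth for the full tumor burden. Every in vivo
segmentation is then scored against that truth, and PET uptake is regressed
against the underlying biology (tumor cell content, ASCT2 amino acid
transporter expression, perfused vasculature, tumor volume, blood–brain
barrier status).

The package provides the complete computational chain: volume geometry and
NIfTI I/O, cross-grid resampling, landmark registration, threshold
segmentation, overlap and surface metrics, exact nonparametric group
comparisons, the correlate regression, and a synthetic phantom generator
that serves as the pipeline's test bed.

## Geometry and resampling

All volumes are axis-aligned lattices with per-axis spacing in millimetres
and a center-of-voxel origin; the world position of voxel $(i,j,k)$ is
$\mathrm{origin} + (i,j,k)\cdot\mathrm{spacing}$. Distances are always
computed in world mm, never in voxel indices, because the analysis mixes a
fine MRI-class grid ($0.2 \times 0.2 \times 0.5$ mm) with a coarse PET grid
($0.5 \times 0.5 \times 1$ mm). Oblique acquisitions are rejected at the
I/O boundary: any rotation must be resolved by the registration step, which
keeps the counting metrics exact.

Masks are resampled by nearest voxel center only — interpolating a binary
mask would manufacture fractional voxels and corrupt the sensitivity and
specificity counts. Intensity volumes moving to a coarser grid are
block-averaged. Because $0.5 / 0.2 = 2.5$ is not an integer, the fine grid
cannot be block-averaged directly onto the PET grid; `resample_to_spacing`
therefore refines to the common 0.1 mm lattice (nearest-neighbour, exact
for the piecewise-constant image model) and then averages integer blocks.
The choice of nearest-neighbour upsampling slightly affects boundary voxel
counts; the scoring grid is a parameter of `evaluate_case` so this
sensitivity can be audited.

## Registration

The original analysis registered images interactively in a GUI; this
implementation uses the deterministic alternative that the ex vivo workflow
already requires: least-squares affine fits to landmark pairs. With $n \ge
d+1$ non-degenerate pairs the ordinary least-squares solution of
$A x_i + t \approx y_i$ is unique; with exactly $d+1$ pairs it
interpolates. Cleared tissue slices deform anisotropically, so per-slice
transforms are full 6-dof 2D affines rather than similarities. Resampling
is by pull-back through the inverse transform, with 0 (background) outside
the acquired field. The registration module reports the fiducial
registration error; no quantitative accuracy target exists for the original
data, so the tests validate *recovery*: slices perturbed by known affines
and re-registered through exact landmarks reproduce the original tumor mask
with Dice above 0.95 (observed ≈ 0.997 — residual error is pure
double-nearest-neighbour resampling at mask boundaries).

## Segmentation and metric expansion

Tumor segmentation is inclusive thresholding (voxel kept iff value ≥
threshold) with an optional exclusion mask standing in for the manual
removal of clearly-non-tumor structures (ventricles, extra-cranial signal).
Inclusive comparison makes the noiseless-phantom recovery exact by
construction. T1 and T2 segmentations are OR-combined into "MRI", and MRI
with PET into "MRI+PET". The expanded-MRI reading grows the MRI mask by a
metric radius (default 2 mm) using an exact anisotropic Euclidean distance
transform (a small compiled kernel; the classic two-pass
lower-envelope-of-parabolas algorithm per axis), not an index-space
structuring element. Expanded masks are clipped to the brain region before
specificity is computed (the unclipped volume is still reported); the
original description is silent on this, and clipping is the conservative
choice since voxels outside the optical brain region are unscoreable.
Expansion is performed in 3D; whether the original was in-plane only is
unstated.

One containment direction of chained expansions is a theorem (triangle
inequality on voxel centers): expanding by $r_1$ then $r_2$ never escapes a
single expansion by $r_1 + r_2$. The converse containment can fail on a
discrete lattice (the intermediate point of the continuous path need not be
a voxel center), so only the true direction is asserted.

## Detection scores

With detection $D$, truth $T$ and optical brain region $B$, all on the fine
(tdTomato) grid:

* sensitivity $= |D \cap T| / |T|$;
* specificity $= (|B| - |(D \cup T) \cap B|)/(|B| - |T|)$ — detections
  outside the brain region are ignored, and true-tumor voxels are never
  counted as false positives;
* Dice $= 2|D \cap T| / (|D| + |T|)$;
* maximum surface distance: surface voxels are set voxels with an unset
  6-neighbour (volume faces count as boundary); for each surface voxel of
  either mask, take the minimum world-mm distance to the other mask's
  surface voxels, and report the maximum over both directions. An empty
  detection has no surface, so the distance is undefined and reported as
  "nd", excluded from medians — exactly how undetected tumors are handled
  in the published table.

An empty detection scores sensitivity 0, Dice 0, specificity 1, distance
"nd". All four metrics are validated against brute-force counting and
all-pairs-distance oracles on random anisotropic mask pairs, and the
surface-distance computation reuses the same exact distance transform as
the expansion.

Reported values are rounded half-up only at the reporting layer (scores to
2 decimals, volumes to whole mm³, p-values to 1 significant figure at or
below 0.01); full precision is kept internally.

## Exact group statistics

With 13 tumors, normal approximations are inappropriate; both Wilcoxon
tests are computed exactly by enumeration over midranked data (ties halve
ranks; doubling makes them integers, and the null distribution is built by
convolution — algebraically identical to enumerating all $2^m$ sign
assignments or all $\binom{n_1+n_2}{n_1}$ group assignments). Paired
modality contrasts use the signed-rank test with zero differences
*discarded* (the classical convention); unpaired Gd+ vs Gd− contrasts use
the rank-sum test. Two-sided p is twice the smaller tail, capped at 1. When
every difference is zero the test is degenerate and reported as p = 1 with
a flag. These conventions reproduce every published p-value from the
packaged per-tumor table: 2/2⁹ ≈ 0.004 and 2/2¹³ ≈ 0.0002 for the
sensitivity gains of the combined reading, 2/2⁹ and 2/2¹⁰ ≈ 0.002 for its
specificity costs, and 36/715 ≈ 0.050 for the Gd+ vs Gd− combined-MRI
sensitivity contrast.

The published table's own "Overall Median" row disagrees with the
accompanying text in two places (optical volume 95 vs 86 mm³ — the latter
is the PET-visible-stratum median — and combined specificity 0.92 vs 0.91).
`summarize_cohort` recomputes everything from the per-tumor rows and treats
the recomputed value as canonical rather than silently reconciling.

## PET correlates

Tumor-level records normalize the maximum PET uptake over the truth mask,
and the mean of each fluorescence channel, by the mean of the same image
over a contralateral normal-brain mask — removing global scale, so the
records are invariant to rescaling any whole image. Voxel-level records
live on the PET grid after block-averaging the fluorescence channels.
Continuous variables are log-transformed and z-scored (denominator $n-1$);
the binary gadolinium status is z-scored but not logged (log 0 is
undefined). Whether the original standardization also applied to the
response is unstated; both conventions are supported
(`standardize_response`, default `TRUE` — with the response standardized
the coefficients are fully standardized betas, and the switch makes the
alternative auditable rather than guessed).

The fit is ordinary least squares; with lectin missing for some tumors the
full model runs on complete cases and the lectin-free model on all cases,
mirroring the dual reporting in the source analysis. Voxel-level fits
ignore within-tumor correlation (plain OLS) since no clustering correction
is described. Partial-regression (added-variable) plots residualize both
the response and the regressor of interest against all other regressors;
the Frisch–Waugh–Lovell identity — the slope of those residuals equals the
multivariate coefficient — is asserted to $10^{-10}$ in the tests.

The published $R^2 = 0.77$ and $\beta_{TDT} = +1.27$ derive from images
that are not public, so they are not reproduction targets. What the package
verifies instead is the statistical machinery: exact coefficient recovery
on noiseless designs, near-null behaviour on pure noise, and unbiased
recovery (within Monte-Carlo error over 200 replicates) of a
tdTomato-dominant generative model at the study's n = 13.

## The phantom generator

Each synthetic case emulates the acquisition geometry and the study's
strata on desk-scale grids: a 70 × 60 × 24 voxel fine grid at
0.2 × 0.2 × 0.5 mm (the true optical in-plane resolution of 34.4 μm is not
simulated — the analysis contracts depend on grid *ratios*, not absolute
resolution) and a PET grid at 0.5 × 0.5 × 1 mm. Components:

* **Brain**: ellipsoid, default semi-axes 6.6 × 5.4 × 5.4 mm.
* **Cell density**: 1 inside a spherical core (default radius 2 mm, offset
  2.2 mm into one hemisphere), ramping to 0 across an infiltrative margin
  (default 1 mm) modulated by a smoothed random field, so the margin is
  irregular. The ground truth is the noiseless tdTomato channel
  thresholded at its generative cutoff (density 0.2) — making the
  noiseless-recovery property exact by definition.
* **T1**: background plus the enhancing core, only when the case is Gd+.
* **T2**: detects tumor down to a cellularity limit controlled by
  `t2_detect_fraction` (1 = sees the whole truth); wider sparse margins
  therefore lower MRI sensitivity, reproducing the hardest-to-detect
  stratum qualitatively.
* **PET**: brain background 1 plus contrast × density (tumor-to-background
  default 3:1; 1:1 for the PET-invisible stratum), convolved with a
  separable Gaussian PSF (FWHM default 1.5 mm, σ = FWHM/2.355 per axis),
  noise added, block-averaged onto the PET lattice. The PSF produces the
  partial-volume overshoot that makes PET-segmented volumes exceed the
  optical truth. The overshoot grows with FWHM while the FWHM stays below
  the core radius; much wider PSFs collapse the peak below threshold, so
  the monotonicity property is asserted over 0.8–2.0 mm.
* **Fluorescence correlates**: ASCT2 and lectin are linear in cell density
  plus noise. This makes the *tumor-level* design strongly collinear
  (deliberately simple physics), which is why coefficient-recovery claims
  are tested on the table-level cohort generator with controlled effect
  sizes rather than on phantom-derived tables.
* **Contralateral mask**: mirrored hemisphere eroded 1.2 mm from the brain
  surface, clear of the tumor — coarse-grid samples of it avoid
  partial-volume dilution at the brain boundary, as a contralateral
  reference ROI would in practice.
* **Segmentation thresholds**: mid-contrast for MR channels, background +
  density-cutoff × contrast for PET (the level whose noiseless iso-surface
  is the truth boundary). A PET-invisible case (contrast 0) gets a
  threshold strictly above background, so the operator "segments nothing" —
  reproducing the volume-0 / sensitivity-0 / specificity-1 / "nd" row
  pattern of undetected tumors.

Cohorts follow the study composition 4 Gd+ / 5 Gd− PET-visible / 4 Gd−
PET-invisible, jitter core radius (±25%), infiltration width (±30%), T2
detection (0.6–0.95) and PET contrast per stratum, and derive per-case
seeds reproducibly from one master seed. The generator's single RNG scope
restores the caller's `.Random.seed`, so no global state leaks.

What passing on phantoms does *not* show: real MR relaxometry or PET count
statistics, tumor-induced edema (largely absent in these xenograft models
anyway), fluorescence loss by tumor cells, or deformable slice distortion
beyond affine. The phantom validates the analysis contracts, not the
acquisition physics.

## Problem sizes and numerical choices

The test suite and drivers use the default 70 × 60 × 24 phantom grid,
13-case cohorts, 100 random mask pairs up to 20³ voxels for the
metric-oracle equivalence, and 200 replicate cohorts for coefficient
recovery — sizes chosen so the complete analysis reruns in well under a
minute while every contract is still exercised at full precision. Numerical
tie-breaks: nearest-neighbour index mapping rounds half away from the lower
voxel (`floor(x + 0.5)`); expansion comparisons carry a 10⁻¹² relative
slack so exact-boundary offsets (e.g. squared distance exactly r²) survive
floating-point; exact-test p-values are built from integer convolution
counts and carry no rounding at all.
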