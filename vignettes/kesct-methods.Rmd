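---
title: "K-edge subtraction micro-CT morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{K-edge subtraction micro-CT morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`kesct` analyzes paired synchrotron micro-CT volumes of contrast-perfused
bone specimens acquired just below (17.9 keV) and just above (18.1 keV) the
K-absorption edge of a zirconium-based vascular casting agent. Because only
the contrast agent has an absorption edge between the two energies, the
registered difference image isolates the vasculature, while bone - whose
attenuation is essentially identical at the two energies - is quantified
from the sub-edge volume alone. The package covers the full chain: a
synthetic dual-energy phantom generator with exact ground truth, rigid
mutual-information registration, K-edge segmentation, 3D morphometry of the
vascular and bone compartments, hydroxyapatite-density distributions, and
nonparametric group statistics.

## Volumes, units, coordinates

A `volume_grid` is a 3D array with isotropic voxels (default 2.74 µm) and a
semantics tag (`gray`, `mu`, `dhap`, `binary`). The first array axis is the
axial slice index and, by convention, the drill-hole / analysis-cylinder
axis. Continuous voxel coordinates are 0-based; the center of 1-based voxel
`i` lies at `(i - 0.5) * voxel_um` micrometers. The analysis region is a
cylinder (default 720 µm diameter x 300 µm height) rasterized by the
voxel-center inclusion rule; its volume is reported as voxel count times
voxel volume, which agrees with the analytic cylinder volume to well under
1% at 2.74 µm voxels.

## Calibration

Two linear maps connect the measured 8-bit gray levels to physical
quantities: `mu = f * gray` (linear attenuation, /cm) and
`d.HAp = 136 * mu - 142` (hydroxyapatite-equivalent density, mg/cm³). The
µ-domain constants are canonical: the bone classification threshold
µ ≥ 4.74 /cm corresponds to d.HAp ≈ 500 mg/cm³ (136 × 4.74 − 142 = 502.6,
i.e. 500 to two significant figures), and the constructor enforces that
self-consistency to 5 mg/cm³.

The gray scaling `f` is acquisition-dependent and deliberately a plain
configuration parameter. The package default is `f = 0.392` /cm per gray
level, the scaling applied to the reconstructed stacks before subtraction;
it is the only choice under which the typical dynamic ranges fit an 8-bit
image: the supra-edge vessel attenuation of ~60 /cm maps to gray ≈ 153,
bone at 500-1400 mg/cm³ maps to gray 12-29, and sub-edge volumes occupy
roughly 0-60 gray. An alternative scaling `f = 7.97/136 ≈ 0.0586`
reproduces a gray-domain density line `d.HAp = 7.97 * gray − 142`
(published for the bone-quantification branch) and can be selected with
`calibration_line(gray_to_mu_factor = 7.97/136)`; the two printed scalings
are mutually inconsistent, so the package takes no position beyond making
both available and applying the configured factor uniformly.

## Registration

The two energy volumes are misaligned mainly by the stage's return-to-origin
error, so a 6-parameter rigid model (3 translations in voxels, 3 rotations
in degrees about the lattice axes, centered on the lattice) is sufficient; a
translation-only mode (`rotations = FALSE`) is available. The metric is
Shannon mutual information of the 64-bin joint histogram, evaluated with
trilinear interpolation on a strided voxel subsample (about 2 x 10^5
samples). The optimizer is fully deterministic: an exhaustive integer-shift
grid (default ±5 voxels), then cyclic coordinate descent with a bracket that
halves over four sweeps (1 voxel / 1 degree down to 0.125), then a
Nelder-Mead polish; the best-so-far parameters are kept if any stage fails
to improve the metric. A simplex started at zero rotation can stall on the
locally flat metric, which is why the bracketing stage precedes it. The
supra-edge volume is the fixed image; registration is estimated on whole
stacks and applied before ROI cropping. Resampling is trilinear with
zero fill outside the lattice; the identity transform returns its input
bit-exactly.

## Segmentation

The vascular pipeline follows the subtraction scheme: (1) the sub-edge
volume is expanded by a 3x3x3 maximum filter so that partial-volume
residuals at bone boundaries cancel in the difference (the neighborhood
size matches the other 3x3x3 operations and is configurable); (2) the
expanded sub-edge volume is subtracted from the supra-edge volume and
negatives are clamped to zero - they carry no vascular signal; (3) the
difference is smoothed with a 3x3x3 average; (4) a global minimum
cross-entropy (Li) threshold is computed over the ROI and voxels at or
above it form the vascular mask. Exact zeros are excluded from the
threshold histogram (configurable): after clamping they dominate the
background class without carrying information. A configurable floor on the
threshold (default 8 gray levels) guards the degenerate case of a specimen
without contrast agent, where the difference image is pure noise and a
histogram split would otherwise label the noise tail as vessels; any
genuine K-edge jump is an order of magnitude above the floor.

The Li threshold minimizes `-(A0 log m0 + A1 log m1)` (intensity sums `A`
and means `m` of the below/above classes) by exhaustive scan over every
distinct intensity split - deterministic, and verified in the tests both
against an independent exhaustive oracle and against the classical
iterative fixed point `t = (m1 - m0) / (log m1 - log m0)`, which induces
the same partition. The returned threshold is the midpoint between the
adjacent intensity levels at the optimal split.

Bone is classified from the 3x3x3-averaged sub-edge volume: every
extravascular voxel with µ ≥ 4.74 /cm (d.HAp above ~500 mg/cm³) is bone.
Vessel and bone masks are disjoint by construction.

## Morphometry

Six indices are computed inside the ROI: vascular and bone volume fractions
(V.Vf, B.Vf, %), mean vessel diameter (V.D, µm), bone thickness (B.Th, µm),
and vessel/bone segment densities (V.Seg, B.Seg, /mm³).

**Skeletonization** is homotopy-preserving 3D curve thinning: iterative
sequential deletion of simple points (topological characterization with
26-connected foreground and 6-connected background) over six directional
sub-iterations per pass, preserving curve endpoints. Voxel degree is
counted under 26-connectivity; node voxels (degree ≥ 3) are merged into
26-connected clusters so a thick junction is one node; segments are maximal
paths between node clusters and/or free ends. An isolated path with two
free ends counts as one segment, as does a pure cycle. Free-end spurs with
fewer than 2 own voxels (default, configurable) are pruned as thinning
artifacts and segments re-extracted.

**Local thickness** is the distance-ridge method: exact Euclidean distance
transform, reduction to maximal-ball centers, and sphere painting. The
diameter convention is `2 * dt` with `dt` the distance from a maximal-ball
center to the nearest background voxel center; a tube rasterized at nominal
diameter `d` voxels then measures approximately `d`, which keeps
boundary-diameter vessels in their nominal size class. The flip side of the
convention is a one-voxel overestimate for degenerate structures (an
isolated voxel measures 2 voxel widths); the tests pin both behaviors.

**V.D** is the unweighted mean of local diameter over all skeleton voxels;
**B.Th** is the mean local thickness over all structure voxels
(structure-volume-weighted). The different supports are deliberate and
preserved. The voxel-weighted V.D convention (rather than per-segment
weighting) is the default; per-segment diameters are also computed for the
size-specific analysis.

**Size-specific quantities** use five half-open diameter classes (<10,
[10,20), [20,30), [30,40), ≥40 µm; the printed labels are ambiguous at the
boundaries, so upper-exclusive edges were fixed). Each segment is assigned
the mean local diameter over its own skeleton voxels; each foreground voxel
is assigned to the segment reached first by a multi-source breadth-first
propagation from all skeleton voxels through the mask (geodesically nearest
skeleton voxel - for voxels equidistant to two segments the tie is broken
by queue order, deterministically). Because every foreground voxel receives
exactly one segment, per-class V.Vf and V.Seg partition the totals exactly,
mirroring the column-consistency of the published group tables.

## Density distribution

Bone voxels of the averaged sub-edge volume are converted to d.HAp and
histogrammed in 8 mg/cm³ bins anchored at 500 mg/cm³ (the segmentation
floor), each bin expressed as percent of all bone voxels; mean and median
come from the raw per-voxel values and are consistent with the histogram to
half a bin. Group summaries average per-specimen histograms with equal
specimen weights (matching a mean ± SEM presentation); voxel-count-weighted
pooling is available via `pooled = TRUE`.

## Statistics

Group comparisons use the tie-corrected Kruskal-Wallis test followed by
Dunn's pairwise z tests on mean ranks, familywise-adjusted over all
k(k−1)/2 pairs. Bonferroni adjustment is the default - the exact correction
used with the commercial package behind the published analysis is not
documented, so the conservative standard choice is made explicit in the
output, with Holm available via a flag. Significance is two-sided at
α = 0.05; summaries are mean ± SEM. Within-group paired changes (body
weight) use the paired t test. Reporting arithmetic
(`percent_contrast`, `partition_check`) reproduces percent-smaller/larger
statements from group means and verifies that size-specific values sum to
their totals within rounding (0.02 percentage points for percent-scale
quantities, 1.0 /mm³ for densities).

## The synthetic phantom

No imaging data accompany the study the pipeline is designed around, so the
generator produces dual-energy specimens with exact ground truth under the
same imaging conditions: 2.74 µm cubic 8-bit voxels, a 720 x 300 µm
analysis cylinder, and a K-edge contrast jump only in the vessels.
Defaults, chosen once:

* **Vessels**: a forest of 6 random binary trees of tapering tubes (root
  diameter 48 µm, child diameter = parent x U(0.7, 0.95), mean edge 70 µm,
  branching half-angle ~32°, depth ≤ 5, minimum diameter 7 µm), confined to
  the ROI. Every internal vertex branches in two, so the number of
  generated edges is the ground-truth segment count. These defaults put
  V.Vf near 6-7% and V.Seg near 3 x 10³ /mm³ with all five diameter classes
  populated, the magnitudes typical of a well-perfused 10-day defect.
* **Contrast**: vessel attenuation 6 /cm below and 60 /cm above the edge
  (the agent's attenuation is not published; both are configurable), i.e.
  a difference of ~138 gray at the default scaling. Bone attenuation is
  identical at both energies, from its density via the calibration line:
  a cortical shell around the drill hole at 1364 mg/cm³ and
  regenerated-bone spheres (radius 12-25 µm) inside the defect at
  800 mg/cm³, placed to a target B.Vf of 28% while avoiding the vessels
  (overlapping vessel/bone labels are rejected, not resolved silently).
  Soft tissue/marrow is 0.8 /cm at both energies.
* **Degradations**: isotropic Gaussian blur of σ = 2.74 µm applied
  identically at both energies (partial volume), additive Gaussian noise of
  2 gray levels applied per acquisition after the geometry, clipping to
  [0, 255] and 8-bit quantization, and a rigid misalignment of the sub-edge
  volume (default 1.5, −2.5, 1.0 voxels and 0.3° axial) emulating the
  stage's return-to-origin error. Ground truth is untouched by all three.

The phantom emulates the contrast physics, partial volume, noise, and
misregistration - not reconstruction: no sinogram simulation, filtered back
projection artifacts, rings, beam hardening, phase contrast, or detector
afterglow, and no uneven vascular filling or irregular angiogenic vessel
contours. Noise is Gaussian, not Poisson. Recovery results on phantoms
therefore demonstrate the correctness of the measurement chain, not the
pipeline's robustness to every artifact of real synchrotron data.

`build_phantom(spec)` is bit-exact reproducible from `spec$seed`.
`truth_indices()` scores recovery analytically from the generating edges
(diameters and ROI-clipped lengths) for the vascular indices, and from the
truth masks via the same thickness/skeleton operators for bone.

## Numerical choices and problem sizes

All stages are deterministic given their inputs; the only randomness is the
phantom seed. Thresholding is global over the ROI (per-slice thresholds are
not used). Degenerate inputs fail loudly: constant volumes cannot be
thresholded, empty ROIs cannot normalize fractions, empty masks yield
missing (not zero) diameters. The test suite runs on reduced phantoms
(180-400 µm ROI cylinders) where every oracle can be brute-forced; the
acceptance script runs one full-size specimen (720 x 300 µm ROI, ~10^7
voxels) end to end, plus a clean 400 µm specimen for the noiseless
recovery bound. These sizes are the package's choice of test conditions;
the defaults of the generator itself always reflect the full imaging
geometry.

## Known limitations

* Thinning erodes the ends of thick tubes by about one radius, so skeleton
  length (and with it voxel-weighted V.D) slightly under-represents thick,
  short branches.
* On dense networks where tubes merge, the skeleton acquires junctions the
  generating tree does not have; segment counts then exceed the generative
  edge count. Ground-truth scoring is reliable for well-separated networks.
* The 2 x dt thickness convention over-measures one-voxel structures by one
  voxel width.
* Mutual information is evaluated on a subsample; pathological textures
  could in principle alias, though the phantom studies recover translations
  to ~0.1 voxel and rotations to ~0.2°.
* Blur before thresholding dilates bright structures; at the default blur
  and noise the segmented vascular volume overshoots ground truth by a few
  percentage points of V.Vf, vanishing as blur and noise go to zero.
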