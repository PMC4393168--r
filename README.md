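# kesct — K-edge subtraction micro-CT vascular and bone morphometry

`kesct` is an R package for analyzing dual-energy synchrotron micro-CT
scans of contrast-perfused bone specimens — the imaging setup used to
quantify angiogenesis and early bone regeneration in cortical drill-hole
defects. Specimens perfused with a zirconium-dioxide casting agent are
scanned just below (17.9 keV) and just above (18.1 keV) the agent's
K-absorption edge; only the contrast agent's attenuation jumps between the
two energies, so the registered difference image isolates the vasculature
while bone is quantified from the sub-edge scan alone. The package is
aimed at researchers doing 3D vascular/bone morphometry on such paired
volumes, and at methodologists who need a fully synthetic, ground-truthed
test bed for subtraction-CT pipelines.

## What it computes

For each specimen (two co-registered 8-bit stacks, 2.74 µm cubic voxels, a
cylindrical analysis region of 720 × 300 µm inside the defect):

* **Registration** — 6-parameter rigid alignment of the two energies by
  mutual-information maximization (deterministic grid + coordinate descent
  + simplex polish).
* **Segmentation** — bone regions of the 17.9 keV volume are expanded by a
  3×3×3 maximum filter, subtracted from the 18.1 keV volume, smoothed with
  3×3×3 averaging, and thresholded by exhaustive minimum cross-entropy
  (Li); extravascular voxels with attenuation µ ≥ 4.74 /cm are bone.
* **Calibration** — gray ↔ µ ↔ hydroxyapatite density via
  `d.HAp (mg/cm³) = 136·µ (/cm) − 142`; the bone threshold corresponds to
  d.HAp ≈ 500 mg/cm³.
* **Morphometry** — V.Vf, B.Vf (%), V.D (µm, mean over skeleton voxels of
  the largest-inscribed-sphere diameter), B.Th (µm, structure-weighted
  local thickness), V.Seg and B.Seg (/mm³, node-to-node or node-to-free-end
  skeleton segments), plus V.Vf and V.Seg per vessel diameter class
  (<10, 10–20, 20–30, 30–40, ≥40 µm) that partition the totals exactly.
* **Density** — relative bone-volume distribution versus d.HAp in
  8 mg/cm³ bins above 500 mg/cm³, with mean and median.
* **Statistics** — Kruskal–Wallis with Dunn's post hoc comparisons,
  paired t tests, mean ± SEM summaries, percent contrasts, and partition
  consistency checks.
* **Synthetic specimens** — `phantom_spec()` / `build_phantom()` generate
  dual-energy phantoms (tapering vessel trees, cortical shell, woven-bone
  blobs, blur, noise, inter-energy misalignment) with exact ground truth
  for every downstream stage.

## Worked example

A clean seven-branch vessel tree, built as a phantom and pushed through the
whole pipeline:

```r
library(kesct)

mk <- function(p1, p2, r) data.frame(p1x = p1[1], p1y = p1[2], p1z = p1[3],
  p2x = p2[1], p2y = p2[2], p2z = p2[3], radius_um = r, tree = 1L, edge = NA)
segs <- rbind(                                      # trunk, 2 children,
  mk(c(10, 150, 150), c(80, 150, 150), 12),         # 4 grandchildren
  mk(c(80, 150, 150), c(150, 100, 150), 9),
  mk(c(80, 150, 150), c(150, 200, 150), 9),
  mk(c(150, 100, 150), c(220, 70, 110), 6),
  mk(c(150, 100, 150), c(220, 70, 190), 6),
  mk(c(150, 200, 150), c(220, 230, 110), 6),
  mk(c(150, 200, 150), c(220, 230, 190), 6))
segs$edge <- 1:7

spec <- phantom_spec(roi_diameter_um = 290, roi_height_um = 230,
                     vessel_segments = segs, bone_regions = list(),
                     blur_sigma_um = 0, noise_sd_gray = 0,
                     misalignment = rigid_transform(), seed = 1)
ph  <- build_phantom(spec)
res <- run_specimen(ph$pair, roi = phantom_roi(spec), register = FALSE)
res
```

```
<specimen_result> specimen (Li threshold 53.67 gray)
<morphometry_result>
  V.Vf   0.78 %   V.D   15.63 um   V.Seg    460.1 /mm^3
  B.Vf   0.00 %   B.Th     NA um   B.Seg      0.0 /mm^3
  ROI volume: 0.0152 mm^3
  size-specific:
   bin   vvf_pct seg_per_mm3
   <10 0.0000000     0.00000
 10-20 0.5915872   394.40303
 20-30 0.1849809    65.73384
 30-40 0.0000000     0.00000
   >40 0.0000000     0.00000
```

The Li threshold (53.67 gray) sits between the background of the clamped
difference image and the ~138-gray K-edge jump of the vessels. The seven
segment rows recover the seven generated tree edges
(`460.1 /mm³ × 0.0152 mm³ = 7`), split between the 10–20 µm class (the
12 µm and 18 µm branches) and the 20–30 µm class (the 24 µm trunk), and the
per-class values sum exactly to the totals. Against the analytic ground
truth (`truth_indices(ph$truth)`: V.Vf 0.72 %, V.D 15.19 µm, 7 segments)
the recovered V.Vf is within 0.06 percentage points and V.D within half a
micrometer.

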