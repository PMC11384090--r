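---
title: "Shape-independent standardized mapping of vertebral bone-marrow PDFF: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-independent standardized mapping of vertebral bone-marrow PDFF: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertemap)
```

## The problem

The proton-density fat fraction (PDFF) of vertebral bone marrow is a
quantitative MRI biomarker of marrow composition, sensitive to aging,
metabolic and hematological disease, and therapy. Chemical-shift-encoded
(Dixon) acquisitions deliver PDFF as a voxel-wise percentage over the whole
lumbar spine, and segmentation of the vertebral bodies (typically by a deep
3D U-Net, consumed here as an input label volume) allows volumetric
statistics per vertebra. What volumetric statistics cannot deliver is a
*spatially resolved, interindividually comparable* picture: vertebral bodies
differ in size and shape within and across subjects, so voxel-wise
comparison of distribution patterns is ill-posed.

`vertemap` addresses this by registering every vertebral body onto a common
**standardized elliptical cylinder** and reading off three perpendicular
mid-plane PDFF distribution maps (mid-transverse, mid-sagittal,
mid-coronal). On the template, pixel *(i, j)* means the same relative
anatomical position in every vertebra of every subject.

## The template mapping

The template transverse section is an ellipse sampled with `nMajor = 20`
points on the major (horizontal) semi-axis and `nMinor = 16` points on the
minor (dorsoventral) semi-axis; the longitudinal axis carries
`nLong = 20` sampling points. We use symmetric odd grids of
`2*nMajor + 1 = 41` columns and `2*nMinor + 1 = 33` rows: counting sampling
points *per semi-axis* leaves the total grid ambiguous, and the odd grid is
the unique choice that contains the centre and both semi-axis endpoints as
grid nodes and is mirror-symmetric about both axes. All three counts are
configurable through `templateGeometry()`.

Mapping one axial slice (`mapTransverseSlice()`) is a three-step,
extent-based linear interpolation:

1. every image row that intersects the mask is resampled along the
   horizontal axis so that the first and last *masked* voxels map to the
   first and last of 41 samples;
2. the stacked rows are resampled column-wise along the dorsoventral axis to
   33 rows, using the true (possibly non-uniform) row positions;
3. each template row *j* is resampled from 41 samples down to the elliptical
   chord width of that row — the number of template nodes with
   `(i/20)^2 + (j/16)^2 <= 1` — and placed centred. Nodes outside the
   ellipse are invalid (`NA`), giving the map an elliptical footprint rather
   than a masked rectangle.

For an elliptical cross-section this composition recovers normalized body
coordinates: template node *(i, j)* lands at `(u, v) = (i/20, j/16)` of the
body, up to voxelization. That is the formal reason the mapping is
shape-independent, and it is what the phantom tests verify (maps of bodies
scaled by 0.7–1.3 with identical normalized fields agree within 2 % PDFF).

The mid-sagittal and mid-coronal maps are built analogously: at the
centre-of-mass plane index, each axial slice's masked run is resampled to 33
(sagittal) or 41 (coronal) samples, and the resulting slice stack is
resampled head–feet to 20 rows. Maps are oriented with the superior end in
the first row.

Details that matter:

* **Mid-plane selection.** The plane index is the voxel nearest the
  unweighted mask centroid; exact `.5` ties resolve to the
  inferior/posterior/left side.
* **Concavities.** Within a row, the run from first to last masked voxel is
  used and interior unmasked gaps are linearly interpolated *from the masked
  values* — background is never sampled. Vertebral bodies are convex at
  slice scale, so gaps are rare and shallow.
* **Missing slices.** Axial slices with no mask at the required plane index
  are excluded before longitudinal resampling, never zero-filled. Masks
  thinner than two usable slices are an error.
* **Degenerate runs.** A single-voxel run broadcasts its value; a request
  for a single output sample returns the run midpoint.

Because every output pixel is a convex combination of masked PDFF values,
the map minimum can only be **at or above** the volumetric minimum and the
map maximum at or below the volumetric maximum, on any input. The smoothing
of the distribution tails — in vivo visible as an overestimated minimum and
underestimated SD on the maps — is thus a theorem of the method, not an
artefact of particular data, and the test suite asserts it on every phantom
it builds.

### Pooled map statistics and their bias

Map statistics (`mapStats()`) are reported per plane and pooled over the
valid pixels of all three planes; the pooled variant is the default for
cohort summaries. The pooled mean is *not* an unbiased estimate of the
volumetric mean for radially structured fields: the longitudinal maps sample
the central planes `u = 0` and `v = 0`, where the expectation of `v^2` over
the template rows is 1/3, whereas the volumetric expectation of `u^2 + v^2`
over an elliptical cross-section is 1/2 (rising towards 2/3 as the
superellipse exponent increases). For a field with radial coefficient *r*
the pooled-map mean is therefore biased by about `-0.11 r` relative to the
volumetric mean (negative for peripherally elevated fat, the usual in vivo
pattern). The package records the signed difference, and its Bland–Altman
convention (`maps - volumetric`) makes this appear as the familiar low
negative bias. Consequently, the mean-agreement test suite defines "smooth"
fields as elliptical bodies with gradients within ±6 %/unit and radial
amplitudes up to 2 %, for which the derived bias bound plus the ±0.3 %
mid-plane discretization scatter at 3 mm sections stays within 0.5 % PDFF.

## Inclination estimation and correction

Vertebral bodies are tilted with respect to the horizontal plane; to make
the mid-transverse plane anatomically axial, each body is rotated about the
horizontal axis through its centre of mass before mapping.

The angle is estimated from the **inferior edge of the mid-sagittal mask
slice**: for every dorsoventral column containing mask, the most inferior
masked voxel centre is taken (in mm, respecting anisotropic spacing), and a
straight-line Hough transform is run over an angle grid (default ±30° in
0.5° steps). Two numerical choices depart from the textbook accumulator:

* **Sliding offset window.** For each candidate angle, points are projected
  onto the line-normal axis and the vote count is the maximum number of
  points inside a sliding window (default 1.1× the longitudinal spacing)
  rather than a fixed-phase histogram bin, removing bin-alignment artefacts.
* **Plateau median.** Slice quantization turns the inferior edge into a
  staircase, and the set of angles achieving the maximum vote count is a
  plateau that brackets the true inclination. Returning the plateau median
  centres the estimate; breaking ties towards the smallest |angle| instead
  would bias small tilts towards zero by several degrees.

Positive angles mean the ventral (anterior) end points inferiorly; the
convention is used consistently by the estimator, the phantom generator and
the rotation, which applies `-angle`.

**Precision is resolution-limited.** With 3 mm sections, a 5° tilt drops the
inferior edge by only ~2 mm across a typical 24 mm body — less than one
slice — and a single-step staircase genuinely underdetermines the slope: no
estimator can recover such angles to better than ~±3°. The angle-recovery
tests therefore characterize the estimator on phantoms with 1.2 mm
isotropic voxels (≥ 2 quantization periods at the smallest tested angle),
where the sweep over ±20° is recovered to ≤ 0.5° and closed-loop correction
leaves ≤ 1° residual. At clinical 3 mm sections, users should expect
reliable correction of moderate-to-large tilts and noisy estimates below
about 5°; estimates from fewer than 5 edge points are flagged invalid and
no correction is applied.

Rotation (`rotateVertebra()`) is performed per vertebra in mm space with the
output grid padded so no masked voxel is lost. The mask is resampled nearest
neighbour (preserving label crispness), the scalar with **mask-aware
bilinear interpolation**: bilinear weights are restricted to masked source
voxels and renormalized. Plain bilinear interpolation would blend the 0 %
background into boundary voxels, which both depresses boundary PDFF and
breaks the min/max-bound theorem for corrected maps; with mask-aware
weights every rotated masked value remains a convex combination of masked
PDFF values.

## Statistics

* **SD convention.** Sample SD (n−1) everywhere, for both volumetric and
  map statistics, so inhomogeneity measures are directly comparable.
* **Segmentation evaluation.** `confusionMetrics()` reports the class-wise
  confusion counts and all derived rates (accuracy, DSC, Jaccard,
  precision/recall, TNR/NPV, FDR/FNR/FPR/FOR) plus absolute and relative
  volumetric error; the relative error is taken against the ground-truth
  volume and flagged `NA` when the truth is empty. The algebraic identities
  (precision + FDR = 1, DSC = 2J/(1+J), ...) are asserted against
  brute-force enumeration in the test suite.
* **Agreement.** `blandAltman()` takes differences as `maps − volumetric`.
* **Group tests.** `compareGroups()` gates on Shapiro–Wilk normality of
  both samples at the same α (default 0.05): Welch's t-test if both pass,
  two-sided Mann–Whitney U otherwise; constant samples (normality
  undefined) fall back to Mann–Whitney. Under the null with two normal
  samples of n = 15 the composite procedure holds its nominal 5 % size
  (calibrated over 2000 seeded replicates in the tests). No
  multiple-testing correction is applied across vertebral levels; raw
  p-values are reported.

## The phantom generator

All testing runs on synthetic phantoms with analytic ground truth
(`generatePhantom()`, `cohortFixture()`). A phantom vertebra is a
superellipse cylinder `|x/a|^n + |y/b|^n <= 1`, `|z| <= h/2`, optionally
tilted about the horizontal axis, carrying the field
`base + g·(u,v,w) + r(u² + v²)` on normalized pre-tilt body coordinates —
so the expected standardized map is the field itself, independent of (a, b,
h) and tilt, which is exactly the property under test. Additive Gaussian
noise on PDFF is seeded and reproducible; vertebrae are stacked by nominal
height bands so that strongly tilted neighbours across a small gap collide
and raise an explicit construction error.

Default conditions mirror a typical lumbar protocol: voxels 1.2 × 1.2 ×
3 mm, semi-axes 13–18 / 9–14 mm, heights 25–32 mm (volumes roughly 10–25
ml), inclinations up to 12°, baselines 30–42 %, gradients up to 12 %/unit,
radial amplitudes up to 12 % and noise 2.5–4 %, giving per-vertebra SDs of
roughly 4–11 % and maxima of roughly 50–90 %. What the phantom does *not*
emulate — trabecular texture, T2*/field inhomogeneity, Rician noise, spine
curvature, realistic surrounding tissue (background is a constant 0 % so
leakage bugs depress means detectably) — bounds what passing tests show: the
geometry, interpolation and statistics of the method are verified, not its
interaction with MR physics or real segmentation errors.

Problem sizes in the test and acceptance suites are desk-scale by design:
single-vertebra phantoms of ~40×30×15 voxels, five-vertebra subjects of
~10⁵ voxels, cohorts of 4–8 subjects, 200 random mask pairs for the metric
oracle and 2000 replicates for the calibration check.

## Axis and storage conventions

Internal arrays are indexed (x, y, z) = (horizontal left→right,
dorsoventral posterior→anterior, longitudinal feet→head), matching NIfTI's
native axis order and R's column-major layout; NIfTI input is reoriented to
this convention from its orientation metadata (files without any orientation
metadata are rejected with instructions rather than guessed). Values outside
[0, 100] % are clipped with a reported count. Oblique acquisitions are
mapped to the nearest axis-aligned orientation with a prominent warning;
truly oblique geometry is out of scope. The default on-disk label coding
1→L1 … 5→L5 is a convention, overridable wherever labels are read.

## Known limitations

* Angular precision at clinical slice thickness is quantization-limited
  (see above); only the sagittal-plane inclination is corrected, not
  lateral tilt or axial rotation.
* The elliptical template is a model: strongly concave or fractured
  vertebral bodies (e.g. severe crush deformities) violate the convex-extent
  assumption of the row resampling.
* Pooled map means carry the derived radial bias relative to volumetric
  means; comparisons should either use the volumetric mean or compare map
  means with map means.
* The package consumes segmentations; it neither trains nor runs a
  segmentation model, and no claim is made about segmentation quality
  beyond the evaluation metrics it computes.
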