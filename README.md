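# vertemap

Shape-independent, standardized assessment of the spatial distribution of
proton-density fat fraction (PDFF) in lumbar vertebral bone marrow.

Vertebral bone-marrow PDFF from chemical-shift-encoded MRI is a quantitative
biomarker of marrow composition, but vertebral bodies vary in size and shape
within and between subjects, so voxel-wise comparison of *distribution
patterns* is ill-posed. `vertemap` registers each segmented vertebral body
onto a standardized elliptical cylinder and derives three perpendicular
mid-plane PDFF distribution maps, so that a template pixel means the same
relative anatomical position in every vertebra of every subject. It is
aimed at researchers quantifying marrow fat from Dixon PDFF maps plus a
vertebral-body segmentation (e.g. from a 3D U-Net).

## Method

For each vertebra with mask `M` and PDFF volume `F`:

1. **Inclination correction.** The inferior edge of the mid-sagittal slice
   of `M` is extracted (most inferior masked pixel per dorsoventral column,
   in mm) and its angle θ against the horizontal plane is estimated by a
   straight-line Hough transform over ±30° (0.5° steps). The ROI is rotated
   by −θ about the horizontal axis through the mask centre of mass (scalar:
   mask-aware bilinear resampling; mask: nearest neighbour).
2. **Template mapping.** The elliptical template samples n_a = 20 points on
   the major (horizontal) and n_b = 16 points on the minor (dorsoventral)
   semi-axis, and n_l = 20 points along the longitudinal axis, on symmetric
   odd grids (41 × 33 transverse, validity
   `(i/n_a)² + (j/n_b)² ≤ 1`). Each mid-plane map is produced by
   extent-based linear interpolation: row-wise along the horizontal axis,
   column-wise along the dorsoventral axis, then per-row resampling to the
   elliptical chord widths (transverse 33 × 41; sagittal and coronal
   n_l × 33 and n_l × 41 via head–feet resampling of the slice stack).
3. **Quantification.** Mean / min / max / sample SD of PDFF over all masked
   voxels (volumetric) and over the valid template pixels (per plane and
   pooled); SD is the inhomogeneity measure. Because map pixels are convex
   combinations of masked voxel values, map min ≥ volumetric min and map
   max ≤ volumetric max on any input.

Supporting statistics: class-wise confusion-matrix metrics (DSC, Jaccard,
precision/recall, FDR/FNR/FPR/FOR, NPV/TNR, volumetric error) for
segmentation evaluation, Bland–Altman agreement (differences taken as
maps − volumetric), and normality-gated two-sample tests (Shapiro–Wilk at
α = 0.05 selecting Welch's t-test or Mann–Whitney U). A superellipse
phantom generator with analytic ground-truth fields on normalized body
coordinates replaces scanner data in all tests.

## Worked example

```r
library(vertemap)

# a tilted synthetic vertebra: 16 x 12 mm semi-axes, 30 mm high, 15 deg
# inclination, PDFF field 38% + gradient + radial term, 3% noise
ph <- generatePhantom(phantomSpec(
  vertebraSpec(16, 12, 30, exponent = 3, inclinationDeg = 15,
               field = fieldSpec(38, c(3, -2, 6), 4)),
  noiseSd = 3, seed = 7, gapMm = 8))

roi <- extractVertebraROI(ph$scalar, ph$labels, 1)
estimateInclination(detectInferiorEdge(roi))
#> Inclination estimate: 14.50 deg (valid, 20 votes from 26 edge points)

volumetricStats(roi)
#> PDFF stats (volumetric, n = 4745): mean 40.28, min 25.11, max 57.23, SD 5.14 %

maps <- buildStandardizedMaps(roi, correctInclination = TRUE)
mapStats(maps)$pooled
#> PDFF stats (maps_pooled, n = 2473): mean 39.35, min 29.75, max 56.30, SD 3.63 %
```

The Hough estimate recovers the 15° tilt to half the 0.5° grid step at this
resolution. The pooled map statistics show the characteristic smoothing of
the standardization: the mean is preserved to ~1 %, while the minimum is
raised and the SD reduced relative to the volumetric assessment — the maps
trade tail fidelity for spatial comparability. `writeMapsPNG(maps, "L1")`
renders the three maps with transparent background outside the elliptical
footprint.

For whole subjects and cohorts, `runSubject()` and `runCohort()` produce
per-vertebra CSV tables (volumetric, pooled and per-plane statistics, with
and without inclination correction), segmentation metrics against an
optional ground truth, group summaries ordered L5→L1, pairwise group tests
and the maps-vs-volumetric Bland–Altman agreement. A thin CLI wrapping
these lives at `inst/scripts/vertemap` (subcommands `run`, `phantom`,
`cohort`).

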