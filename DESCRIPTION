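Package: vertemap
Title: Shape-Independent Standardized Mapping of Vertebral Bone-Marrow Fat Fraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for standardized, shape-independent assessment of the
    spatial distribution of proton-density fat fraction (PDFF) in lumbar
    vertebral bone marrow from quantitative chemical-shift-encoded MRI.
    Segmented vertebral bodies are corrected for their inclination with
    respect to the horizontal plane using a Hough transform of the
    mid-sagittal segmentation edge, then mapped onto a standardized
    elliptical-cylinder template by slice-wise linear interpolation,
    yielding mid-transverse, mid-sagittal and mid-coronal PDFF
    distribution maps that are directly comparable across vertebrae and
    subjects. Includes volumetric and map-based PDFF statistics,
    segmentation-evaluation metrics of the class-wise confusion matrix,
    Bland-Altman agreement analysis, normality-gated two-sample tests,
    a synthetic vertebra phantom generator with analytic ground truth,
    and a pipeline for single subjects and cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    RNifti,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
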