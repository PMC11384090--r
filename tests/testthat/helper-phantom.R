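# Shared fixture builders: all phantoms are generated in code at test time.

# Single-vertebra phantom ROI with the given geometry and field.
singleVertebraROI <- function(a = 15, b = 11, h = 30, n = 2.5, tilt = 0,
                              field = fieldSpec(40), spacing = c(1.2, 1.2, 3),
                              noiseSd = 0, seed = NULL, gapMm = 8) {
  ph <- generatePhantom(phantomSpec(
    vertebraSpec(a, b, h, exponent = n, inclinationDeg = tilt, field = field),
    spacing = spacing, noiseSd = noiseSd, seed = seed, gapMm = gapMm))
  extractVertebraROI(ph$scalar, ph$labels, 1L)
}

# Five-vertebra uniform phantom volume pair.
uniformPhantom <- function(base = 40, spacing = c(1.2, 1.2, 3)) {
  verts <- lapply(1:5, function(k)
    vertebraSpec(15, 11, 28, exponent = 2.5, field = fieldSpec(base)))
  generatePhantom(phantomSpec(verts, spacing = spacing))
}

# Random smooth (linear + radial, noiseless) field spec; the admissible
# curvature derives from the pooled-map bias model (see methods vignette):
# elliptical bodies, gradients within +-6 %/unit, radial amplitude <= 2 %.
randomSmoothROI <- function() {
  fld <- fieldSpec(runif(1, 25, 40), runif(3, -6, 6), runif(1, 0, 2))
  singleVertebraROI(a = runif(1, 13, 18), b = runif(1, 9, 14),
                    h = runif(1, 25, 32), n = 2, field = fld)
}

# Unweighted mask centroid (1-based voxel coordinates).
maskCentroid2 <- function(mask) colMeans(which(mask, arr.ind = TRUE))

# Independent brute-force confusion counts via cross-tabulation.
bruteForceConfusion <- function(pred, truth) {
  tab <- table(factor(as.vector(pred), levels = c(FALSE, TRUE)),
               factor(as.vector(truth), levels = c(FALSE, TRUE)))
  list(tp = tab["TRUE", "TRUE"], fp = tab["TRUE", "FALSE"],
       fn = tab["FALSE", "TRUE"], tn = tab["FALSE", "FALSE"])
}
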