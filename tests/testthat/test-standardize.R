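test_that("template geometry has the documented structure", {
  geom <- templateGeometry()
  msk <- templateMask(geom)
  expect_equal(dim(msk), c(33L, 41L))
  # exact centred ellipse in index coordinates
  expected <- outer((-16:16) / 16, (-20:20) / 20,
                    function(q, p) p^2 + q^2 <= 1 + 1e-12)
  expect_identical(msk, expected)
  # symmetric under both mirrors
  expect_identical(msk, msk[33:1, ])
  expect_identical(msk, msk[, 41:1])
  expect_error(templateGeometry(1, 16, 20), ">= 2")
})

test_that("masked-run resampling matches its closed form", {
  expect_equal(resampleMaskedRun(c(10, 20, 30), 5), c(10, 15, 20, 25, 30))
  expect_equal(resampleMaskedRun(rep(7, 4), 9), rep(7, 9))
  expect_equal(resampleMaskedRun(c(0, 100), 41), seq(0, 100, by = 2.5))
  expect_equal(resampleMaskedRun(5, 4), rep(5, 4))   # single sample broadcasts
  expect_error(resampleMaskedRun(numeric(0), 5), "empty run")
})

test_that("a uniform slice maps to a uniform elliptical template", {
  geom <- templateGeometry()
  slice <- matrix(40, 30, 24)
  mask <- matrix(FALSE, 30, 24)
  xs <- ((1:30) - 15.5) / 12
  ys <- ((1:24) - 12.5) / 9
  mask[outer(xs^2, ys^2, "+") <= 1] <- TRUE
  out <- mapTransverseSlice(slice, mask, geom)
  expect_identical(is.na(out), !templateMask(geom))
  expect_true(all(out[!is.na(out)] == 40))
  expect_error(mapTransverseSlice(slice, mask & FALSE, geom), "empty")
})

test_that("a radially symmetric field maps symmetrically under both mirror axes", {
  geom <- templateGeometry()
  nx <- 41; ny <- 31
  xs <- ((1:nx) - (nx + 1) / 2) / 17
  ys <- ((1:ny) - (ny + 1) / 2) / 12
  r2 <- outer(xs^2, ys^2, "+")
  mask <- r2 <= 1
  slice <- 40 + 10 * r2
  out <- mapTransverseSlice(slice, mask, geom)
  flipH <- out[, ncol(out):1]
  flipV <- out[nrow(out):1, ]
  expect_lt(max(abs(out - flipH), na.rm = TRUE), 0.5)
  expect_lt(max(abs(out - flipV), na.rm = TRUE), 0.5)
})

test_that("two ellipses with the same normalized field map to the same template", {
  geom <- templateGeometry()
  mkSlice <- function(a, b, spacing = 1) {
    nx <- ceiling(2 * a / spacing) + 4
    ny <- ceiling(2 * b / spacing) + 4
    xs <- ((1:nx) - (nx + 1) / 2) * spacing / a
    ys <- ((1:ny) - (ny + 1) / 2) * spacing / b
    mask <- outer(xs^2, ys^2, "+") <= 1
    u <- matrix(xs, nx, ny)
    v <- matrix(ys, nx, ny, byrow = TRUE)
    list(slice = 35 + 5 * u - 4 * v + 3 * (u^2 + v^2), mask = mask)
  }
  s1 <- mkSlice(15, 10)
  s2 <- mkSlice(21, 14)
  m1 <- mapTransverseSlice(s1$slice, s1$mask, geom)
  m2 <- mapTransverseSlice(s2$slice, s2$mask, geom)
  expect_lt(max(abs(m1 - m2), na.rm = TRUE), 2)
})

test_that("standardized maps have the documented dimensions", {
  roi <- singleVertebraROI()
  maps <- buildStandardizedMaps(roi)
  expect_equal(dim(distributionMap(maps, "transverse")), c(33L, 41L))
  expect_equal(dim(distributionMap(maps, "sagittal")), c(20L, 33L))
  expect_equal(dim(distributionMap(maps, "coronal")), c(20L, 41L))
})

test_that("an untilted uniform phantom yields uniform maps in every plane", {
  roi <- singleVertebraROI(field = fieldSpec(40))
  maps <- buildStandardizedMaps(roi)
  for (pl in c("transverse", "sagittal", "coronal")) {
    m <- distributionMap(maps, pl)
    expect_true(all(m[is.finite(m)] == 40), label = pl)
  }
})

test_that("a longitudinal gradient appears as a linear ramp in the coronal map", {
  g <- 8
  roi <- singleVertebraROI(a = 16, b = 12, h = 30, n = 2,
                           field = fieldSpec(40, c(0, 0, g)),
                           spacing = c(1.2, 1.2, 1.5))
  maps <- buildStandardizedMaps(roi)
  colMeansCor <- rowMeans(distributionMap(maps, "coronal"))
  span <- colMeansCor[1] - colMeansCor[length(colMeansCor)]
  # rows run superior to inferior, so the span is +2g minus half-voxel ends
  expect_lt(abs(span - 2 * g), 0.5 + 2 * g * 1.5 / 30)
  resid <- lm(colMeansCor ~ seq_along(colMeansCor))$residuals
  expect_lt(max(abs(resid)), 0.5)
})

test_that("maps are invariant to in-plane resolution (scale invariance)", {
  fld <- fieldSpec(35, c(5, -4, 6), 2)
  m1 <- buildStandardizedMaps(singleVertebraROI(n = 2.5, field = fld,
                                                spacing = c(1.2, 1.2, 3)))
  m2 <- buildStandardizedMaps(singleVertebraROI(n = 2.5, field = fld,
                                                spacing = c(0.6, 0.6, 3)))
  for (pl in c("transverse", "sagittal", "coronal"))
    expect_lt(max(abs(distributionMap(m1, pl) - distributionMap(m2, pl)),
                  na.rm = TRUE), 1)
})

test_that("vertebrae differing only by isotropic scale yield matching maps", {
  fld <- fieldSpec(35, c(5, -4, 8), 4)
  maps <- lapply(c(0.7, 1, 1.3), function(s)
    buildStandardizedMaps(singleVertebraROI(a = 15 * s, b = 11 * s,
                                            h = 30 * s, n = 2.5,
                                            field = fld)))
  for (pl in c("transverse", "sagittal", "coronal")) {
    ref <- distributionMap(maps[[2]], pl)
    expect_lt(max(abs(distributionMap(maps[[1]], pl) - ref), na.rm = TRUE), 2)
    expect_lt(max(abs(distributionMap(maps[[3]], pl) - ref), na.rm = TRUE), 2)
  }
})

test_that("map extrema are bounded by volumetric extrema (smoothing theorem)", {
  set.seed(31)
  for (rep in 1:5) {
    roi <- singleVertebraROI(a = runif(1, 13, 18), b = runif(1, 9, 14),
                             h = runif(1, 25, 32), n = runif(1, 2, 4),
                             field = fieldSpec(runif(1, 30, 42),
                                               runif(3, -6, 6),
                                               runif(1, 0, 10)),
                             noiseSd = 3, seed = rep)
    vs <- volumetricStats(roi)
    ms <- mapStats(buildStandardizedMaps(roi))$pooled
    expect_gte(ms$min, vs$min)
    expect_lte(ms$max, vs$max)
  }
})

test_that("the smoothing bounds survive inclination correction of tilted bodies", {
  for (th in c(-12, 15)) {
    roi <- singleVertebraROI(a = 16, b = 12, h = 30, n = 3, tilt = th,
                             field = fieldSpec(38, c(3, -2, 6), 4),
                             noiseSd = 3, seed = 17)
    vs <- volumetricStats(roi)
    ms <- mapStats(buildStandardizedMaps(roi, correctInclination = TRUE))$pooled
    expect_gte(ms$min, vs$min)
    expect_lte(ms$max, vs$max)
  }
})

test_that("masks thinner than two slices cannot produce longitudinal maps", {
  d <- c(15, 15, 5)
  mask <- array(FALSE, d)
  mask[4:12, 4:12, 3] <- TRUE
  roi <- new("VertebraROI", scalar = array(40, d), mask = mask,
             spacing = c(1, 1, 3), com = maskCentroid2(mask),
             labelName = "L1")
  expect_error(buildStandardizedMaps(roi), "thinner than 2")
})
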