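test_that("volumetric statistics match hand computation and a brute-force oracle", {
  d <- c(3, 3, 3)
  mask <- array(FALSE, d)
  mask[1:3, 1, 1] <- TRUE
  sc <- array(0, d)
  sc[1:3, 1, 1] <- c(10, 20, 30)
  roi <- new("VertebraROI", scalar = sc, mask = mask, spacing = c(1, 1, 1),
             com = maskCentroid2(mask), labelName = "L1")
  st <- volumetricStats(roi)
  expect_equal(st$mean, 20)
  expect_equal(st$min, 10)
  expect_equal(st$max, 30)
  expect_equal(st$sd, 10)            # sample SD convention
  expect_equal(st$n, 3L)

  roiR <- singleVertebraROI(field = fieldSpec(38, c(4, -3, 5), 6),
                            noiseSd = 4, seed = 9)
  stR <- volumetricStats(roiR)
  vals <- numeric(0)                 # explicit voxel loop as oracle
  for (i in which(maskData(roiR)))
    vals <- c(vals, voxelData(roiR)[i])
  expect_identical(stR$mean, mean(vals))
  expect_identical(stR$sd, sd(vals))
  expect_identical(stR$min, min(vals))
})

test_that("uniform phantom statistics are exact", {
  roi <- singleVertebraROI(field = fieldSpec(40))
  st <- volumetricStats(roi)
  expect_identical(st$mean, 40)
  expect_identical(st$sd, 0)
  ms <- mapStats(buildStandardizedMaps(roi))
  expect_identical(ms$pooled$mean, 40)
  expect_identical(ms$pooled$sd, 0)
})

test_that("pooled map statistics aggregate the per-plane pixel counts", {
  roi <- singleVertebraROI(field = fieldSpec(38, c(4, -3, 5), 3))
  ms <- mapStats(buildStandardizedMaps(roi))
  expect_equal(ms$pooled$n, sum(vapply(ms$perPlane, `[[`, 0L, "n")))
  expect_equal(ms$perPlane$transverse$n, sum(templateMask(templateGeometry())))
})

test_that("confusion metrics match brute-force enumeration and the shifted-cube example", {
  truth <- array(FALSE, c(10, 10, 10))
  truth[4:6, 4:6, 4:6] <- TRUE
  pred <- array(FALSE, c(10, 10, 10))
  pred[5:7, 4:6, 4:6] <- TRUE
  cm <- confusionMetrics(pred, truth, voxelVolumeMl = 0.001)
  expect_equal(cm$tp, 18)
  expect_equal(cm$fp, 9)
  expect_equal(cm$fn, 9)
  expect_equal(cm$dsc, 36 / 54)
  expect_equal(cm$jaccard, 0.5)
  expect_equal(cm$absVolErrorMl, 0)

  ident <- confusionMetrics(truth, truth, 0.001)
  expect_equal(ident$dsc, 1)
  expect_equal(ident$fdr, 0)
  disjoint <- array(FALSE, c(10, 10, 10)); disjoint[1, 1, 1] <- TRUE
  expect_equal(confusionMetrics(disjoint, truth, 0.001)$dsc, 0)
})

test_that("confusion-metric identities hold on random mask pairs", {
  set.seed(77)
  for (rep in 1:40) {
    pred <- array(runif(8^3) < runif(1, 0.1, 0.6), c(8, 8, 8))
    truth <- array(runif(8^3) < runif(1, 0.1, 0.6), c(8, 8, 8))
    cm <- confusionMetrics(pred, truth, 0.004)
    bf <- bruteForceConfusion(pred, truth)
    expect_equal(cm$tp, unname(bf$tp))
    expect_equal(cm$tn, unname(bf$tn))
    expect_equal(cm$precision + cm$fdr, 1)
    expect_equal(cm$recall + cm$fnr, 1)
    expect_equal(cm$tnr + cm$fpr, 1)
    expect_equal(cm$npv + cm$forate, 1)
    expect_equal(cm$dsc, 2 * cm$jaccard / (1 + cm$jaccard))
  }
})

test_that("relative volumetric error is undefined for an empty truth", {
  pred <- array(FALSE, c(3, 3, 3)); pred[1, 1, 1] <- TRUE
  cm <- confusionMetrics(pred, array(FALSE, c(3, 3, 3)), 0.001)
  expect_true(is.na(cm$relVolErrorPercent))
})

test_that("Bland-Altman matches its closed form", {
  ba <- blandAltman(c(10, 20, 30), c(8.5, 18.5, 28.5))
  expect_equal(ba$bias, -1.5)
  expect_equal(ba$sdDiff, 0)
  expect_equal(ba$loaLow, -1.5)
  expect_equal(ba$loaHigh, -1.5)

  ba2 <- blandAltman(c(0, 10), c(0, 8))
  expect_equal(ba2$bias, -1)
  expect_equal(ba2$sdDiff, sqrt(2))
  expect_equal(ba2$loaLow, -1 - 1.96 * sqrt(2))
  expect_equal(ba2$loaHigh, -1 + 1.96 * sqrt(2))

  x <- c(3, 7, 12, 20)
  ba3 <- blandAltman(x, x)
  expect_equal(ba3$bias, 0)
  expect_equal(ba3$loaHigh - ba3$loaLow, 0)
  expect_error(blandAltman(1, 2), "2 pairs")
})

test_that("group comparison selects the test by normality and detects separation", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.5, 6.1, 7.9, 8.2)
  same <- compareGroups(x, x)
  expect_gt(same$pValue, 0.9)
  expect_false(same$significant)

  set.seed(21)
  sep <- compareGroups(rnorm(50), rnorm(50) + 5)
  expect_true(sep$significant)

  set.seed(22)
  skewed <- compareGroups(rexp(30)^2, rexp(30)^2)
  expect_equal(skewed$testName, "mann_whitney_u")

  const <- compareGroups(rep(5, 10), rep(5, 10))
  expect_equal(const$testName, "mann_whitney_u")
})
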