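test_that("ROI extraction centres the mask and enforces label presence", {
  arr <- array(50, c(20, 20, 20))
  lab <- array(0L, c(20, 20, 20))
  lab[6:15, 6:15, 6:15] <- 1L
  sv <- scalarVolume(arr, c(1, 1, 1))
  lv <- labelVolume(lab, defaultLabelMap(), c(1, 1, 1))
  roi <- extractVertebraROI(sv, lv, 1L)
  expect_equal(unname(comVoxel(roi)), dim(maskData(roi)) / 2 + 0.5,
               tolerance = 1e-12)
  expect_error(extractVertebraROI(sv, lv, 3L), "not present")
})

test_that("only the largest connected component of a fragmented label is kept", {
  arr <- array(50, c(20, 20, 20))
  lab <- array(0L, c(20, 20, 20))
  lab[3:10, 3:10, 3:10] <- 1L        # 512 voxels
  lab[15:16, 15:16, 15:16] <- 1L     # 8 voxels, disconnected
  sv <- scalarVolume(arr, c(1, 1, 1))
  lv <- labelVolume(lab, defaultLabelMap(), c(1, 1, 1))
  expect_warning(roi <- extractVertebraROI(sv, lv, 1L), "largest")
  expect_equal(sum(maskData(roi)), 512L)
})

test_that("the inferior edge of an axis-aligned box is collinear at constant z", {
  arr <- array(40, c(11, 11, 11))
  mask <- array(FALSE, c(11, 11, 11))
  mask[3:9, 3:9, 4:8] <- TRUE
  roi <- new("VertebraROI", scalar = arr, mask = mask,
             spacing = c(1.2, 1.2, 3), com = maskCentroid2(mask),
             labelName = "L1")
  pts <- detectInferiorEdge(roi)
  expect_equal(nrow(pts), 7L)
  expect_equal(unname(diff(range(pts[, "z_mm"]))), 0)
})

test_that("a sheared box yields edge points on a line of slope dz/dy", {
  d <- c(11, 10, 16)
  mask <- array(FALSE, d)
  for (j in 1:8) mask[3:9, j + 1, (2 + j):(7 + j)] <- TRUE
  roi <- new("VertebraROI", scalar = array(40, d), mask = mask,
             spacing = c(1.2, 1.5, 3), com = maskCentroid2(mask),
             labelName = "L1")
  pts <- detectInferiorEdge(roi)
  slopes <- diff(pts[, "z_mm"]) / diff(pts[, "y_mm"])
  expect_equal(unname(slopes), rep(3 / 1.5, length(slopes)))
})

test_that("degenerate edges are flagged invalid with zero angle", {
  est <- estimateInclination(cbind(y_mm = c(1, 2), z_mm = c(0, 0)))
  expect_false(est$valid)
  expect_equal(est$angleDeg, 0)

  d <- c(7, 7, 7)
  mask <- array(FALSE, d)
  mask[4, 4, 2:6] <- TRUE            # single dorsoventral column
  roi <- new("VertebraROI", scalar = array(40, d), mask = mask,
             spacing = c(1, 1, 1), com = maskCentroid2(mask),
             labelName = "L1")
  est2 <- estimateInclination(detectInferiorEdge(roi))
  expect_false(est2$valid)
})

test_that("points sampled from a known line are recovered within the angle resolution", {
  for (angle in c(-17, 0, 10)) {
    y <- seq(0, 30, by = 1.2)
    z <- 5 + tan(angle * pi / 180) * y
    est <- estimateInclination(cbind(y, z), resolutionDeg = 0.5,
                               offsetWindowMm = 1)
    expect_lt(abs(est$angleDeg - angle), 0.5 + 1e-9)
    expect_true(est$valid)
  }
})

test_that("tilted phantoms are recovered across the angle sweep", {
  for (th in c(-20, -10, -5, 0, 5, 10, 20)) {
    roi <- singleVertebraROI(a = 16, b = 12, h = 30, n = 3, tilt = th,
                             spacing = c(1.2, 1.2, 1.2))
    est <- estimateInclination(detectInferiorEdge(roi))
    expect_lt(abs(est$angleDeg - th), 1.5)
  }
})

test_that("zero-angle rotation is the identity", {
  roi <- singleVertebraROI()
  expect_identical(rotateVertebra(roi, 0), roi)
})

test_that("rotation round trip keeps the mask nearly intact", {
  roi <- singleVertebraROI(a = 15, b = 11, h = 30, n = 3,
                           field = fieldSpec(40, c(5, 3, 6), 3),
                           spacing = c(1.2, 1.2, 1.5))
  r1 <- rotateVertebra(roi, 10)
  expect_lt(abs(sum(maskData(r1)) - sum(maskData(roi))) / sum(maskData(roi)),
            0.03)
  r2 <- rotateVertebra(r1, -10)
  off <- round(comVoxel(r2) - comVoxel(roi))
  i0 <- which(maskData(roi), arr.ind = TRUE)
  i2 <- sweep(which(maskData(r2), arr.ind = TRUE), 2, off)
  k0 <- paste(i0[, 1], i0[, 2], i0[, 3])
  k2 <- paste(i2[, 1], i2[, 2], i2[, 3])
  dice <- 2 * length(intersect(k0, k2)) / (length(k0) + length(k2))
  expect_gte(dice, 0.97)
})

test_that("closed-loop correction removes the estimated inclination", {
  for (th in c(-15, 5, 12)) {
    roi <- singleVertebraROI(a = 16, b = 12, h = 30, n = 3, tilt = th,
                             spacing = c(1.2, 1.2, 1.2))
    est <- estimateInclination(detectInferiorEdge(roi))
    corrected <- rotateVertebra(roi, est$angleDeg)
    resid <- estimateInclination(detectInferiorEdge(corrected))$angleDeg
    expect_lte(abs(resid), 1.0)
  }
})

test_that("inclination estimation is equivariant under rotation", {
  roi <- singleVertebraROI(a = 16, b = 12, h = 30, n = 3,
                           spacing = c(1.2, 1.2, 1.2))
  base <- estimateInclination(detectInferiorEdge(roi))$angleDeg
  for (th in c(-6, 4, 9)) {
    rotated <- rotateVertebra(roi, th)
    est <- estimateInclination(detectInferiorEdge(rotated))$angleDeg
    expect_lt(abs(est - (base - th)), 1.5)
  }
})
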