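# Inclination estimation and correction.
#
# Each vertebral body is treated independently: its inclination with respect
# to the horizontal plane is estimated from the inferior edge of the
# mid-sagittal segmentation slice by a straight-line Hough transform on
# mm-scaled edge points, and corrected by rotating the ROI about the
# horizontal axis through its centre of mass.

#' Extract a single-vertebra ROI from a labelled volume
#'
#' Crops the tight bounding box of the requested label plus a margin. When a
#' label decomposes into several connected components (a segmentation
#' artefact), only the largest 6-connected component is kept, with a warning.
#'
#' @param scalar A [ScalarVolume3D].
#' @param labels A companion [LabelVolume3D] of identical shape.
#' @param label Integer label value to extract.
#' @param marginVoxels Margin added around the bounding box (default 2).
#' @return A [VertebraROI]; the centre of mass is the unweighted mask
#'   centroid in cropped 1-based voxel coordinates.
#' @export
extractVertebraROI <- function(scalar, labels, label, marginVoxels = 2L) {
  stopifnot(is(scalar, "ScalarVolume3D"), is(labels, "LabelVolume3D"))
  if (!identical(dim(scalar@data), dim(labels@data)))
    stop("scalar and label volumes have different shapes")
  mask <- labels@data == label
  if (!any(mask))
    stop("label ", label, " is not present in the label volume")
  comp <- labelComponents3D(mask)
  nComp <- max(comp)
  if (nComp > 1L) {
    sizes <- tabulate(comp[comp > 0L], nComp)
    keep <- which.max(sizes)
    warning("label ", label, " has ", nComp,
            " connected components; keeping the largest (",
            sizes[keep], " of ", sum(sizes), " voxels)")
    mask <- comp == keep
  }
  bb <- apply(which(mask, arr.ind = TRUE), 2, range)
  d <- dim(mask)
  lo <- pmax(bb[1, ] - marginVoxels, 1L)
  hi <- pmin(bb[2, ] + marginVoxels, d)
  sc <- scalar@data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  mk <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  nm <- labels@labelMap[as.character(label)]
  if (is.na(nm)) nm <- as.character(label)
  new("VertebraROI", scalar = sc, mask = mk, spacing = scalar@spacing,
      com = maskCentroid(mk), labelName = unname(nm))
}

#' Inferior edge of the mid-sagittal mask slice
#'
#' Takes the mid-sagittal slice at the horizontal index nearest the centre of
#' mass; for every dorsoventral column containing mask, the most inferior
#' masked voxel centre is emitted, converted to millimetres with the
#' anisotropic voxel spacing.
#'
#' @param roi A [VertebraROI].
#' @return Two-column matrix (`y_mm`, `z_mm`) of edge-point centres, with the
#'   longitudinal spacing attached as attribute `"spacingZ"`.
#' @export
detectInferiorEdge <- function(roi) {
  stopifnot(is(roi, "VertebraROI"))
  ix <- nearestIndexTieLow(roi@com[1])
  slice <- roi@mask[ix, , , drop = TRUE]   # dorsoventral x longitudinal
  cols <- which(apply(slice, 1, any))
  pts <- vapply(cols, function(j) min(which(slice[j, ])), 0L)
  out <- cbind(y_mm = (cols - 0.5) * roi@spacing[2],
               z_mm = (pts - 0.5) * roi@spacing[3])
  attr(out, "spacingZ") <- roi@spacing[3]
  out
}

#' Hough-transform inclination estimate
#'
#' Performs a straight-line Hough transform of the inferior-edge points over
#' an angle grid. For each candidate angle the points are projected onto the
#' line-normal offset axis and the vote count is the maximum number of points
#' falling inside a sliding offset window (width `offsetWindowMm`), which
#' avoids histogram bin-phase artefacts. Because slice quantization makes the
#' maximum-vote set a plateau of angles bracketing the true inclination, the
#' returned angle is the median of that plateau.
#'
#' @param edgePoints Matrix from [detectInferiorEdge()], or any 2-column
#'   (y_mm, z_mm) point matrix.
#' @param halfRangeDeg Half-width of the angle search range (default 30).
#' @param resolutionDeg Angle grid step (default 0.5).
#' @param offsetWindowMm Offset window width; default 1.1 x the longitudinal
#'   spacing carried by `edgePoints` (2 mm if absent).
#' @param minEdgePoints Minimum number of edge points for a valid estimate
#'   (default 5). Below it, angle 0 is returned flagged invalid.
#' @return List of class `InclinationEstimate` with `angleDeg`,
#'   `houghVotes`, `nEdgePoints` and `valid`.
#' @export
estimateInclination <- function(edgePoints, halfRangeDeg = 30,
                                resolutionDeg = 0.5, offsetWindowMm = NULL,
                                minEdgePoints = 5L) {
  n <- nrow(edgePoints)
  if (is.null(offsetWindowMm)) {
    spz <- attr(edgePoints, "spacingZ")
    offsetWindowMm <- if (is.null(spz)) 2 else 1.1 * spz
  }
  if (is.null(n) || n < minEdgePoints) {
    return(structure(list(angleDeg = 0, houghVotes = 0L,
                          nEdgePoints = if (is.null(n)) 0L else n,
                          valid = FALSE),
                     class = "InclinationEstimate"))
  }
  y <- edgePoints[, 1]
  z <- edgePoints[, 2]
  angles <- seq(-halfRangeDeg, halfRangeDeg, by = resolutionDeg)
  votes <- vapply(angles, function(aDeg) {
    a <- aDeg * pi / 180
    rho <- sort(z * cos(a) - y * sin(a))
    # max count of points within any offset window of the given width
    j <- findInterval(rho + offsetWindowMm, rho)
    max(j - seq_along(rho) + 1L)
  }, 0L)
  best <- max(votes)
  plateau <- angles[votes == best]
  structure(list(angleDeg = stats::median(plateau), houghVotes = best,
                 nEdgePoints = n, valid = TRUE),
            class = "InclinationEstimate")
}

#' @export
print.InclinationEstimate <- function(x, ...) {
  cat(sprintf("Inclination estimate: %.2f deg (%s, %d votes from %d edge points)\n",
              x$angleDeg, if (x$valid) "valid" else "invalid",
              x$houghVotes, x$nEdgePoints))
  invisible(x)
}

#' Rotate a vertebra ROI about the horizontal axis
#'
#' Applies the inclination correction: a rotation by `-angleDeg` about the
#' horizontal axis through the mask centre of mass, performed in millimetre
#' space to respect anisotropic voxels. Scalar values are resampled with
#' bilinear interpolation, the mask with nearest neighbour; the output grid
#' is padded so no masked voxel is lost. `angleDeg = 0` returns the input
#' unchanged.
#'
#' @param roi A [VertebraROI].
#' @param angleDeg Inclination angle to correct, degrees (|angle| <= 45).
#' @return A rotated [VertebraROI] with recomputed centre of mass.
#' @export
rotateVertebra <- function(roi, angleDeg) {
  stopifnot(is(roi, "VertebraROI"), abs(angleDeg) <= 45)
  if (angleDeg == 0) return(roi)
  sp <- roi@spacing
  d <- dim(roi@mask)
  phi <- -angleDeg * pi / 180            # applied rotation
  cph <- cos(phi); sph <- sin(phi)

  # mm extents relative to com along y and z
  yr <- (c(1, d[2]) - roi@com[2]) * sp[2]
  zr <- (c(1, d[3]) - roi@com[3]) * sp[3]
  corners <- expand.grid(y = yr, z = zr)
  yRot <- corners$y * cph - corners$z * sph
  zRot <- corners$y * sph + corners$z * cph
  padY <- max(0L, ceiling((max(abs(yRot)) - max(abs(yr))) / sp[2]) + 1L)
  padZ <- max(0L, ceiling((max(abs(zRot)) - max(abs(zr))) / sp[3]) + 1L)

  ny2 <- d[2] + 2L * padY
  nz2 <- d[3] + 2L * padZ
  com2 <- roi@com + c(0, padY, padZ)
  # target voxel centres in mm relative to com, inverse-rotated into source
  yt <- (seq_len(ny2) - com2[2]) * sp[2]
  zt <- (seq_len(nz2) - com2[3]) * sp[3]
  Yt <- matrix(yt, ny2, nz2)
  Zt <- matrix(zt, ny2, nz2, byrow = TRUE)
  ySrc <- Yt * cph + Zt * sph
  zSrc <- -Yt * sph + Zt * cph
  fy <- ySrc / sp[2] + roi@com[2]
  fz <- zSrc / sp[3] + roi@com[3]

  # bilinear weights in the (y, z) plane, shared by every x slab
  i0 <- floor(fy); j0 <- floor(fz)
  wy <- fy - i0; wz <- fz - j0
  scalar2 <- array(0, c(d[1], ny2, nz2))
  mask2 <- array(FALSE, c(d[1], ny2, nz2))
  S <- matrix(roi@scalar, d[1], d[2] * d[3])
  M <- matrix(roi@mask, d[1], d[2] * d[3])
  colIdx <- function(i, j) {
    ok <- i >= 1 & i <= d[2] & j >= 1 & j <= d[3]
    idx <- ifelse(ok, i + (j - 1) * d[2], 1L)
    list(idx = idx, ok = ok)
  }
  # mask-aware bilinear resampling: weights are restricted to masked source
  # voxels and renormalized, so rotated scalar values are convex combinations
  # of masked PDFF values and background never bleeds across the boundary
  acc <- matrix(0, d[1], ny2 * nz2)
  accPlain <- matrix(0, d[1], ny2 * nz2)
  accW <- matrix(0, d[1], ny2 * nz2)
  for (corner in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    ci <- colIdx(i0 + corner[1], j0 + corner[2])
    w <- (if (corner[1]) wy else 1 - wy) * (if (corner[2]) wz else 1 - wz)
    w <- rep(as.vector(w * ci$ok), each = d[1])
    src <- S[, ci$idx, drop = FALSE]
    msk <- M[, ci$idx, drop = FALSE] * w
    acc <- acc + src * msk
    accW <- accW + msk
    accPlain <- accPlain + src * w
  }
  scalar2 <- array(ifelse(accW > 1e-9, acc / pmax(accW, 1e-9), accPlain),
                   c(d[1], ny2, nz2))
  nn <- colIdx(round(fy), round(fz))
  mask2 <- array(M[, nn$idx, drop = FALSE] & rep(nn$ok, each = d[1]),
                 c(d[1], ny2, nz2))
  if (!any(mask2))
    stop("rotation produced an empty mask")
  new("VertebraROI", scalar = pmin(pmax(scalar2, 0), 100), mask = mask2,
      spacing = sp, com = maskCentroid(mask2), labelName = roi@labelName)
}
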