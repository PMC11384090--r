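# Standardized elliptical-cylinder mapping.
#
# Every vertebral body, regardless of size and shape, is resampled onto the
# same elliptical-cylinder template by extent-based linear interpolation:
# within each image row the masked extent is stretched to a fixed number of
# samples, the stacked rows are resampled in the perpendicular direction, and
# template rows are finally shrunk to the elliptical chord widths. The
# composition approximately recovers normalized body coordinates, which is
# what makes maps of differently shaped vertebrae directly comparable.

#' Construct template geometry
#'
#' @param nMajor Sampling points on the major (horizontal) semi-axis
#'   (default 20).
#' @param nMinor Sampling points on the minor (dorsoventral) semi-axis
#'   (default 16).
#' @param nLong Longitudinal sampling points (default 20).
#' @return A [TemplateGeometry].
#' @export
templateGeometry <- function(nMajor = 20L, nMinor = 16L, nLong = 20L) {
  new("TemplateGeometry", nMajor = as.integer(nMajor),
      nMinor = as.integer(nMinor), nLong = as.integer(nLong))
}

#' Elliptical validity mask of the transverse template
#'
#' @param geom A [TemplateGeometry].
#' @return Logical matrix `(2*nMinor+1) x (2*nMajor+1)`; node (i, j) in
#'   centred index coordinates is valid iff
#'   `(i/nMajor)^2 + (j/nMinor)^2 <= 1`.
#' @export
templateMask <- function(geom) {
  stopifnot(is(geom, "TemplateGeometry"))
  iCol <- (-geom@nMajor):geom@nMajor
  jRow <- (-geom@nMinor):geom@nMinor
  outer(jRow / geom@nMinor, iCol / geom@nMajor,
        function(q, p) p^2 + q^2 <= 1 + 1e-12)
}

#' Resample a masked run to a fixed number of samples
#'
#' Linear interpolation over the masked extent: the first and last samples of
#' the run map exactly to the first and last output samples, interior values
#' are interpolated at uniform fractional positions. A single-sample run
#' broadcasts its value; `nOut = 1` returns the value at the midpoint of the
#' run.
#'
#' @param values Numeric vector, the scalar values of one masked run.
#' @param nOut Number of output samples.
#' @return Numeric vector of length `nOut`.
#' @export
resampleMaskedRun <- function(values, nOut) {
  k <- length(values)
  if (k == 0L) stop("empty run")
  stopifnot(nOut >= 1L)
  if (k == 1L) return(rep(values, nOut))
  xin <- seq(0, 1, length.out = k)
  xout <- if (nOut == 1L) 0.5 else seq(0, 1, length.out = nOut)
  stats::approx(xin, values, xout = xout)$y
}

# Resample one image row: take the run from first to last masked voxel,
# interpolate across interior gaps from the masked values (never sampling
# background), then stretch the run to nOut samples.
.resampleRow <- function(values, maskRow, nOut) {
  pos <- which(maskRow)
  if (!length(pos)) return(NULL)
  if (length(pos) == 1L) return(rep(values[pos], nOut))
  span <- (pos - pos[1]) / (pos[length(pos)] - pos[1])
  xout <- if (nOut == 1L) 0.5 else seq(0, 1, length.out = nOut)
  stats::approx(span, values[pos], xout = xout)$y
}

#' Map one axial slice onto the elliptical template
#'
#' Step 1 resamples every image row intersecting the mask along the
#' horizontal axis to `2*nMajor+1` samples; step 2 resamples the stacked rows
#' column-wise along the dorsoventral axis to `2*nMinor+1` rows; step 3
#' shrinks each template row to its elliptical chord width and centres it,
#' leaving nodes outside the ellipse invalid (`NA`).
#'
#' @param scalarSlice Numeric matrix (horizontal x dorsoventral).
#' @param maskSlice Logical matrix of the same shape.
#' @param geom A [TemplateGeometry].
#' @return Numeric matrix `(2*nMinor+1) x (2*nMajor+1)` with `NA` outside the
#'   elliptical footprint.
#' @export
mapTransverseSlice <- function(scalarSlice, maskSlice, geom) {
  stopifnot(is(geom, "TemplateGeometry"))
  if (!any(maskSlice)) stop("mask slice is empty")
  nCols <- 2L * geom@nMajor + 1L
  nRows <- 2L * geom@nMinor + 1L
  ys <- which(apply(maskSlice, 2, any))
  rows <- lapply(ys, function(j)
    .resampleRow(scalarSlice[, j], maskSlice[, j], nCols))
  rect <- do.call(rbind, rows)              # length(ys) x nCols
  if (length(ys) == 1L) {
    rect2 <- matrix(rep(rect, each = nRows), nRows, nCols)
  } else {
    span <- (ys - ys[1]) / (ys[length(ys)] - ys[1])
    yout <- seq(0, 1, length.out = nRows)
    rect2 <- apply(rect, 2, function(col)
      stats::approx(span, col, xout = yout)$y)
  }
  valid <- templateMask(geom)
  out <- matrix(NA_real_, nRows, nCols)
  centre <- geom@nMajor + 1L
  for (j in seq_len(nRows)) {
    w <- sum(valid[j, ])
    if (w == 0L) next
    half <- (w - 1L) %/% 2L
    out[j, (centre - half):(centre + half)] <-
      resampleMaskedRun(rect2[j, ], w)
  }
  out
}

# Build one longitudinal map (mid-sagittal or mid-coronal): per axial slice
# resample the masked run at the fixed plane index to nAcross samples, then
# resample the slice stack along the longitudinal axis to nLong rows. Rows
# are ordered superior to inferior for display.
.mapLongitudinal <- function(scalar, mask, planeIdx, alongAxis, nAcross, nLong) {
  d <- dim(mask)
  runs <- list()
  zUsed <- integer(0)
  for (k in seq_len(d[3])) {
    if (alongAxis == 2L) {                 # sagittal: runs along dorsoventral
      mk <- mask[planeIdx, , k]
      vals <- scalar[planeIdx, , k]
    } else {                               # coronal: runs along horizontal
      mk <- mask[, planeIdx, k]
      vals <- scalar[, planeIdx, k]
    }
    r <- .resampleRow(vals, mk, nAcross)
    if (!is.null(r)) {
      runs[[length(runs) + 1L]] <- r
      zUsed <- c(zUsed, k)
    }
  }
  if (length(runs) < 2L)
    stop("mask is thinner than 2 usable slices at the mid-plane; cannot ",
         "build longitudinal maps")
  stack <- do.call(rbind, runs)            # nUsed x nAcross, inferior first
  span <- (zUsed - zUsed[1]) / (zUsed[length(zUsed)] - zUsed[1])
  zout <- seq(0, 1, length.out = nLong)
  long <- apply(stack, 2, function(col) stats::approx(span, col, xout = zout)$y)
  long[nLong:1, , drop = FALSE]            # superior at the top row
}

#' Build the three standardized distribution maps of one vertebra
#'
#' Optionally estimates and corrects the inclination first (recording the
#' angle), then extracts the mid-transverse map from the axial slice at the
#' centre of mass, and the mid-sagittal / mid-coronal maps by per-slice run
#' resampling at the centre-of-mass plane index followed by head--feet
#' resampling to `nLong` rows. Axial slices without mask at the required
#' plane index are excluded before longitudinal resampling, never zero-filled.
#'
#' @param roi A [VertebraROI].
#' @param geom A [TemplateGeometry] (default [templateGeometry()]).
#' @param correctInclination Estimate and correct the inclination first?
#' @param houghArgs List of arguments passed to [estimateInclination()].
#' @return A [StandardizedMaps]. With defaults the maps measure 33 x 41
#'   (transverse), 20 x 33 (sagittal) and 20 x 41 (coronal).
#' @export
buildStandardizedMaps <- function(roi, geom = templateGeometry(),
                                  correctInclination = FALSE,
                                  houghArgs = list()) {
  stopifnot(is(roi, "VertebraROI"), is(geom, "TemplateGeometry"))
  angle <- 0
  corrected <- FALSE
  if (correctInclination) {
    est <- do.call(estimateInclination,
                   c(list(detectInferiorEdge(roi)), houghArgs))
    if (est$valid && est$angleDeg != 0) {
      roi <- rotateVertebra(roi, est$angleDeg)
      angle <- est$angleDeg
      corrected <- TRUE
    }
  }
  mid <- nearestIndexTieLow(roi@com)
  if (sum(apply(roi@mask, 3, any)) < 2L)
    stop("mask is thinner than 2 slices longitudinally")
  trSlice <- roi@scalar[, , mid[3], drop = TRUE]
  trMask <- roi@mask[, , mid[3], drop = TRUE]
  if (!any(trMask))
    stop("no mask on the mid-transverse slice at the centre of mass")
  transverse <- mapTransverseSlice(trSlice, trMask, geom)
  sagittal <- .mapLongitudinal(roi@scalar, roi@mask, mid[1], 2L,
                               2L * geom@nMinor + 1L, geom@nLong)
  coronal <- .mapLongitudinal(roi@scalar, roi@mask, mid[2], 1L,
                              2L * geom@nMajor + 1L, geom@nLong)
  new("StandardizedMaps", transverse = transverse, sagittal = sagittal,
      coronal = coronal, labelName = roi@labelName,
      inclinationCorrected = corrected, angleDeg = angle)
}
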