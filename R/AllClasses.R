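#' @import methods
NULL

#' Canonical 3D scalar PDFF volume
#'
#' A 3D grid of proton-density fat fraction (PDFF) values in percent, held in
#' the package's canonical axis convention: array index 1 runs along the
#' horizontal (left--right) axis, index 2 along the dorsoventral
#' (anterior--posterior) axis, and index 3 along the longitudinal (feet--head)
#' axis, with the third index increasing towards the head. Values are clipped
#' to the physically meaningful range [0, 100].
#'
#' @slot data 3D numeric array of PDFF values (percent).
#' @slot spacing Numeric length-3 voxel spacing in mm, ordered
#'   (horizontal, dorsoventral, longitudinal).
#'
#' @seealso [readScalarVolume()], [writeScalarVolume()]
#' @export
setClass("ScalarVolume3D",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite values (mm)")
    v <- object@data
    if (any(v[is.finite(v)] < 0) || any(v[is.finite(v)] > 100))
      msg <- c(msg, "finite PDFF values must lie in [0, 100] percent")
    if (length(msg)) msg else TRUE
  }
)

#' Integer vertebra label volume
#'
#' An integer 3D grid aligned voxel-for-voxel with a companion
#' [ScalarVolume3D]. Voxel value 0 is background; positive values identify
#' vertebral bodies through `labelMap`, a named character vector mapping label
#' values (as names) to vertebra names such as `"L1"` ... `"L5"`.
#'
#' @slot data 3D integer array of labels.
#' @slot labelMap Named character vector, names are label values.
#' @slot spacing Voxel spacing in mm, as in [ScalarVolume3D].
#'
#' @seealso [readLabelVolume()], [defaultLabelMap()]
#' @export
setClass("LabelVolume3D",
  representation(data = "array", labelMap = "character", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values (mm)")
    if (length(object@labelMap) == 0L || is.null(names(object@labelMap)))
      msg <- c(msg, "labelMap must be a non-empty named character vector")
    vals <- unique(as.vector(object@data))
    vals <- vals[vals != 0]
    if (length(vals) && !all(as.character(vals) %in% names(object@labelMap)))
      msg <- c(msg, "all non-zero voxel values must be keys of labelMap")
    if (length(msg)) msg else TRUE
  }
)

#' Single-vertebra region of interest
#'
#' The cropped PDFF sub-volume and binary mask of one vertebral body, together
#' with the (unweighted) centre of mass of the mask in 1-based voxel
#' coordinates of the cropped grid. All geometric processing (inclination
#' estimation and correction, template mapping) operates on this object.
#'
#' @slot scalar 3D numeric array, cropped PDFF values (percent).
#' @slot mask 3D logical array of identical dimensions.
#' @slot spacing Voxel spacing in mm.
#' @slot com Centre of mass of the mask, 1-based voxel coordinates.
#' @slot labelName Vertebra name, e.g. `"L3"`.
#'
#' @seealso [extractVertebraROI()], [rotateVertebra()], [volumetricStats()]
#' @export
setClass("VertebraROI",
  representation(scalar = "array", mask = "array", spacing = "numeric",
                 com = "numeric", labelName = "character"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@scalar), dim(object@mask)))
      msg <- c(msg, "scalar and mask must have identical dimensions")
    if (!is.logical(object@mask))
      msg <- c(msg, "mask must be logical")
    if (!any(object@mask))
      msg <- c(msg, "mask must contain at least one voxel")
    if (length(object@com) != 3L)
      msg <- c(msg, "com must have length 3")
    else if (any(object@mask)) {
      bb <- apply(which(object@mask, arr.ind = TRUE), 2, range)
      if (any(object@com < bb[1, ] - 0.5) || any(object@com > bb[2, ] + 0.5))
        msg <- c(msg, "com must lie inside the mask bounding box")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Elliptical-cylinder template geometry
#'
#' Sampling geometry of the standardized elliptical cylinder. The transverse
#' template grid has `2*nMajor + 1` columns (horizontal direction, along the
#' major semi-axis) and `2*nMinor + 1` rows (dorsoventral direction, minor
#' semi-axis), so that the centre and both semi-axis endpoints are grid nodes;
#' `nLong` rows sample the longitudinal axis of the cylinder. Defaults follow
#' the standard template of 20 / 16 sampling points on the major / minor
#' semi-axes and 20 longitudinal sampling points.
#'
#' @slot nMajor Sampling points on the major (horizontal) semi-axis.
#' @slot nMinor Sampling points on the minor (dorsoventral) semi-axis.
#' @slot nLong Longitudinal sampling points.
#'
#' @seealso [templateGeometry()], [templateMask()]
#' @export
setClass("TemplateGeometry",
  representation(nMajor = "integer", nMinor = "integer", nLong = "integer"),
  validity = function(object) {
    if (object@nMajor < 2L || object@nMinor < 2L || object@nLong < 2L)
      "nMajor, nMinor and nLong must all be >= 2" else TRUE
  }
)

#' Standardized PDFF distribution maps
#'
#' The three perpendicular standardized distribution maps of one vertebral
#' body: mid-transverse (rows = dorsoventral, columns = horizontal, elliptical
#' footprint, invalid template nodes are `NA`), mid-sagittal (rows =
#' longitudinal head-to-feet, columns = dorsoventral) and mid-coronal (rows =
#' longitudinal, columns = horizontal). Valid pixels are PDFF percent in
#' [0, 100].
#'
#' @slot transverse Numeric matrix `(2*nMinor+1) x (2*nMajor+1)`, `NA` outside
#'   the elliptical template footprint.
#' @slot sagittal Numeric matrix `nLong x (2*nMinor+1)`.
#' @slot coronal Numeric matrix `nLong x (2*nMajor+1)`.
#' @slot labelName Vertebra the maps belong to.
#' @slot inclinationCorrected Whether inclination correction was applied.
#' @slot angleDeg Inclination angle (degrees) used for correction (0 when
#'   uncorrected or the estimate was invalid).
#'
#' @seealso [buildStandardizedMaps()], [mapStats()], [writeMapsPNG()]
#' @export
setClass("StandardizedMaps",
  representation(transverse = "matrix", sagittal = "matrix",
                 coronal = "matrix", labelName = "character",
                 inclinationCorrected = "logical", angleDeg = "numeric"),
  validity = function(object) {
    msg <- character()
    for (nm in c("transverse", "sagittal", "coronal")) {
      m <- slot(object, nm)
      v <- m[is.finite(m)]
      if (length(v) && (any(v < 0) || any(v > 100)))
        msg <- c(msg, sprintf("%s map values must lie in [0, 100]", nm))
    }
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "ScalarVolume3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("ScalarVolume3D: %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2], object@spacing[3]))
  v <- object@data[is.finite(object@data)]
  cat(sprintf("  PDFF range %.1f - %.1f %%\n", min(v), max(v)))
})

setMethod("show", "LabelVolume3D", function(object) {
  d <- dim(object@data)
  present <- presentLabels(object)
  cat(sprintf("LabelVolume3D: %d x %d x %d voxels, %d vertebra(e): %s\n",
              d[1], d[2], d[3], length(present),
              if (length(present)) paste(object@labelMap[as.character(present)],
                                         collapse = ", ") else "none"))
})

setMethod("show", "VertebraROI", function(object) {
  d <- dim(object@mask)
  cat(sprintf("VertebraROI %s: %d x %d x %d voxels, %d in mask (%.1f ml)\n",
              object@labelName, d[1], d[2], d[3], sum(object@mask),
              sum(object@mask) * prod(object@spacing) / 1000))
})

setMethod("show", "TemplateGeometry", function(object) {
  cat(sprintf("TemplateGeometry: %d / %d sampling points on major / minor semi-axes, %d longitudinal\n",
              object@nMajor, object@nMinor, object@nLong))
  cat(sprintf("  transverse grid %d x %d, %d valid nodes\n",
              2L * object@nMinor + 1L, 2L * object@nMajor + 1L,
              sum(templateMask(object))))
})

setMethod("show", "StandardizedMaps", function(object) {
  cat(sprintf("StandardizedMaps %s (%s, angle %.1f deg)\n", object@labelName,
              if (object@inclinationCorrected) "inclination-corrected" else "uncorrected",
              object@angleDeg))
  cat(sprintf("  transverse %d x %d | sagittal %d x %d | coronal %d x %d\n",
              nrow(object@transverse), ncol(object@transverse),
              nrow(object@sagittal), ncol(object@sagittal),
              nrow(object@coronal), ncol(object@coronal)))
})
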