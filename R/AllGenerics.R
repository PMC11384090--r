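#' Voxel data of a volume object
#'
#' @param x A [ScalarVolume3D], [LabelVolume3D] or [VertebraROI].
#' @return The underlying 3D array (scalar values for a `VertebraROI`).
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname voxelData
#' @export
setMethod("voxelData", "ScalarVolume3D", function(x) x@data)
#' @rdname voxelData
#' @export
setMethod("voxelData", "LabelVolume3D", function(x) x@data)
#' @rdname voxelData
#' @export
setMethod("voxelData", "VertebraROI", function(x) x@scalar)

#' Voxel spacing in millimetres
#'
#' @param x A volume-like object.
#' @return Numeric length-3 spacing (horizontal, dorsoventral, longitudinal).
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))

#' @rdname spacingMm
#' @export
setMethod("spacingMm", "ScalarVolume3D", function(x) x@spacing)
#' @rdname spacingMm
#' @export
setMethod("spacingMm", "LabelVolume3D", function(x) x@spacing)
#' @rdname spacingMm
#' @export
setMethod("spacingMm", "VertebraROI", function(x) x@spacing)

#' Binary mask of a vertebra ROI
#'
#' @param x A [VertebraROI].
#' @return Logical 3D array.
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))

#' @rdname maskData
#' @export
setMethod("maskData", "VertebraROI", function(x) x@mask)

#' Centre of mass of a vertebra mask
#'
#' @param x A [VertebraROI].
#' @return 1-based voxel coordinates of the unweighted mask centroid.
#' @export
setGeneric("comVoxel", function(x) standardGeneric("comVoxel"))

#' @rdname comVoxel
#' @export
setMethod("comVoxel", "VertebraROI", function(x) x@com)

#' Label-to-vertebra mapping of a label volume
#'
#' @param x A [LabelVolume3D].
#' @return Named character vector (names = label values).
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' @rdname labelMap
#' @export
setMethod("labelMap", "LabelVolume3D", function(x) x@labelMap)

#' Labels actually present in a label volume
#'
#' @param x A [LabelVolume3D].
#' @return Sorted integer vector of non-zero label values with >= 1 voxel.
#' @export
setGeneric("presentLabels", function(x) standardGeneric("presentLabels"))

#' @rdname presentLabels
#' @export
setMethod("presentLabels", "LabelVolume3D", function(x) {
  vals <- sort(unique(as.vector(x@data)))
  as.integer(vals[vals != 0])
})

#' Extract one standardized distribution map
#'
#' @param x A [StandardizedMaps] object.
#' @param plane One of `"transverse"`, `"sagittal"`, `"coronal"`.
#' @return Numeric matrix; invalid template pixels are `NA`.
#' @export
setGeneric("distributionMap", function(x, plane) standardGeneric("distributionMap"))

#' @rdname distributionMap
#' @export
setMethod("distributionMap", "StandardizedMaps", function(x, plane) {
  plane <- match.arg(plane, c("transverse", "sagittal", "coronal"))
  slot(x, plane)
})
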