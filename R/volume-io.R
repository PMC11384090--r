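#' Default lumbar label convention
#'
#' Label value 1 maps to L1 through 5 to L5. The on-disk numeric coding of
#' vertebra labels is a convention of the segmentation tool, not a property of
#' the data; override it wherever a different coding is used.
#'
#' @return Named character vector `c("1" = "L1", ..., "5" = "L5")`.
#' @export
defaultLabelMap <- function() {
  stats::setNames(paste0("L", 1:5), as.character(1:5))
}

#' Construct a ScalarVolume3D from an array
#'
#' Values outside the physical PDFF range [0, 100] percent are clipped (MR
#' reconstruction noise routinely produces small excursions); the number of
#' clipped voxels is attached as attribute `"nClipped"` and reported.
#'
#' @param data 3D numeric array in canonical axis order
#'   (horizontal, dorsoventral, longitudinal).
#' @param spacing Voxel spacing in mm, length 3.
#' @return A [ScalarVolume3D].
#' @export
scalarVolume <- function(data, spacing) {
  if (length(dim(data)) != 3L)
    stop("scalar volume data must be a 3D array, got ",
         length(dim(data)), " dimension(s)")
  cl <- clipRange(data)
  if (cl$nClipped > 0)
    message(cl$nClipped, " voxel(s) outside [0, 100] % clipped")
  vol <- new("ScalarVolume3D", data = cl$values, spacing = as.numeric(spacing))
  attr(vol, "nClipped") <- cl$nClipped
  vol
}

#' Construct a LabelVolume3D from an array
#'
#' Voxel values not listed in `labelMap` are zeroed with a warning, so stray
#' labels from upstream segmentation cannot silently enter the analysis.
#'
#' @param data 3D numeric/integer array; values must be integral.
#' @param labelMap Named character vector mapping label values to vertebra
#'   names; see [defaultLabelMap()].
#' @param spacing Voxel spacing in mm.
#' @return A [LabelVolume3D].
#' @export
labelVolume <- function(data, labelMap = defaultLabelMap(), spacing) {
  if (length(dim(data)) != 3L)
    stop("label volume data must be a 3D array")
  if (max(abs(data - round(data))) > 1e-3)
    stop("label volume contains non-integer voxel values beyond rounding tolerance")
  data <- array(as.integer(round(data)), dim(data))
  vals <- unique(as.vector(data))
  stray <- vals[vals != 0L & !(as.character(vals) %in% names(labelMap))]
  if (length(stray)) {
    warning("zeroing voxels with unknown label(s): ",
            paste(stray, collapse = ", "))
    data[data %in% stray] <- 0L
  }
  new("LabelVolume3D", data = data, labelMap = labelMap,
      spacing = as.numeric(spacing))
}

# Canonicalize an RNifti image to RAS axes (x: left->right, y:
# posterior->anterior, z: feet->head). Oblique acquisitions are mapped to the
# nearest axis-aligned orientation (axis permutation/flip) with a prominent
# warning.
.canonicalizeNifti <- function(img, path) {
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code == 0L && hdr$sform_code == 0L)
    stop("NIfTI file '", path, "' carries no orientation metadata ",
         "(qform and sform codes are both 0); re-export the file with a ",
         "valid affine or construct the volume manually with scalarVolume()/",
         "labelVolume() after verifying the axis order")
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  rot <- sweep(rot, 2, sqrt(colSums(rot^2)), "/")
  if (!all(abs(rot) > 0.99 | abs(rot) < 0.01))
    warning("oblique acquisition in '", path,
            "': reorienting to the nearest canonical axes; geometry assumes ",
            "axis-aligned voxels")
  RNifti::orientation(img) <- "RAS"
  img
}

#' Read a PDFF scalar volume from NIfTI
#'
#' The image is reoriented to the canonical axis convention (see
#' [ScalarVolume3D]) using its orientation metadata, the voxel spacing is
#' extracted, and values are clipped to [0, 100] percent with the clipped
#' voxel count reported and attached as attribute `"nClipped"`.
#'
#' @param path Path to a 3D NIfTI-1 file.
#' @return A [ScalarVolume3D].
#' @export
readScalarVolume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("'", path, "' is not a 3D volume (", length(dim(img)), " dimensions)")
  img <- .canonicalizeNifti(img, path)
  scalarVolume(array(as.numeric(img), dim(img)), RNifti::pixdim(img))
}

#' Read a vertebra label volume from NIfTI
#'
#' @param path Path to a 3D NIfTI-1 file of integer labels.
#' @param labelMap Named character vector mapping label values to vertebra
#'   names; defaults to [defaultLabelMap()].
#' @return A [LabelVolume3D] in canonical axes; unknown labels are zeroed
#'   with a warning.
#' @export
readLabelVolume <- function(path, labelMap = defaultLabelMap()) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("'", path, "' is not a 3D volume")
  img <- .canonicalizeNifti(img, path)
  labelVolume(array(as.numeric(img), dim(img)), labelMap, RNifti::pixdim(img))
}

.writeNiftiCanonical <- function(data, spacing, path) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  RNifti::qform(img) <- structure(diag(c(spacing, 1)), code = 1L)
  ok <- try(RNifti::writeNifti(img, path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write NIfTI to '", path, "': ",
         attr(ok, "condition")$message)
  invisible(path)
}

#' Write a scalar volume to NIfTI
#'
#' @param vol A [ScalarVolume3D].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
writeScalarVolume <- function(vol, path) {
  stopifnot(is(vol, "ScalarVolume3D"))
  .writeNiftiCanonical(vol@data, vol@spacing, path)
}

#' Write a label volume to NIfTI
#'
#' @param labels A [LabelVolume3D].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeLabelVolume <- function(labels, path) {
  stopifnot(is(labels, "LabelVolume3D"))
  .writeNiftiCanonical(labels@data, labels@spacing, path)
}

#' Render standardized maps to PNG files
#'
#' Writes one greyscale PNG per plane (`<prefix>_transverse.png`,
#' `<prefix>_sagittal.png`, `<prefix>_coronal.png`), mapping 0--100 % PDFF to
#' black--white. Template pixels outside the elliptical footprint are fully
#' transparent, never rendered as spurious zeros.
#'
#' @param maps A [StandardizedMaps] object.
#' @param prefix Output path prefix (directory must exist).
#' @return Character vector of the three file paths, invisibly.
#' @export
writeMapsPNG <- function(maps, prefix) {
  stopifnot(is(maps, "StandardizedMaps"))
  planes <- c("transverse", "sagittal", "coronal")
  paths <- character(0)
  for (pl in planes) {
    m <- slot(maps, pl)
    if (!any(is.finite(m)))
      stop("standardized ", pl, " map has no valid pixels; refusing to ",
           "write a blank image")
    g <- pmin(pmax(m / 100, 0), 1)
    rgba <- array(0, c(nrow(m), ncol(m), 4))
    rgba[, , 1] <- ifelse(is.finite(g), g, 0)
    rgba[, , 2] <- rgba[, , 1]
    rgba[, , 3] <- rgba[, , 1]
    rgba[, , 4] <- ifelse(is.finite(g), 1, 0)
    p <- paste0(prefix, "_", pl, ".png")
    png::writePNG(rgba, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
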