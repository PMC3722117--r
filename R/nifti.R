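# NIfTI is the pipeline's canonical on-disk volume format. Internally the
# package works in DICOM-style LPS world coordinates; NIfTI affines are RAS,
# so the first two affine rows are negated on the way in and out.

geometry_to_ras_affine <- function(geometry) {
  rot <- geometry$direction %*% diag(geometry$spacing)
  aff <- rbind(cbind(rot, geometry$origin), c(0, 0, 0, 1))
  aff[1:2, ] <- -aff[1:2, ]
  aff
}

ras_affine_to_geometry <- function(affine, shape) {
  aff <- affine
  aff[1:2, ] <- -aff[1:2, ]  # back to LPS
  rot <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  image_geometry(shape, spacing, origin = aff[1:3, 4],
                 direction = sweep(rot, 2, spacing, `/`))
}

#' Write / read an SUV image as NIfTI
#'
#' The grid geometry travels in the NIfTI sform/qform (converted between the
#' package's LPS convention and NIfTI's RAS). Voxel data round-trip
#' bit-exactly at float64.
#'
#' @param image an \code{suv_image}.
#' @param path file path (\code{.nii} or \code{.nii.gz}).
#' @return \code{write_nifti_image}: the path, invisibly;
#'   \code{read_nifti_image}: an \code{suv_image}.
#' @export
write_nifti_image <- function(image, path) {
  stopifnot(inherits(image, "suv_image"))
  write_nifti_raw(image$values, image$geometry, path, datatype = "double")
}

#' @rdname write_nifti_image
#' @export
read_nifti_image <- function(path) {
  img <- RNifti::readNifti(path)
  suv_image(nifti_geometry(img), array(as.numeric(img), dim = dim(img)))
}

#' Write / read a binary structure mask as NIfTI
#'
#' Masks are stored as uint8 0/1; the label travels outside the file (NIfTI
#' has no structure-name field), so supply it on read.
#'
#' @param mask a \code{structure_mask}.
#' @param path file path.
#' @param label structure label to attach on read.
#' @return \code{write_nifti_mask}: the path, invisibly;
#'   \code{read_nifti_mask}: a \code{structure_mask}.
#' @export
write_nifti_mask <- function(mask, path) {
  stopifnot(inherits(mask, "structure_mask"))
  write_nifti_raw(array(as.integer(mask$voxels), dim(mask$voxels)),
                  mask$geometry, path, datatype = "uint8")
}

#' @rdname write_nifti_mask
#' @export
read_nifti_mask <- function(path, label = "mask") {
  img <- RNifti::readNifti(path)
  structure_mask(nifti_geometry(img), array(as.numeric(img) != 0, dim(img)),
                 label)
}

write_nifti_raw <- function(values, geometry, path, datatype) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- geometry$spacing
  aff <- geometry_to_ras_affine(geometry)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

nifti_geometry <- function(img) {
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  ras_affine_to_geometry(unclass(aff)[1:4, 1:4], dim(img))
}
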