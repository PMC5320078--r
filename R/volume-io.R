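#' Read a CT volume
#'
#' Reads a head-CT volume into Hounsfield units. \code{path} may be a NIfTI
#' file (\code{.nii} / \code{.nii.gz}; voxel data passed through, pixdim
#' taken as spacing) or a directory containing a single DICOM series
#' (slices sorted by position along the slice normal, RescaleSlope /
#' RescaleIntercept applied).
#'
#' @param path NIfTI file or DICOM directory.
#' @return A \linkS4class{CTVolume}.
#' @export
readVolume <- function(path) {
  if (dir.exists(path)) return(readDicomSeries(path))
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  vox <- array(as.vector(img), dim(img))
  if (length(dim(vox)) != 3) stop("expected a 3D NIfTI volume")
  sp <- RNifti::pixdim(img)[1:3]
  vol <- ctVolume(vox, sp)
  if (min(vox) >= 0)
    warning("volume contains no negative HU values (no air?); ",
            "check that the rescale to HU was applied")
  vol
}

#' Write a CT volume as NIfTI
#'
#' @param vol a \code{CTVolume}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return Invisibly, \code{path}.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(structure(vol@voxels, pixdim = vol@spacing))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a binary mask as NIfTI
#'
#' The mask is written as a 0/1 uint8 volume sharing \code{ref}'s geometry.
#'
#' @param mask a \code{BinaryVolume}.
#' @param ref the parent \code{CTVolume} (geometry check and spacing).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeMask <- function(mask, ref, path) {
  checkSameGeometry(mask, ref)
  arr <- array(as.integer(mask@mask), dim(mask@mask))
  img <- RNifti::asNifti(structure(arr, pixdim = ref@spacing),
                         datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI file holding a 0/1 volume.
#' @param ref optional reference volume; when given, the shape is checked.
#' @return A \linkS4class{BinaryVolume} (nonzero voxels are foreground).
#' @export
readMask <- function(path, ref = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim(img))
  if (length(dim(arr)) != 3) stop("expected a 3D NIfTI mask")
  bv <- binaryVolume(arr != 0, spacing = RNifti::pixdim(img)[1:3])
  if (!is.null(ref)) checkSameGeometry(bv, ref)
  bv
}
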