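## NIfTI-1 I/O. All volumes are written with the voxel dimensions in
## pixdim; slice index is the third array axis.

#' Write / read phantom volumes as NIfTI-1
#'
#' Echo volumes are written as one `.nii.gz` file per echo; label maps
#' as one integer volume (0 background/muscle, 1 epineurium,
#' 2 fascicle).
#'
#' @param vol An [echo_pair()] or [nerve_label_map()].
#' @param path,path1,path2 Output file paths (`.nii` or `.nii.gz`).
#' @return The written path(s), invisibly.
#' @name nifti_io
NULL

as_nifti_with_dims <- function(arr, voxdim) {
  img <- RNifti::asNifti(arr)
  RNifti::`pixdim<-`(img, voxdim)
}

#' @rdname nifti_io
#' @export
write_echo_pair <- function(vol, path1, path2) {
  stopifnot(inherits(vol, "echo_pair"))
  RNifti::writeNifti(as_nifti_with_dims(vol$echo1, vol$voxdim), path1)
  RNifti::writeNifti(as_nifti_with_dims(vol$echo2, vol$voxdim), path2)
  invisible(c(path1, path2))
}

#' @rdname nifti_io
#' @param te1,te2 Echo times (ms) of the two volumes being read.
#' @export
read_echo_pair <- function(path1, path2, te1, te2) {
  i1 <- RNifti::readNifti(path1)
  i2 <- RNifti::readNifti(path2)
  voxdim <- RNifti::pixdim(i1)[1:3]
  echo_pair(array(as.numeric(i1), dim = dim(i1)),
            array(as.numeric(i2), dim = dim(i2)),
            te1, te2, voxdim)
}

#' @rdname nifti_io
#' @export
write_label_map <- function(vol, path) {
  stopifnot(inherits(vol, "nerve_label_map"))
  img <- as_nifti_with_dims(vol$labels, vol$voxdim)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_label_map <- function(path) {
  img <- RNifti::readNifti(path)
  nerve_label_map(array(as.integer(img), dim = dim(img)),
                  RNifti::pixdim(img)[1:3])
}

#' @rdname nifti_io
#' @param map A `"pt2star_map"` from [compute_pt2star()].
#' @param path_values,path_valid Output paths for the pT2* values
#'   (invalid voxels written as 0) and the validity mask.
#' @export
write_pt2star_map <- function(map, path_values, path_valid) {
  stopifnot(inherits(map, "pt2star_map"))
  vals <- map$values
  vals[!map$valid] <- 0
  RNifti::writeNifti(as_nifti_with_dims(vals, map$voxdim), path_values)
  valid <- array(as.integer(map$valid), dim = dim(map$valid))
  RNifti::writeNifti(as_nifti_with_dims(valid, map$voxdim), path_valid,
                     datatype = "int16")
  invisible(c(path_values, path_valid))
}
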