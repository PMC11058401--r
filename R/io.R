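#' Write a volume to NIfTI-1
#'
#' @param v a [volume_grid()] or [atlas_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(v, path) {
  if (inherits(v, "atlas_volume")) {
    img <- RNifti::asNifti(v$labels)
  } else {
    stopifnot(inherits(v, "volume_grid"))
    img <- RNifti::asNifti(v$values)
    RNifti::pixdim(img) <- v$voxel_size_mm
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI-1
#'
#' @param path NIfTI file.
#' @param modality modality tag for the returned [volume_grid()].
#' @return a `volume_grid`.
#' @export
read_volume_nifti <- function(path, modality = "fa") {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(vs)) || any(vs <= 0)) vs <- c(1, 1, 1)
  volume_grid(array(as.numeric(img), dim = dim(img)[1:3]), vs, modality)
}

#' Read an integer atlas from NIfTI-1
#' @param path NIfTI file of integer labels.
#' @param names optional region names.
#' @return an `atlas_volume`.
#' @export
read_atlas_nifti <- function(path, names = NULL) {
  img <- RNifti::readNifti(path)
  atlas_volume(array(as.integer(round(as.numeric(img))),
                     dim = dim(img)[1:3]), names)
}

write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_scores_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

write_manifest_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
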