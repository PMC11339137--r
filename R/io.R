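# NIfTI and sidecar I/O. All volumes share a diagonal affine built from
# the voxel spacing; inputs to the analysis operations are assumed
# co-registered.

#' Write a 3D/4D array as NIfTI-1
#'
#' @param arr Numeric or integer array.
#' @param spacing Voxel spacing in mm (length 3).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_nifti_map <- function(arr, spacing, path) {
  img <- RNifti::asNifti(arr + 0)  # drop non-NIfTI attributes, force numeric
  # full pixdim header: qfac, then up to 7 grid spacings
  img$pixdim <- c(1, spacing, rep(1, 7 - length(spacing)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return The image array with attribute `spacing` (mm).
#' @export
read_nifti_map <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "spacing") <- RNifti::pixdim(img)[1:3]
  arr
}

#' Write a DWI volume with its acquisition scheme
#'
#' Writes the 4D signal as NIfTI plus FSL-style bval/bvec text files
#' sharing the stem of `path`.
#'
#' @param dwi A `dwi_volume` from [synthesize_signal()].
#' @param path NIfTI output path (`.nii.gz`).
#' @return Invisibly, the three paths written.
#' @export
write_dwi <- function(dwi, path) {
  scheme <- attr(dwi, "scheme")
  spacing <- attr(dwi, "spacing")
  write_nifti_map(unclass(dwi), spacing, path)
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  write_bval_bvec(scheme, paste0(stem, ".bval"), paste0(stem, ".bvec"))
  invisible(c(path, paste0(stem, ".bval"), paste0(stem, ".bvec")))
}

#' Read a DWI volume and its bval/bvec scheme
#'
#' @param path NIfTI path; bval/bvec are looked up next to it.
#' @return A `dwi_volume` (4D array with `scheme` and `spacing`
#'   attributes).
#' @export
read_dwi <- function(path) {
  arr <- read_nifti_map(path)
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  scheme <- read_bval_bvec(paste0(stem, ".bval"), paste0(stem, ".bvec"))
  structure(unclass(arr), scheme = scheme,
            spacing = attr(arr, "spacing"), S0 = 1, class = "dwi_volume")
}

#' Write a zone parcellation with its JSON sidecar
#'
#' The zone labels (0 excluded/background, 1 inner, 2 middle, 3 outer)
#' go to NIfTI; thresholds, counts and exclusion tallies to a JSON
#' sidecar next to it.
#'
#' @param parcellation A `zone_parcellation`.
#' @param spacing Voxel spacing (mm).
#' @param path NIfTI output path.
#' @return Invisibly, the paths written.
#' @export
write_zones <- function(parcellation, spacing, path) {
  write_nifti_map(parcellation$zone, spacing, path)
  side <- list(thresholds_mm = parcellation$thresholds,
               counts = parcellation$counts,
               exclusions = as.list(parcellation$exclusions))
  json_path <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, json_path))
}
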