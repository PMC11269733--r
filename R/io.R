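# NIfTI I/O for voxel maps and BOLD series (RNifti backend). Internally
# the package works on flat voxel vectors / time-by-voxel matrices with a
# `grid` attribute; these helpers move between that layout and NIfTI files.

#' Write a per-voxel scalar map to NIfTI
#'
#' @param values Per-voxel vector of length `prod(grid)`.
#' @param grid Integer length-3 voxel grid dimensions.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_voxelmap_nifti <- function(values, grid, path) {
  if (length(values) != prod(grid)) stop("values do not match grid")
  img <- array(as.numeric(values), dim = grid)
  RNifti::writeNifti(RNifti::asNifti(img), path)
  invisible(path)
}

#' Read a per-voxel scalar map from NIfTI
#'
#' @param path NIfTI file path.
#' @return Numeric voxel vector with a `grid` attribute.
#' @export
read_voxelmap_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  structure(as.numeric(img), grid = dim(img)[1:3])
}

#' Write a BOLD volume series to a 4-D NIfTI file
#'
#' @param series Time-by-voxel `volume_series` with `grid` and `tr_s`
#'   attributes.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bold_nifti <- function(series, path) {
  grid <- attr(series, "grid")
  if (is.null(grid)) stop("series lacks a grid attribute")
  img <- array(t(unclass(series)), dim = c(grid, nrow(series)))
  nif <- RNifti::asNifti(img)
  RNifti::pixdim(nif) <- c(1, 1, 1, attr(series, "tr_s"))
  RNifti::writeNifti(nif, path)
  invisible(path)
}

#' Read a 4-D NIfTI file as a time-by-voxel series
#'
#' @param path NIfTI file path.
#' @param tr_s TR override in seconds; defaults to the file's pixdim.
#' @return A `volume_series` matrix with `grid` and `tr_s` attributes.
#' @export
read_bold_nifti <- function(path, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4-D BOLD image")
  out <- t(matrix(as.numeric(img), prod(d[1:3]), d[4]))
  attr(out, "grid") <- d[1:3]
  attr(out, "tr_s") <- if (is.null(tr_s)) RNifti::pixdim(img)[4] else tr_s
  class(out) <- c("volume_series", class(out))
  out
}
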