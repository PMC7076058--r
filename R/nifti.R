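#' Read and write label volumes as NIfTI-1
#'
#' Label volumes are stored as integer NIfTI with an axis-aligned RAS
#' affine built from the grid spacing and origin. Reading requires
#' integer-valued data and an axis-aligned affine with positive spacings;
#' anything else is rejected rather than silently reoriented.
#'
#' @param volume a [label_volume()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `write_label_volume` returns `path` invisibly;
#'   `read_label_volume` returns a [label_volume()].
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "label_volume"))
  img <- RNifti::asNifti(volume$labels,
                         reference = list(pixdim = c(1, volume$grid$spacing,
                                                     0, 0, 0, 0)),
                         datatype = "int16")
  aff <- grid_affine(volume$grid)
  RNifti::qform(img) <- structure(aff, code = 1L)
  RNifti::sform(img) <- structure(aff, code = 1L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D NIfTI volume, got ", length(dim(arr)), " dimensions")
  if (any(abs(arr - round(arr)) > 0))
    stop("NIfTI data are not integer-valued; refusing to coerce labels")
  grid <- grid_from_affine(RNifti::xform(img), dim(arr))
  arr <- array(as.integer(arr), dim = dim(arr))  # drop image attributes
  label_volume(arr, grid)
}

#' Write a binary ROI mask as 0/1 NIfTI
#' @param mask a [roi_mask()].
#' @param path output file path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  write_label_volume(
    label_volume(array(as.integer(mask$mask), dim = mask$grid$shape),
                 mask$grid), path)
}

#' Write a scalar field (e.g. |E|) as NIfTI aligned to a grid
#' @param field numeric 3-D array.
#' @param grid the [voxel_grid()] the field lives on.
#' @param path output file path.
#' @export
write_field <- function(field, grid, path) {
  if (!identical(as.integer(dim(field)), grid$shape))
    stop("field dimensions do not match grid shape")
  field[is.na(field)] <- 0
  img <- RNifti::asNifti(field,
                         reference = list(pixdim = c(1, grid$spacing,
                                                     0, 0, 0, 0)),
                         datatype = "double")
  aff <- grid_affine(grid)
  RNifti::qform(img) <- structure(aff, code = 1L)
  RNifti::sform(img) <- structure(aff, code = 1L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

grid_affine <- function(grid) {
  aff <- diag(4)
  diag(aff)[1:3] <- grid$spacing
  aff[1:3, 4] <- grid$origin
  aff
}

grid_from_affine <- function(aff, shape) {
  rot <- aff[1:3, 1:3]
  offdiag <- rot - diag(diag(rot))
  if (any(abs(offdiag) > 1e-4 * max(abs(diag(rot)))))
    stop("NIfTI affine is not axis-aligned; reorient the volume first")
  spacing <- diag(rot)
  if (any(spacing <= 0))
    stop("NIfTI affine has non-positive or flipped spacing; expected RAS")
  voxel_grid(shape, spacing = spacing, origin = aff[1:3, 4])
}
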