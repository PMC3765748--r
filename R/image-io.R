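#' Volumetric image with a voxel-to-world affine
#'
#' Light container for 3D/4D image data used throughout the pipeline. The
#' affine maps 0-based voxel indices to world millimetres (NIfTI convention).
#'
#' @param data 3D or 4D numeric array.
#' @param affine 4x4 voxel-to-world matrix; must be invertible.
#' @return An object of class `brain_image` with elements `data` and `affine`.
#' @export
brain_image <- function(data, affine) {
  data <- as.array(data)
  if (!length(dim(data)) %in% c(3L, 4L))
    stop_named("data", "must be a 3D or 4D array")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) ||
      abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop_named("affine", "must be an invertible 4x4 matrix")
  structure(list(data = data, affine = affine), class = "brain_image")
}

#' @export
print.brain_image <- function(x, ...) {
  cat("<brain_image> ", paste(dim(x$data), collapse = " x "),
      " | voxel ", paste(signif(affine_voxel_size(x$affine), 4),
                         collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

as_brain_image <- function(x, affine = NULL) {
  if (inherits(x, "brain_image")) return(x)
  if (inherits(x, "niftiImage")) {
    return(brain_image(as.array(x), structure(RNifti::xform(x), dim = c(4L, 4L))))
  }
  if (is.array(x)) {
    if (is.null(affine))
      stop_named("affine", "required when constructing from a bare array")
    return(brain_image(x, affine))
  }
  if (is.character(x) && length(x) == 1L) return(read_volume(x))
  stop_named("image", "cannot interpret input as an image")
}

#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [brain_image].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_named("path", paste("no such file:", path))
  img <- RNifti::readNifti(path)
  as_brain_image(img)
}

#' Write a NIfTI volume
#'
#' The affine is stored in both the sform and qform so round-trips preserve it.
#'
#' @param image A [brain_image], or an array (then `affine` is required).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine Optional 4x4 affine when `image` is a bare array.
#' @param datatype NIfTI storage type, e.g. `"float"` or `"int16"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(image, path, affine = NULL, datatype = "float") {
  image <- as_brain_image(image, affine)
  img <- RNifti::asNifti(image$data)
  nd <- length(dim(image$data))
  RNifti::pixdim(img) <- c(affine_voxel_size(image$affine),
                           rep(1, nd - 3L))
  img <- RNifti::`sform<-`(img, structure(image$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(image$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' In-mask voxel-by-time matrix with grid geometry
#'
#' @param data Numeric matrix, one row per in-mask voxel, one column per frame.
#' @param mask 3D logical array; `sum(mask)` must equal `nrow(data)`. Rows are
#'   ordered by the linear (column-major) index of the mask voxels.
#' @param affine 4x4 voxel-to-world matrix.
#' @param tr_s Repetition time in seconds.
#' @param provenance Optional list describing the processing applied.
#' @return An object of class `voxel_ts`.
#' @export
voxel_ts <- function(data, mask, affine, tr_s, provenance = list()) {
  data <- as.matrix(data)
  mask <- array(as.logical(mask), dim(mask))
  if (length(dim(mask)) != 3L) stop_named("mask", "must be a 3D array")
  if (nrow(data) != sum(mask))
    stop_named("data", sprintf("row count (%d) must equal mask true-count (%d)",
                               nrow(data), sum(mask)))
  check_scalar(tr_s, "tr_s", lo = .Machine$double.eps)
  affine <- as.matrix(affine)
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop_named("affine", "must be invertible")
  structure(list(data = data, mask = mask, affine = affine, tr_s = tr_s,
                 provenance = provenance), class = "voxel_ts")
}

#' @export
print.voxel_ts <- function(x, ...) {
  cat("<voxel_ts> ", nrow(x$data), " voxels x ", ncol(x$data), " frames | TR ",
      x$tr_s, " s | grid ", paste(dim(x$mask), collapse = " x "), "\n", sep = "")
  invisible(x)
}

# Place per-voxel values back into a 3D array (background = `fill`).
map_to_array <- function(values, mask, fill = 0) {
  out <- array(fill, dim(mask))
  out[mask] <- values
  out
}
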