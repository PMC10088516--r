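#' 3D scalar volume with physical geometry
#'
#' A minimal container for an angiographic volume or phantom: a 3D intensity
#' array plus voxel spacing (mm) and the world coordinate of the corner voxel
#' centre. World coordinates are RAS-like with an identity direction matrix;
#' voxel `(i, j, k)` (1-based in R) has world position
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing_mm positive numeric of length 3, voxel size in mm.
#' @param origin_mm numeric of length 3, world position (mm) of voxel
#'   `(1, 1, 1)`'s centre.
#' @return An object of class `cv_volume`.
#' @export
cv_volume <- function(data, spacing_mm, origin_mm = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  if (any(spacing_mm <= 0)) stop("voxel spacing must be positive")
  structure(
    list(data = data, spacing = spacing_mm, origin = as.numeric(origin_mm),
         orientation = diag(3)),
    class = "cv_volume")
}

#' @export
print.cv_volume <- function(x, ...) {
  cat(sprintf("<cv_volume> %s voxels, spacing %s mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname cv_volume
#' @param x object to test.
#' @export
is_cv_volume <- function(x) inherits(x, "cv_volume")

# world coordinates of voxel centres given 1-based index matrix (n x 3)
voxel_to_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

# nearest voxel index (1-based, n x 3) for world-mm points
world_to_voxel <- function(vol, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  round(sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/")) + 1
}

#' Binary segmentation mask
#'
#' Voxel-aligned binary mask sharing geometry with its source volume, plus
#' provenance (seeds and thresholds used to grow it).
#'
#' @param data logical 3D array.
#' @param spacing_mm,origin_mm geometry, as in [cv_volume()].
#' @param provenance list describing how the mask was produced.
#' @return An object of class `cv_mask`.
#' @export
cv_mask <- function(data, spacing_mm, origin_mm = c(0, 0, 0), provenance = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3, is.logical(data))
  obj <- cv_volume(array(FALSE, dim(data)), spacing_mm, origin_mm)
  obj$data <- data
  obj$provenance <- provenance
  class(obj) <- c("cv_mask", "cv_volume")
  obj
}

#' @export
print.cv_mask <- function(x, ...) {
  cat(sprintf("<cv_mask> %s voxels, %d foreground (%.2f mm^3)\n",
              paste(dim(x$data), collapse = " x "), sum(x$data),
              sum(x$data) * prod(x$spacing)))
  invisible(x)
}

#' Voxel-count volume of a mask
#'
#' @param mask a [cv_mask()].
#' @return Foreground voxel count times voxel volume, in mm^3.
#' @export
mask_volume <- function(mask) sum(mask$data) * prod(mask$spacing)

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over \pkg{RNifti}. `write_volume` stores spacing in the
#' NIfTI pixdim and the origin in the sform translation; `read_volume`
#' recovers them. Masks are written as 0/1 integer volumes.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol a [cv_volume()] or [cv_mask()].
#' @return `read_volume` returns a [cv_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3) stop("expected a 3D NIfTI volume: ", path)
  xf <- RNifti::xform(img)
  sp <- sqrt(colSums(xf[seq_len(3), seq_len(3)]^2))
  org <- xf[seq_len(3), 4]
  cv_volume(arr, sp, org)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  arr <- vol$data
  if (is.logical(arr)) arr <- array(as.integer(arr), dim(arr))
  img <- RNifti::asNifti(arr)
  mat <- diag(4)
  diag(mat)[seq_len(3)] <- vol$spacing
  mat[seq_len(3), 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(mat, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
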