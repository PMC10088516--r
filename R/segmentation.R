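#' Region-growing lumen segmentation
#'
#' Grows the set of voxels with intensity in `[lower, upper]` that are
#' 26-connected to at least one seed. Bright-blood angiography makes the
#' lumen the high-intensity compartment, so the usual call fixes `lower`
#' (e.g. from [suggest_lower_threshold()]) and leaves `upper = Inf`.
#'
#' @param volume a [cv_volume()].
#' @param seeds integer matrix (n x 3) of 1-based voxel indices, or a single
#'   length-3 vector. Every seed must lie inside the grid and have intensity
#'   within `[lower, upper]`.
#' @param lower,upper inclusive intensity thresholds.
#' @return A [cv_mask()] with provenance recording seeds and thresholds.
#' @export
region_grow <- function(volume, seeds, lower, upper = Inf) {
  stopifnot(is_cv_volume(volume))
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 3, byrow = TRUE)
  seeds <- matrix(as.integer(round(seeds)), ncol = 3)
  dm <- dim(volume$data)
  for (s in seq_len(nrow(seeds))) {
    ijk <- seeds[s, ]
    if (any(ijk < 1) || any(ijk > dm))
      stop(sprintf("seed %d at (%s) lies outside the %s grid",
                   s, paste(ijk, collapse = ", "), paste(dm, collapse = " x ")))
    v <- volume$data[ijk[1], ijk[2], ijk[3]]
    if (v < lower || v > upper)
      stop(sprintf("seed %d at (%s) rejected: intensity %.4g outside [%.4g, %.4g]",
                   s, paste(ijk, collapse = ", "), v, lower, upper))
  }
  grown <- cpp_region_grow(as.numeric(volume$data), dm, seeds - 1L, lower, upper)
  maskarr <- array(grown, dm)
  if (!any(maskarr)) stop("region growing produced an empty mask")
  cv_mask(maskarr, volume$spacing, volume$origin,
          provenance = list(seeds = seeds, lower = lower, upper = upper))
}

#' Keep only the largest 26-connected component
#'
#' Removes noise islands after thresholded growth. Ties in component size are
#' broken in favour of the component containing the lexicographically
#' smallest voxel index.
#'
#' @param mask a nonempty [cv_mask()].
#' @return A [cv_mask()] of the single largest component.
#' @export
largest_connected_component <- function(mask) {
  stopifnot(inherits(mask, "cv_mask"))
  if (!any(mask$data)) stop("empty mask")
  lab <- cpp_label_components(as.logical(mask$data), dim(mask$data))
  sizes <- tabulate(lab)
  # labels are assigned in scan order, so which.max's first-max rule
  # implements the lexicographic tie-break
  keep <- which.max(sizes)
  out <- mask
  out$data <- array(lab == keep, dim(mask$data))
  out$provenance <- c(mask$provenance,
                      list(components = length(sizes), kept_size = sizes[keep]))
  out
}

#' Suggest a lower region-growing threshold from a background box
#'
#' The documented default threshold is `mean + 2 * SD` of the intensities in
#' a user-marked background box (a region known to contain no vessel).
#'
#' @param volume a [cv_volume()].
#' @param box integer vector `c(i0, i1, j0, j1, k0, k1)` of 1-based inclusive
#'   voxel index bounds of the background box.
#' @param k multiplier for the SD term (default 2).
#' @return The suggested lower threshold (numeric scalar).
#' @export
suggest_lower_threshold <- function(volume, box, k = 2) {
  stopifnot(is_cv_volume(volume), length(box) == 6)
  box <- as.integer(box)
  dm <- dim(volume$data)
  if (any(box[c(1, 3, 5)] < 1) || any(box[c(2, 4, 6)] > dm) ||
      any(box[c(1, 3, 5)] > box[c(2, 4, 6)]))
    stop("background box out of range")
  vals <- volume$data[box[1]:box[2], box[3]:box[4], box[5]:box[6]]
  mean(vals) + k * sd(as.numeric(vals))
}
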