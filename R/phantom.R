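#' Parametric tube specification
#'
#' Describes a synthetic vessel phantom: a tube of known radius swept along an
#' analytic centerline (straight cylinder, torus arc, circular helix, or a
#' Y-shaped bifurcation). The analytic curve gives exact ground truth for the
#' downstream morphometry: radius, curvature, torsion, and the circular
#' cross-section quantities (area, perimeter, min/max diameter, circularity).
#'
#' Closed forms used for ground truth: a torus arc of bend radius `R` has
#' curvature `1/R` and zero torsion; a helix `(a cos t, a sin t, b t)` has
#' curvature `a/(a^2+b^2)` and torsion `b/(a^2+b^2)`; straight segments have
#' both zero. A circular section of radius `r` has area `pi r^2`, perimeter
#' `2 pi r`, min = max diameter `2 r` and circularity 1.
#'
#' @param kind one of `"cylinder"`, `"torus_arc"`, `"helix"`, `"bifurcation"`.
#' @param radius_mm lumen radius (mm); for a bifurcation, length 1 (shared) or
#'   3 (parent, daughter 1, daughter 2).
#' @param length_mm cylinder / bifurcation-parent length (mm).
#' @param bend_radius_mm torus bend radius `R` (mm); must exceed `radius_mm`.
#' @param arc_deg torus arc angle in degrees.
#' @param coil_radius_mm helix coil radius `a` (mm).
#' @param pitch_mm helix pitch parameter `b` (mm per radian).
#' @param turns number of helix turns.
#' @param branch_angle_deg bifurcation daughter half-angle from the parent axis.
#' @param daughter_length_mm bifurcation daughter length (mm).
#' @param foreground_intensity,background_intensity intensities before noise.
#' @param noise_sigma Rician noise scale applied by [make_tube_phantom()];
#'   0 for a noiseless phantom.
#' @param pose optional rigid transform: `list(rotation = 3x3, translation =
#'   length-3)` applied to the canonical centerline.
#' @return An object of class `tube_spec`.
#' @export
tube_spec <- function(kind = c("cylinder", "torus_arc", "helix", "bifurcation"),
                      radius_mm = 2,
                      length_mm = 40,
                      bend_radius_mm = 10,
                      arc_deg = 180,
                      coil_radius_mm = 5,
                      pitch_mm = 2,
                      turns = 1.5,
                      branch_angle_deg = 35,
                      daughter_length_mm = 15,
                      foreground_intensity = 100,
                      background_intensity = 0,
                      noise_sigma = 0,
                      pose = NULL) {
  kind <- match.arg(kind)
  if (any(radius_mm <= 0)) stop("radius_mm must be positive")
  if (kind == "torus_arc" && bend_radius_mm <= max(radius_mm))
    stop("torus bend_radius_mm must exceed the lumen radius (self-intersection)")
  if (foreground_intensity <= background_intensity)
    stop("foreground_intensity must exceed background_intensity")
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative")
  if (kind == "bifurcation" && !length(radius_mm) %in% c(1, 3))
    stop("bifurcation radius_mm must have length 1 or 3")
  if (!is.null(pose)) {
    stopifnot(is.list(pose), is.matrix(pose$rotation),
              all(dim(pose$rotation) == c(3, 3)), length(pose$translation) == 3)
    if (max(abs(crossprod(pose$rotation) - diag(3))) > 1e-8)
      stop("pose$rotation must be orthonormal")
  }
  structure(list(kind = kind, radius_mm = radius_mm, length_mm = length_mm,
                 bend_radius_mm = bend_radius_mm, arc_deg = arc_deg,
                 coil_radius_mm = coil_radius_mm, pitch_mm = pitch_mm,
                 turns = turns, branch_angle_deg = branch_angle_deg,
                 daughter_length_mm = daughter_length_mm,
                 foreground_intensity = foreground_intensity,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma, pose = pose),
            class = "tube_spec")
}

# Analytic centerline branches of a spec, sampled at arclength step <= ds.
# Returns a list of branches: list(points = n x 3, radius = n, curvature = n,
# torsion = n, branch_id). Daughter branches of a bifurcation start exactly at
# the parent's last point (the shared junction).
tube_branches <- function(spec, ds) {
  r <- spec$radius_mm
  branches <- switch(spec$kind,
    cylinder = {
      n <- max(2L, ceiling(spec$length_mm / ds) + 1L)
      t <- seq(0, spec$length_mm, length.out = n)
      list(list(points = cbind(0, 0, t), radius = rep(r, n),
                curvature = rep(0, n), torsion = rep(0, n), branch_id = 1L))
    },
    torus_arc = {
      R <- spec$bend_radius_mm
      arc <- spec$arc_deg * pi / 180
      n <- max(2L, ceiling(R * arc / ds) + 1L)
      th <- seq(0, arc, length.out = n)
      list(list(points = cbind(R * cos(th), R * sin(th), 0),
                radius = rep(r, n),
                curvature = rep(1 / R, n), torsion = rep(0, n), branch_id = 1L))
    },
    helix = {
      a <- spec$coil_radius_mm; b <- spec$pitch_mm
      tmax <- 2 * pi * spec$turns
      speed <- sqrt(a^2 + b^2)
      n <- max(2L, ceiling(tmax * speed / ds) + 1L)
      th <- seq(0, tmax, length.out = n)
      list(list(points = cbind(a * cos(th), a * sin(th), b * th),
                radius = rep(r, n),
                curvature = rep(a / (a^2 + b^2), n),
                torsion = rep(b / (a^2 + b^2), n), branch_id = 1L))
    },
    bifurcation = {
      rr <- if (length(r) == 3) r else rep(r, 3)
      ang <- spec$branch_angle_deg * pi / 180
      np <- max(2L, ceiling(spec$length_mm / ds) + 1L)
      tp <- seq(0, spec$length_mm, length.out = np)
      junction <- c(0, 0, spec$length_mm)
      nd <- max(2L, ceiling(spec$daughter_length_mm / ds) + 1L)
      td <- seq(0, spec$daughter_length_mm, length.out = nd)
      d1 <- c(sin(ang), 0, cos(ang)); d2 <- c(-sin(ang), 0, cos(ang))
      list(
        list(points = cbind(0, 0, tp), radius = rep(rr[1], np),
             curvature = rep(0, np), torsion = rep(0, np), branch_id = 1L),
        list(points = cbind(junction[1] + td * d1[1], junction[2] + td * d1[2],
                            junction[3] + td * d1[3]),
             radius = rep(rr[2], nd), curvature = rep(0, nd),
             torsion = rep(0, nd), branch_id = 2L),
        list(points = cbind(junction[1] + td * d2[1], junction[2] + td * d2[2],
                            junction[3] + td * d2[3]),
             radius = rep(rr[3], nd), curvature = rep(0, nd),
             torsion = rep(0, nd), branch_id = 3L))
    })
  if (!is.null(spec$pose)) {
    branches <- lapply(branches, function(b) {
      b$points <- sweep(b$points %*% t(spec$pose$rotation), 2,
                        spec$pose$translation, "+")
      b
    })
  }
  branches
}

#' Generate a tube phantom volume with analytic ground truth
#'
#' Rasterises the tube by a voxel-centre membership test (a voxel is
#' foreground iff its centre lies within the local tube radius of the
#' analytic centerline; no anti-aliasing), so the voxel-count volume
#' converges to the analytic `pi r^2 L` as spacing shrinks. Ground truth is
#' sampled along the centerline at intervals no larger than the voxel
#' spacing.
#'
#' @param spec a [tube_spec()].
#' @param spacing_mm isotropic voxel size in mm (default 0.284, the target
#'   angiographic resolution).
#' @param shape optional voxel grid dimensions (length-3 integer). When
#'   omitted the grid is sized to fit the tube with `margin_vox` voxels of
#'   background on every side; when given, the tube is centred in the grid
#'   and must fit with at least a 2-voxel margin.
#' @param margin_vox background margin (voxels) used when `shape` is NULL.
#' @param seed RNG seed for the Rician noise stage (when
#'   `spec$noise_sigma > 0`).
#' @return A list with elements `volume` (a [cv_volume()]), `mask` (the
#'   noiseless rasterisation, a [cv_mask()] — the membership oracle), and
#'   `truth` (a data.frame of ground-truth centerline samples: branch_id,
#'   x/y/z mm, arclength_mm, radius_mm, curvature_per_mm, torsion_per_mm,
#'   area_mm2, perimeter_mm, min_diameter_mm, max_diameter_mm, circularity).
#' @export
make_tube_phantom <- function(spec, spacing_mm = 0.284, shape = NULL,
                              margin_vox = 4, seed = NULL) {
  stopifnot(inherits(spec, "tube_spec"))
  if (spacing_mm <= 0) stop("spacing_mm must be positive")
  if (min(spec$radius_mm) < 1.5 * spacing_mm)
    warning(sprintf("tube radius %.3g mm is below 1.5 voxels (%.3g mm): sub-resolution tube",
                    min(spec$radius_mm), 1.5 * spacing_mm))
  ds <- spacing_mm / 2
  branches <- tube_branches(spec, ds)
  allpts <- do.call(rbind, lapply(branches, `[[`, "points"))
  allrad <- unlist(lapply(branches, `[[`, "radius"))
  lo <- apply(allpts - allrad, 2, min)
  hi <- apply(allpts + allrad, 2, max)
  if (is.null(shape)) {
    # half-voxel offset keeps analytic symmetry axes off the voxel-centre
    # lattice (avoids Gauss-circle resonance in the voxel-count volume)
    origin <- lo - (margin_vox + 0.5) * spacing_mm
    shape <- as.integer(ceiling((hi - origin) / spacing_mm)) + margin_vox + 1L
  } else {
    shape <- as.integer(shape)
    stopifnot(length(shape) == 3)
    extent <- (shape - 1) * spacing_mm
    centre <- (lo + hi) / 2
    origin <- centre - extent / 2
    slack <- pmin(lo - origin, origin + extent - hi)
    if (any(slack < 2 * spacing_mm)) {
      ax <- which.min(slack)
      stop(sprintf(
        "tube exits the volume along axis %d: extent %.2f..%.2f mm needs > %.2f mm grid span plus a 2-voxel margin",
        ax, lo[ax], hi[ax], hi[ax] - lo[ax]))
    }
  }
  ends_of <- lapply(branches, function(b) b$points[nrow(b$points), ])
  maskvec <- NULL
  for (b in branches) {
    bm <- cpp_rasterize_tube(b$points, b$radius, shape,
                             rep(spacing_mm, 3), origin, NULL)
    # clip the spherical end caps back to flat end planes so the voxel
    # count tracks the analytic pi r^2 L; a daughter branch keeps its start
    # cap, which fills the wedge at the junction with its parent
    barr <- array(bm, shape)
    np <- nrow(b$points)
    t0 <- b$points[2, ] - b$points[1, ]
    t1 <- b$points[np, ] - b$points[np - 1, ]
    is_daughter <- any(vapply(ends_of, function(e)
      sum(abs(e - b$points[1, ])) < 1e-9, TRUE))
    marked <- which(barr, arr.ind = TRUE)
    w <- sweep(sweep(marked - 1, 2, rep(spacing_mm, 3), "*"), 2, origin, "+")
    # only voxels inside the cap ball are candidates — the end plane must
    # not clip unrelated parts of a coiled tube
    d1 <- sweep(w, 2, b$points[np, ], "-")
    beyond <- (d1 %*% t1 > 0) & (rowSums(d1^2) <= (b$radius[np] + spacing_mm)^2)
    if (!is_daughter) {
      d0 <- sweep(w, 2, b$points[1, ], "-")
      beyond <- beyond |
        ((d0 %*% t0 < 0) & (rowSums(d0^2) <= (b$radius[1] + spacing_mm)^2))
    }
    barr[marked[beyond, , drop = FALSE]] <- FALSE
    maskvec <- if (is.null(maskvec)) as.logical(barr) else maskvec | as.logical(barr)
  }
  maskarr <- array(maskvec, shape)
  mask <- cv_mask(maskarr, spacing_mm, origin,
                  provenance = list(source = "phantom", kind = spec$kind))
  inten <- array(spec$background_intensity, shape)
  inten[maskarr] <- spec$foreground_intensity
  vol <- cv_volume(inten, spacing_mm, origin)
  if (spec$noise_sigma > 0)
    vol <- add_acquisition_noise(vol, spec$noise_sigma, seed = seed)
  truth <- do.call(rbind, lapply(branches, function(b) {
    # ground-truth table at <= spacing_mm intervals
    keep <- unique(c(seq(1, nrow(b$points), by = 2L), nrow(b$points)))
    p <- b$points[keep, , drop = FALSE]
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    r <- b$radius[keep]
    data.frame(branch_id = b$branch_id,
               x = p[, 1], y = p[, 2], z = p[, 3],
               arclength_mm = c(0, cumsum(seg)),
               radius_mm = r,
               curvature_per_mm = b$curvature[keep],
               torsion_per_mm = b$torsion[keep],
               area_mm2 = pi * r^2,
               perimeter_mm = 2 * pi * r,
               min_diameter_mm = 2 * r,
               max_diameter_mm = 2 * r,
               circularity = 1)
  }))
  rownames(truth) <- NULL
  list(volume = vol, mask = mask, truth = truth)
}

#' Add Rician acquisition noise
#'
#' Magnitude-MR noise: each voxel value `v` becomes
#' `sqrt((v + sigma*X)^2 + (sigma*Y)^2)` with independent standard normal
#' `X, Y`. `sigma = 0` returns the input unchanged. Reproducible for a given
#' seed; the caller's RNG state is left untouched.
#'
#' @param volume a [cv_volume()].
#' @param sigma nonnegative Rician scale.
#' @param seed integer RNG seed.
#' @return A noise-corrupted copy of `volume`.
#' @export
add_acquisition_noise <- function(volume, sigma, seed = NULL) {
  stopifnot(is_cv_volume(volume))
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) return(volume)
  n <- length(volume$data)
  noisy <- with_seed(seed, {
    sqrt((volume$data + sigma * rnorm(n))^2 + (sigma * rnorm(n))^2)
  })
  out <- volume
  out$data <- array(noisy, dim(volume$data))
  out
}
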