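#' Branch centerlines with maximal-inscribed-sphere radii
#'
#' `compute_centerline` traces, for each (source, target) endpoint pair, the
#' minimal-cost path through the 26-connected foreground voxel graph with
#' edge cost `length / d^4`, where `d` is the Euclidean distance transform
#' (distance to the lumen boundary) averaged over the edge's endpoints. The
#' inverse-power weighting drives the path onto the ridge of the distance
#' transform — the locus of maximal inscribed spheres — strongly enough
#' that bends are not corner-cut. Paths sharing a source are merged into a
#' tree at their divergence points. Each point is then recentered to
#' sub-voxel accuracy as the in-plane centroid of the lumen in the plane
#' perpendicular to the local tangent (followed by a light Laplacian pass
#' that removes the transverse sawtooth of oblique voxel runs), and the
#' maximal-inscribed-sphere radius (misr) is the exact distance from the
#' point to the nearest background voxel centre.
#'
#' @param mask a [cv_mask()]; must be a single connected component for paths
#'   to exist between all endpoint pairs.
#' @param endpoints a list of endpoint pairs; each element is a 2 x 3 matrix
#'   (rows: source, target, world mm) or a length-6 vector
#'   `c(source, target)`. A single pair may be given directly.
#' @param recenter logical; apply in-plane centroid recentering (default TRUE).
#' @param recenter_iters number of recentering sweeps.
#' @return An object of class `cv_centerline`: a list of branches, each with
#'   `id`, `points` (n x 3 mm), `misr_mm`, `arclength_mm`, `parent` (branch
#'   id or NA). Attribute `pitch_mm` is set after resampling.
#' @export
compute_centerline <- function(mask, endpoints, recenter = TRUE,
                               recenter_iters = 3) {
  stopifnot(inherits(mask, "cv_mask"))
  pairs <- normalize_endpoints(endpoints)
  dm <- dim(mask$data)
  edt <- array(cpp_edt(as.logical(mask$data), dm, mask$spacing), dm)
  g <- cpp_voxel_graph(as.logical(mask$data), dm, mask$spacing)
  dvals <- edt[g$fg_linear]
  # quartic penalty: corner-cutting through low-clearance voxels must cost
  # more than the length saved, or paths hug the inner wall of bends
  w <- g$length / pmax((dvals[g$from] + dvals[g$to]) / 2, 1e-6)^4
  graph <- igraph::make_graph(rbind(g$from, g$to), n = length(g$fg_linear),
                              directed = FALSE)
  fg_index <- integer(prod(dm))
  fg_index[g$fg_linear] <- seq_along(g$fg_linear)

  snap <- function(pt, what) {
    ijk <- world_to_voxel(list(spacing = mask$spacing, origin = mask$origin), pt)
    ijk <- pmin(pmax(ijk, 1L), matrix(dm, 1))
    linid <- ijk[1] + dm[1] * ((ijk[2] - 1) + dm[2] * (ijk[3] - 1))
    if (!mask$data[linid]) {
      # tolerate endpoints a rounding step off the lumen (e.g. on the
      # surface): snap to the nearest foreground voxel within 2 voxels
      rng <- lapply(1:3, function(d) max(1, ijk[d] - 2):min(dm[d], ijk[d] + 2))
      cand <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
      lc <- cand[, 1] + dm[1] * ((cand[, 2] - 1) + dm[2] * (cand[, 3] - 1))
      fg <- mask$data[lc]
      if (!any(fg))
        stop(sprintf("%s endpoint (%s) mm lies outside the mask", what,
                     paste(signif(pt, 4), collapse = ", ")))
      cw <- sweep(sweep(cand[fg, , drop = FALSE] - 1, 2, mask$spacing, "*"),
                  2, mask$origin, "+")
      best <- which.min(colSums((t(cw) - as.numeric(pt))^2))
      linid <- lc[fg][best]
    }
    fg_index[linid]
  }
  paths <- lapply(seq_along(pairs), function(p) {
    src <- snap(pairs[[p]][1, ], "source")
    tgt <- snap(pairs[[p]][2, ], "target")
    if (src == tgt)
      stop("degenerate endpoint pair: source and target snap to the same voxel")
    sp <- igraph::shortest_paths(graph, from = src, to = tgt, weights = w,
                                 output = "vpath")
    vp <- as.integer(sp$vpath[[1]])
    if (length(vp) == 0)
      stop("no path between endpoints: mask is disconnected between them")
    vp
  })
  branches <- merge_paths_to_tree(paths)
  vol_like <- list(spacing = mask$spacing, origin = mask$origin)
  for (b in seq_along(branches)) {
    linids <- g$fg_linear[branches[[b]]$voxels]
    k <- (linids - 1) %/% (dm[1] * dm[2])
    r <- (linids - 1) %% (dm[1] * dm[2])
    idx <- cbind(r %% dm[1] + 1, r %/% dm[1] + 1, k + 1)
    branches[[b]]$points <- voxel_to_world(vol_like, idx)
  }
  if (recenter) branches <- recenter_branches(branches, mask, edt, recenter_iters)
  hv <- mean(mask$spacing) / 2
  for (b in seq_along(branches)) {
    pts <- branches[[b]]$points
    # exact point-to-background distance (interpolated EDT clips the ridge
    # apex); for a tube many background centres graze the lumen surface, so
    # the minimum itself is already a tight surface-distance estimate
    guess <- trilinear(edt, mask$spacing, mask$origin, pts) + 2 * hv + 2 * max(mask$spacing)
    dbg <- cpp_min_bg_dist(as.logical(mask$data), dim(mask$data), mask$spacing,
                           mask$origin, pts, guess)
    branches[[b]]$misr_mm <- pmax(dbg, 1e-3)
    seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
    branches[[b]]$arclength_mm <- c(0, cumsum(seg))
    branches[[b]]$voxels <- NULL
  }
  structure(list(branches = branches), class = "cv_centerline")
}

normalize_endpoints <- function(endpoints) {
  if (is.matrix(endpoints) && nrow(endpoints) == 2) endpoints <- list(endpoints)
  if (is.numeric(endpoints) && !is.matrix(endpoints) && length(endpoints) == 6)
    endpoints <- list(matrix(endpoints, 2, 3, byrow = TRUE))
  lapply(endpoints, function(e) {
    if (!is.matrix(e) && is.numeric(e) && length(e) == 6)
      e <- matrix(e, 2, 3, byrow = TRUE)
    e <- unname(as.matrix(e))
    stopifnot(is.matrix(e), all(dim(e) == c(2, 3)))
    e
  })
}

# Merge voxel-id paths into a branch tree: paths sharing a source are split
# at divergence points; the shared prefix becomes the parent branch.
merge_paths_to_tree <- function(paths) {
  branches <- list()
  nextid <- 0L
  add_group <- function(group, parent, start_offset) {
    # group: list of integer voxel-id paths sharing their first voxel
    if (length(group) == 1) {
      nextid <<- nextid + 1L
      branches[[nextid]] <<- list(id = nextid, voxels = group[[1]], parent = parent)
      return(invisible(NULL))
    }
    lens <- vapply(group, length, 1L)
    lcp <- 1L
    while (lcp < min(lens)) {
      nxt <- vapply(group, function(p) p[lcp + 1L], 1L)
      if (length(unique(nxt)) > 1) break
      lcp <- lcp + 1L
    }
    nextid <<- nextid + 1L
    myid <- nextid
    branches[[myid]] <<- list(id = myid, voxels = group[[1]][seq_len(lcp)],
                              parent = parent)
    rest <- lapply(group, function(p) p[lcp:length(p)]) # keep junction voxel
    rest <- rest[vapply(rest, length, 1L) > 1]
    if (length(rest)) {
      key <- vapply(rest, function(p) p[2L], 1L)
      for (k in unique(key)) add_group(rest[key == k], myid, lcp)
    }
  }
  firsts <- vapply(paths, `[`, 1L, 1L)
  for (f in unique(firsts)) add_group(paths[firsts == f], NA_integer_, 0L)
  branches
}

# In-plane lumen centroid recentering. Daughter branches keep their first
# point welded to the parent's matching point.
recenter_branches <- function(branches, mask, edt, iters) {
  maskd <- array(as.numeric(mask$data), dim(mask$data))
  for (it in seq_len(iters)) {
    for (b in seq_along(branches)) {
      pts <- branches[[b]]$points
      n <- nrow(pts)
      if (n < 3) next
      for (i in seq_len(n)) {
        # wide tangent stencil: voxel paths zig-zag along oblique runs and
        # nearest-neighbour tangents flip direction step to step
        i0 <- max(1, i - 3); i1 <- min(n, i + 3)
        tg <- pts[i1, ] - pts[i0, ]
        tl <- sqrt(sum(tg^2))
        if (tl < 1e-9) next
        tg <- tg / tl
        basis <- plane_basis(tg)
        # window must span the whole cross-section even when the current
        # point sits off-centre, so scale by twice the local clearance
        rad <- 2 * trilinear(edt, mask$spacing, mask$origin, matrix(pts[i, ], 1)) +
          3 * mean(mask$spacing)
        step <- mean(mask$spacing) / 2
        offs <- seq(-rad, rad, by = step)
        grid <- expand.grid(u = offs, v = offs)
        keep <- grid$u^2 + grid$v^2 <= rad^2
        grid <- grid[keep, ]
        samp <- sweep(outer(grid$u, basis$u) + outer(grid$v, basis$v), 2,
                      pts[i, ], "+")
        vals <- trilinear(maskd, mask$spacing, mask$origin, samp)
        inside <- vals >= 0.5
        if (sum(inside) < 3) next
        cu <- mean(grid$u[inside]); cv <- mean(grid$v[inside])
        pts[i, ] <- pts[i, ] + cu * basis$u + cv * basis$v
      }
      branches[[b]]$points <- pts
    }
    # weld daughters to their parent's junction point
    for (b in seq_along(branches)) {
      p <- branches[[b]]$parent
      if (!is.na(p))
        branches[[b]]$points[1, ] <- branches[[p]]$points[nrow(branches[[p]]$points), ]
    }
  }
  # light Laplacian pass (ends fixed) removes residual transverse sawtooth
  # before arclength parameterisation
  for (pass in 1:2) {
    for (b in seq_along(branches)) {
      pts <- branches[[b]]$points
      n <- nrow(pts)
      if (n < 3) next
      inner <- 2:(n - 1)
      pts[inner, ] <- 0.25 * pts[inner - 1, ] + 0.5 * pts[inner, ] +
        0.25 * pts[inner + 1, ]
      branches[[b]]$points <- pts
    }
    for (b in seq_along(branches)) {
      p <- branches[[b]]$parent
      if (!is.na(p))
        branches[[b]]$points[1, ] <- branches[[p]]$points[nrow(branches[[p]]$points), ]
    }
  }
  branches
}

plane_basis <- function(tangent) {
  a <- if (abs(tangent[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * tangent) * tangent
  u <- u / sqrt(sum(u^2))
  v <- c(tangent[2] * u[3] - tangent[3] * u[2],
         tangent[3] * u[1] - tangent[1] * u[3],
         tangent[1] * u[2] - tangent[2] * u[1])
  list(u = u, v = v)
}

# Trilinear interpolation of a 3D array at world-mm points (n x 3).
trilinear <- function(arr, spacing, origin, pts) {
  pts <- matrix(pts, ncol = 3)
  dm <- dim(arr)
  fx <- (pts[, 1] - origin[1]) / spacing[1]
  fy <- (pts[, 2] - origin[2]) / spacing[2]
  fz <- (pts[, 3] - origin[3]) / spacing[3]
  i0 <- pmin(pmax(floor(fx), 0), dm[1] - 2); wx <- pmin(pmax(fx - i0, 0), 1)
  j0 <- pmin(pmax(floor(fy), 0), dm[2] - 2); wy <- pmin(pmax(fy - j0, 0), 1)
  k0 <- pmin(pmax(floor(fz), 0), dm[3] - 2); wz <- pmin(pmax(fz - k0, 0), 1)
  at <- function(di, dj, dk)
    arr[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  (1 - wz) * ((1 - wy) * ((1 - wx) * at(0, 0, 0) + wx * at(1, 0, 0)) +
              wy * ((1 - wx) * at(0, 1, 0) + wx * at(1, 1, 0))) +
    wz * ((1 - wy) * ((1 - wx) * at(0, 0, 1) + wx * at(1, 0, 1)) +
          wy * ((1 - wx) * at(0, 1, 1) + wx * at(1, 1, 1)))
}

#' @export
print.cv_centerline <- function(x, ...) {
  cat(sprintf("<cv_centerline> %d branch(es)\n", length(x$branches)))
  for (b in x$branches)
    cat(sprintf("  branch %d: %d points, length %.2f mm, parent %s\n",
                b$id, nrow(b$points), max(b$arclength_mm),
                ifelse(is.na(b$parent), "-", b$parent)))
  invisible(x)
}

#' Resample a centerline at uniform arclength pitch
#'
#' Fits a natural cubic spline through each branch's points (per coordinate,
#' parameterised by arclength) and resamples at `n = round(L / pitch) + 1`
#' exactly uniform intervals, preserving both endpoints. The misr profile is
#' re-interpolated at the new stations. Branches shorter than `2 * pitch`
#' are dropped with a warning.
#'
#' @param cl a `cv_centerline`.
#' @param pitch_mm target spacing between neighbouring points (default
#'   0.284 mm, the study's segment pitch).
#' @return A resampled `cv_centerline` with attribute `pitch_mm`.
#' @export
resample_centerline <- function(cl, pitch_mm = 0.284) {
  stopifnot(inherits(cl, "cv_centerline"), pitch_mm > 0)
  out <- list()
  for (b in cl$branches) {
    L <- max(b$arclength_mm)
    if (L < 2 * pitch_mm) {
      warning(sprintf("branch %d dropped: length %.3g mm < 2 * pitch (%.3g mm)",
                      b$id, L, 2 * pitch_mm))
      next
    }
    s <- b$arclength_mm
    fx <- splinefun(s, b$points[, 1], method = "natural")
    fy <- splinefun(s, b$points[, 2], method = "natural")
    fz <- splinefun(s, b$points[, 3], method = "natural")
    # arclength of the spline itself, by dense sampling
    sf <- seq(0, L, length.out = max(20 * length(s), 200))
    pf <- cbind(fx(sf), fy(sf), fz(sf))
    seg <- sqrt(rowSums((pf[-1, , drop = FALSE] - pf[-nrow(pf), , drop = FALSE])^2))
    cum <- c(0, cumsum(seg))
    Ltrue <- cum[length(cum)]
    n <- max(3L, round(Ltrue / pitch_mm) + 1L)
    starget <- seq(0, Ltrue, length.out = n)
    tpar <- approx(cum, sf, xout = starget, ties = "ordered")$y
    pts <- cbind(fx(tpar), fy(tpar), fz(tpar))
    pts[1, ] <- b$points[1, ]
    pts[n, ] <- b$points[nrow(b$points), ]
    misr <- approx(s, b$misr_mm, xout = pmin(pmax(tpar, 0), L), rule = 2)$y
    nb <- b
    nb$points <- pts
    nb$misr_mm <- misr
    nb$arclength_mm <- starget
    out[[length(out) + 1]] <- nb
  }
  if (!length(out)) stop("all branches shorter than 2 * pitch: nothing to resample")
  structure(list(branches = out), class = "cv_centerline",
            pitch_mm = pitch_mm)
}

#' Frenet curvature and torsion along a centerline
#'
#' Curvature `kappa = |r' x r''| / |r'|^3` and torsion
#' `tau = ((r' x r'') . r''') / |r' x r''|^2`, with derivatives taken from a
#' moving local polynomial fit of the points against arclength (degree
#' `degree`, window half-width `smoothing` mm). Local polynomial
#' differentiation suppresses the voxel-snapping jitter that dominates raw
#' finite differences. Windows are clipped at branch ends, giving one-sided
#' stencils there. Where `|r' x r''|` falls below tolerance the segment is
#' flagged straight and torsion is reported as 0.
#'
#' @param cl a resampled `cv_centerline` (each branch needs >= 5 points).
#' @param smoothing window half-width in mm (default 3).
#' @param degree polynomial degree (default 5 — an odd degree avoids the
#'   truncation bias of even degrees in the third derivative; capped by
#'   window size).
#' @return data.frame with columns `branch_id`, `point`, `curvature_per_mm`,
#'   `torsion_per_mm`, `straight`, plus unit tangents `tx`, `ty`, `tz`.
#' @export
frenet_features <- function(cl, smoothing = 4, degree = 5) {
  stopifnot(inherits(cl, "cv_centerline"), smoothing > 0)
  res <- list()
  for (b in cl$branches) {
    n <- nrow(b$points)
    if (n < 5) stop(sprintf("branch %d has %d points; >= 5 required", b$id, n))
    s <- b$arclength_mm
    kap <- tau <- numeric(n)
    straight <- logical(n)
    tans <- matrix(0, n, 3)
    minpts <- degree + 2L
    for (i in seq_len(n)) {
      win <- which(abs(s - s[i]) <= smoothing)
      if (length(win) < minpts) {
        half <- ceiling(minpts / 2)
        lo <- max(1L, i - half); hi <- min(n, lo + minpts - 1L)
        lo <- max(1L, hi - minpts + 1L)
        win <- lo:hi
      }
      d <- min(degree, length(win) - 2L)
      u <- s[win] - s[i]
      X <- outer(u, 0:d, "^")
      cf <- qr.solve(qr(X), b$points[win, , drop = FALSE])
      r1 <- cf[2, ]
      r2 <- if (d >= 2) 2 * cf[3, ] else c(0, 0, 0)
      r3 <- if (d >= 3) 6 * cf[4, ] else c(0, 0, 0)
      cr <- c(r1[2] * r2[3] - r1[3] * r2[2],
              r1[3] * r2[1] - r1[1] * r2[3],
              r1[1] * r2[2] - r1[2] * r2[1])
      ncr <- sqrt(sum(cr^2))
      nr1 <- sqrt(sum(r1^2))
      tans[i, ] <- r1 / max(nr1, 1e-12)
      kap[i] <- ncr / max(nr1, 1e-12)^3
      if (ncr < 1e-8) {
        tau[i] <- 0
        straight[i] <- TRUE
      } else {
        tau[i] <- sum(cr * r3) / ncr^2
      }
    }
    res[[length(res) + 1]] <- data.frame(
      branch_id = b$id, point = seq_len(n),
      curvature_per_mm = kap, torsion_per_mm = tau, straight = straight,
      tx = tans[, 1], ty = tans[, 2], tz = tans[, 3])
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
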