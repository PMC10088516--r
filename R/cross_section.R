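#' Planar cross-section contour of a surface mesh
#'
#' Intersects the luminal surface with the plane through `point` normal to
#' `tangent`. The intersection of a watertight triangle mesh with a plane is
#' a set of closed polylines; the one enclosing `point` (the lumen contour at
#' that centerline station) is returned as a counterclockwise-ordered polygon
#' in in-plane coordinates.
#'
#' @param mesh a `cv_mesh` from [extract_surface()].
#' @param point world-mm position on/near the centerline (length 3).
#' @param tangent plane normal (the local centerline tangent); need not be
#'   unit length but must be nonzero.
#' @return An n x 2 matrix of in-plane mm coordinates (origin at `point`),
#'   counterclockwise, with attributes `basis` (the in-plane axes) and
#'   `point`.
#' @export
cross_section_contour <- function(mesh, point, tangent) {
  point <- as.numeric(point)
  tangent <- as.numeric(tangent)
  tl <- sqrt(sum(tangent^2))
  if (tl < 1e-12) stop("tangent must be nonzero")
  tangent <- tangent / tl
  V <- mesh$vertices
  d <- (V[, 1] - point[1]) * tangent[1] + (V[, 2] - point[2]) * tangent[2] +
    (V[, 3] - point[3]) * tangent[3]
  d[d == 0] <- 1e-12
  tr <- mesh$triangles
  da <- d[tr[, 1]]; db <- d[tr[, 2]]; dc <- d[tr[, 3]]
  crossing <- (pmin(da, db, dc) < 0) & (pmax(da, db, dc) > 0)
  if (!any(crossing)) stop("plane does not intersect the mesh")
  tr <- tr[crossing, , drop = FALSE]
  # for each crossing triangle, its two crossed edges and intersection points
  seg_keys <- matrix(NA_character_, nrow(tr), 2)
  seg_pts <- array(NA_real_, c(nrow(tr), 2, 3))
  edge_pairs <- rbind(c(1, 2), c(2, 3), c(3, 1))
  for (ti in seq_len(nrow(tr))) {
    got <- 0L
    for (e in 1:3) {
      a <- tr[ti, edge_pairs[e, 1]]; b <- tr[ti, edge_pairs[e, 2]]
      if (d[a] * d[b] < 0) {
        got <- got + 1L
        t <- d[a] / (d[a] - d[b])
        seg_pts[ti, got, ] <- V[a, ] + t * (V[b, ] - V[a, ])
        seg_keys[ti, got] <- paste(min(a, b), max(a, b))
      }
      if (got == 2L) break
    }
  }
  ok <- !is.na(seg_keys[, 2])
  seg_keys <- seg_keys[ok, , drop = FALSE]
  seg_pts <- seg_pts[ok, , , drop = FALSE]
  loops <- chain_segments(seg_keys, seg_pts)
  if (!length(loops)) stop("no closed intersection loop (boundary-touching mesh?)")
  basis <- plane_basis(tangent)
  enclosing <- NULL
  for (lp in loops) {
    uv <- cbind((lp[, 1] - point[1]) * basis$u[1] + (lp[, 2] - point[2]) * basis$u[2] +
                  (lp[, 3] - point[3]) * basis$u[3],
                (lp[, 1] - point[1]) * basis$v[1] + (lp[, 2] - point[2]) * basis$v[2] +
                  (lp[, 3] - point[3]) * basis$v[3])
    if (point_in_polygon(0, 0, uv)) { enclosing <- uv; break }
  }
  if (is.null(enclosing))
    stop("no intersection loop encloses the point: point outside the lumen")
  if (shoelace(enclosing) < 0) enclosing <- enclosing[rev(seq_len(nrow(enclosing))), ]
  attr(enclosing, "basis") <- basis
  attr(enclosing, "point") <- point
  enclosing
}

# chain plane-triangle segments into closed loops via shared mesh-edge keys
chain_segments <- function(seg_keys, seg_pts) {
  ns <- nrow(seg_keys)
  used <- logical(ns)
  # map edge key -> segment indices (each interior edge appears in 2 segments)
  keymap <- split(rep(seq_len(ns), 2), c(seg_keys[, 1], seg_keys[, 2]))
  loops <- list()
  for (s0 in seq_len(ns)) {
    if (used[s0]) next
    pts <- list()
    cur <- s0; enter_key <- seg_keys[s0, 1]
    closed <- FALSE
    repeat {
      used[cur] <- TRUE
      exit_key <- if (seg_keys[cur, 1] == enter_key) seg_keys[cur, 2] else seg_keys[cur, 1]
      exit_slot <- if (seg_keys[cur, 1] == exit_key) 1 else 2
      pts[[length(pts) + 1]] <- seg_pts[cur, exit_slot, ]
      cand <- keymap[[exit_key]]
      cand <- cand[!used[cand]]
      if (!length(cand)) {
        closed <- exit_key == seg_keys[s0, 1]
        break
      }
      cur <- cand[1]
      enter_key <- exit_key
    }
    if (closed && length(pts) >= 3)
      loops[[length(loops) + 1]] <- do.call(rbind, pts)
  }
  loops
}

shoelace <- function(uv) {
  n <- nrow(uv)
  j <- c(2:n, 1)
  sum(uv[, 1] * uv[j, 2] - uv[j, 1] * uv[, 2]) / 2
}

point_in_polygon <- function(px, py, uv) {
  n <- nrow(uv)
  j <- c(n, seq_len(n - 1))
  xi <- uv[, 1]; yi <- uv[, 2]; xj <- uv[j, 1]; yj <- uv[j, 2]
  cross <- ((yi > py) != (yj > py)) &
    (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
  sum(cross) %% 2 == 1
}

#' Morphometric quantities of a planar contour
#'
#' Area by the shoelace formula, perimeter as the edge-length sum, minimal
#' and maximal diameter as the min/max Feret (caliper) widths of the convex
#' hull, their ratio, and circularity `4 pi A / P^2` (the isoperimetric
#' ratio: 1 for a circle, below 1 otherwise).
#'
#' @param polygon n x 2 matrix (n >= 3) of planar mm coordinates; must be
#'   simple (non-self-intersecting).
#' @param check verify simplicity (O(n^2); disable for contours known simple
#'   by construction).
#' @return A one-row data.frame: `area_mm2`, `perimeter_mm`,
#'   `min_diameter_mm`, `max_diameter_mm`, `min_max_ratio`, `circularity`.
#' @export
contour_metrics <- function(polygon, check = TRUE) {
  polygon <- matrix(as.numeric(polygon), ncol = 2)
  n <- nrow(polygon)
  if (n < 3) stop("polygon needs at least 3 vertices")
  if (check && !is_simple_polygon(polygon)) stop("self-intersecting polygon")
  A <- abs(shoelace(polygon))
  if (A < 1e-9) stop("near-zero contour area")
  j <- c(2:n, 1)
  P <- sum(sqrt(rowSums((polygon[j, ] - polygon)^2)))
  hull <- polygon[grDevices::chull(polygon), , drop = FALSE]
  maxf <- sqrt(max(dist2_all(hull)))
  minf <- min_feret(hull)
  data.frame(area_mm2 = A, perimeter_mm = P,
             min_diameter_mm = minf, max_diameter_mm = maxf,
             min_max_ratio = minf / maxf,
             circularity = 4 * pi * A / P^2)
}

dist2_all <- function(p) {
  g <- rowSums(p^2)
  d2 <- outer(g, g, "+") - 2 * tcrossprod(p)
  pmax(d2, 0)
}

# minimal caliper width of a convex polygon: min over hull edges of the
# maximal vertex distance from the edge's supporting line
min_feret <- function(hull) {
  n <- nrow(hull)
  if (n == 2) return(0)
  j <- c(2:n, 1)
  e <- hull[j, ] - hull
  len <- sqrt(rowSums(e^2))
  keep <- len > 1e-12
  widths <- vapply(which(keep), function(i) {
    nrm <- c(-e[i, 2], e[i, 1]) / len[i]
    proj <- (hull[, 1] - hull[i, 1]) * nrm[1] + (hull[, 2] - hull[i, 2]) * nrm[2]
    max(abs(proj))
  }, 0)
  min(widths)
}

is_simple_polygon <- function(p) {
  n <- nrow(p)
  a <- p; b <- p[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)] # skip segments adjacent to i
    if (!length(js)) next
    if (any(segments_cross(a[i, ], b[i, ], a[js, , drop = FALSE],
                           b[js, , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

segments_cross <- function(p1, p2, q1, q2) {
  d1 <- (p2[1] - p1[1]) * (q1[, 2] - p1[2]) - (p2[2] - p1[2]) * (q1[, 1] - p1[1])
  d2 <- (p2[1] - p1[1]) * (q2[, 2] - p1[2]) - (p2[2] - p1[2]) * (q2[, 1] - p1[1])
  d3 <- (q2[, 1] - q1[, 1]) * (p1[2] - q1[, 2]) - (q2[, 2] - q1[, 2]) * (p1[1] - q1[, 1])
  d4 <- (q2[, 1] - q1[, 1]) * (p2[2] - q1[, 2]) - (q2[, 2] - q1[, 2]) * (p2[1] - q1[, 1])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Per-point morphological feature table
#'
#' Combines, at every resampled centerline point, the maximal inscribed
#' sphere radius, the cross-section contour metrics and the Frenet
#' curvature/torsion into the nine-feature record used for territory
#' summaries. Points whose contour extraction fails (e.g. at a bifurcation
#' apex) are recorded as missing rather than dropped; a branch with more
#' than `max_missing_frac` failed points raises a quality error.
#'
#' @param mesh a `cv_mesh` of the lumen.
#' @param cl a resampled `cv_centerline` lying inside the mesh.
#' @param smoothing Frenet window half-width in mm (see [frenet_features()]).
#' @param max_missing_frac maximal tolerated fraction of failed points per
#'   branch (default 0.2).
#' @return data.frame with one row per centerline point: `branch_id`,
#'   `point`, `arclength_mm`, the nine features (`area_mm2`, `misr_mm`,
#'   `min_diameter_mm`, `max_diameter_mm`, `min_max_ratio`,
#'   `curvature_per_mm`, `torsion_per_mm`, `perimeter_mm`, `circularity`)
#'   and a logical `missing` flag.
#' @export
point_features <- function(mesh, cl, smoothing = 4, max_missing_frac = 0.2) {
  stopifnot(inherits(mesh, "cv_mesh"), inherits(cl, "cv_centerline"))
  fren <- frenet_features(cl, smoothing = smoothing)
  rows <- list()
  for (b in cl$branches) {
    fb <- fren[fren$branch_id == b$id, ]
    n <- nrow(b$points)
    nfail <- 0L
    for (i in seq_len(n)) {
      met <- tryCatch({
        poly <- cross_section_contour(mesh, b$points[i, ],
                                      c(fb$tx[i], fb$ty[i], fb$tz[i]))
        contour_metrics(poly, check = FALSE)
      }, error = function(e) NULL)
      if (is.null(met)) {
        nfail <- nfail + 1L
        met <- data.frame(area_mm2 = NA_real_, perimeter_mm = NA_real_,
                          min_diameter_mm = NA_real_, max_diameter_mm = NA_real_,
                          min_max_ratio = NA_real_, circularity = NA_real_)
      }
      rows[[length(rows) + 1]] <- data.frame(
        branch_id = b$id, point = i, arclength_mm = b$arclength_mm[i],
        area_mm2 = met$area_mm2, misr_mm = b$misr_mm[i],
        min_diameter_mm = met$min_diameter_mm,
        max_diameter_mm = met$max_diameter_mm,
        min_max_ratio = met$min_max_ratio,
        curvature_per_mm = fb$curvature_per_mm[i],
        torsion_per_mm = fb$torsion_per_mm[i],
        perimeter_mm = met$perimeter_mm, circularity = met$circularity,
        missing = is.na(met$area_mm2))
    }
    if (nfail / n > max_missing_frac)
      stop(sprintf("branch %d: %d/%d cross-sections failed (> %.0f%%): quality error",
                   b$id, nfail, n, 100 * max_missing_frac))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
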