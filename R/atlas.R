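#' Load and validate an arterial atlas
#'
#' The atlas maps named arterial branches to territory chunks over which
#' feature means are reported. The shipped default
#' (`system.file("extdata", "arterial_atlas.csv", package = "cvmorph")`)
#' partitions 74 named branches of the intracranial circulation into 19
#' chunks (basilar, left/right ICA, left/right vertebral, basal and pial
#' ACA/MCA/PCA territories per side, and left/right cerebellar groups). The
#' file is a plain CSV with columns `branch_id`, `branch_name`, `chunk_id`,
#' `chunk_name` and is meant to be edited for other nomenclatures; every
#' branch must belong to exactly one chunk.
#'
#' @param path CSV path; defaults to the shipped atlas.
#' @return An object of class `cv_atlas`: list with data.frames `branches`
#'   (`branch_id`, `branch_name`, `chunk_id`) and `chunks` (`chunk_id`,
#'   `chunk_name`).
#' @export
load_atlas <- function(path = system.file("extdata", "arterial_atlas.csv",
                                          package = "cvmorph")) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(tab) == 0) stop("atlas file is empty: ", path)
  req <- c("branch_id", "branch_name", "chunk_id", "chunk_name")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("atlas is missing required column(s): ", paste(miss, collapse = ", "))
  bad <- which(is.na(tab$branch_id) | is.na(tab$chunk_id) |
                 !nzchar(tab$branch_name) | !nzchar(tab$chunk_name))
  if (length(bad))
    stop("atlas rows with missing values: ", paste(bad, collapse = ", "))
  dup <- which(duplicated(tab$branch_id))
  if (length(dup))
    stop("duplicate branch_id at atlas row(s): ", paste(dup, collapse = ", "),
         " (each branch must belong to exactly one chunk)")
  dupn <- which(duplicated(tab$branch_name))
  if (length(dupn))
    stop("duplicate branch_name at atlas row(s): ", paste(dupn, collapse = ", "))
  cmap <- unique(tab[, c("chunk_id", "chunk_name")])
  if (anyDuplicated(cmap$chunk_id))
    stop("chunk_id mapped to more than one chunk_name: ",
         paste(cmap$chunk_id[duplicated(cmap$chunk_id)], collapse = ", "))
  if (anyDuplicated(cmap$chunk_name))
    stop("chunk_name mapped to more than one chunk_id: ",
         paste(cmap$chunk_name[duplicated(cmap$chunk_name)], collapse = ", "))
  structure(list(
    branches = tab[, c("branch_id", "branch_name", "chunk_id")],
    chunks = cmap[order(cmap$chunk_id), ]), class = "cv_atlas")
}

#' @export
print.cv_atlas <- function(x, ...) {
  cat(sprintf("<cv_atlas> %d branches in %d chunks\n",
              nrow(x$branches), nrow(x$chunks)))
  invisible(x)
}

#' Assign centerline points to labelled branches
#'
#' Semi-automatic territory labelling: the user supplies one seed point per
#' anatomical branch; every centerline point receives the branch_id of the
#' topologically nearest seed, where distance is geodesic along the
#' centerline tree (consecutive points within a branch plus parent-child
#' junction links). Ties go to the lower branch_id. Each seed must lie
#' within the local maximal-inscribed-sphere radius of some centerline
#' point.
#'
#' @param cl a `cv_centerline`.
#' @param labels data.frame with columns `branch_id`, `x`, `y`, `z` (seed
#'   world positions, mm).
#' @return `cl` with a per-branch integer vector `label` giving the
#'   anatomical branch_id of every point.
#' @export
assign_branches <- function(cl, labels) {
  stopifnot(inherits(cl, "cv_centerline"),
            all(c("branch_id", "x", "y", "z") %in% names(labels)))
  pts <- do.call(rbind, lapply(cl$branches, `[[`, "points"))
  misr <- unlist(lapply(cl$branches, `[[`, "misr_mm"))
  nb <- vapply(cl$branches, function(b) nrow(b$points), 1L)
  offs <- cumsum(c(0L, nb[-length(nb)]))
  # geodesic graph over centerline points
  edges <- list(); wts <- list()
  for (i in seq_along(cl$branches)) {
    b <- cl$branches[[i]]
    n <- nrow(b$points)
    if (n > 1) {
      seg <- sqrt(rowSums((b$points[-1, , drop = FALSE] -
                             b$points[-n, , drop = FALSE])^2))
      edges[[length(edges) + 1]] <- cbind(offs[i] + seq_len(n - 1),
                                          offs[i] + seq_len(n - 1) + 1)
      wts[[length(wts) + 1]] <- seg
    }
    if (!is.na(b$parent)) {
      pidx <- which(vapply(cl$branches, `[[`, 1L, "id") == b$parent)
      pj <- offs[pidx] + nrow(cl$branches[[pidx]]$points)
      edges[[length(edges) + 1]] <- cbind(pj, offs[i] + 1L)
      wts[[length(wts) + 1]] <- sqrt(sum((cl$branches[[pidx]]$points[
        nrow(cl$branches[[pidx]]$points), ] - b$points[1, ])^2))
    }
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_graph(t(em), n = nrow(pts), directed = FALSE)
  w <- unlist(wts)
  seed_pts <- as.matrix(labels[, c("x", "y", "z")])
  seed_node <- integer(nrow(labels))
  for (s in seq_len(nrow(labels))) {
    d2 <- rowSums(sweep(pts, 2, seed_pts[s, ], "-")^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) > misr[j])
      stop(sprintf(
        "seed for branch %s at (%s) mm is %.2f mm from the nearest centerline point (misr %.2f mm)",
        labels$branch_id[s], paste(signif(seed_pts[s, ], 4), collapse = ", "),
        sqrt(d2[j]), misr[j]))
    seed_node[s] <- j
  }
  D <- igraph::distances(g, v = seed_node, weights = w)
  lab_order <- order(labels$branch_id) # ties resolved to the lower branch_id
  D <- D[lab_order, , drop = FALSE]
  ids <- labels$branch_id[lab_order]
  assign <- ids[apply(D, 2, which.min)]
  unreached <- apply(D, 2, function(col) all(!is.finite(col)))
  if (any(unreached))
    warning(sprintf("%d centerline point(s) unreachable from any seed (unlabeled island)",
                    sum(unreached)))
  assign[unreached] <- NA_integer_
  for (i in seq_along(cl$branches))
    cl$branches[[i]]$label <- assign[offs[i] + seq_len(nb[i])]
  cl
}

#' Chunk-level feature means
#'
#' Unweighted per-point means of every feature over the non-missing,
#' non-excluded points of each chunk's member branches. Chunks left with no
#' points are emitted with missing means and `point_count` 0 rather than
#' dropped — missingness is data, not an error.
#'
#' @param features a [point_features()] table carrying a `branch_id` column
#'   whose values are anatomical branch ids of `atlas` (e.g. after
#'   [assign_branches()] relabelling).
#' @param atlas a `cv_atlas`.
#' @param exclusions integer vector of branch_ids to exclude (e.g. the
#'   symptomatic stenotic segment); must be known to the atlas.
#' @return data.frame, one row per chunk: `chunk_id`, `chunk_name`, the nine
#'   feature means, `point_count`, `branch_count`.
#' @export
chunk_means <- function(features, atlas, exclusions = integer(0)) {
  stopifnot(inherits(atlas, "cv_atlas"), "branch_id" %in% names(features))
  if (length(exclusions)) {
    unknown <- setdiff(exclusions, atlas$branches$branch_id)
    if (length(unknown))
      stop("exclusions not in atlas: ", paste(unknown, collapse = ", "))
  }
  featcols <- c("area_mm2", "misr_mm", "min_diameter_mm", "max_diameter_mm",
                "min_max_ratio", "curvature_per_mm", "torsion_per_mm",
                "perimeter_mm", "circularity")
  featcols <- intersect(featcols, names(features))
  keep <- !(features$branch_id %in% exclusions)
  if ("missing" %in% names(features)) keep <- keep & !features$missing
  f <- features[keep, , drop = FALSE]
  chunk_of <- setNames(atlas$branches$chunk_id, atlas$branches$branch_id)
  f$chunk_id <- chunk_of[as.character(f$branch_id)]
  rows <- lapply(seq_len(nrow(atlas$chunks)), function(i) {
    cid <- atlas$chunks$chunk_id[i]
    sub <- f[!is.na(f$chunk_id) & f$chunk_id == cid, , drop = FALSE]
    means <- if (nrow(sub)) colMeans(sub[, featcols, drop = FALSE], na.rm = TRUE)
      else setNames(rep(NA_real_, length(featcols)), featcols)
    means[!is.finite(means)] <- NA_real_
    out <- data.frame(chunk_id = cid, chunk_name = atlas$chunks$chunk_name[i])
    out[featcols] <- as.list(means)
    out$point_count <- nrow(sub)
    out$branch_count <- length(unique(sub$branch_id))
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
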