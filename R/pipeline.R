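#' Pipeline configuration
#'
#' Validated, declarative configuration for [run_pipeline()]. Unknown keys
#' are rejected; numeric parameters are range-checked before any I/O
#' happens. Either `input` (a NIfTI path or a [cv_volume()]) must be given.
#'
#' @param input NIfTI path or [cv_volume()] to process.
#' @param output_dir directory for result artifacts (created if needed).
#' @param seeds region-growing seeds: n x 3 matrix of 1-based voxel indices.
#' @param lower,upper region-growing intensity thresholds (see
#'   [suggest_lower_threshold()] for the documented default policy).
#' @param endpoints centerline endpoint pairs (see [compute_centerline()]).
#' @param pitch_mm centerline resampling pitch (default 0.284 mm).
#' @param smoothing Frenet spline window half-width, mm.
#' @param smoothing_iterations Taubin iterations for the surface.
#' @param labels optional branch seed labels (see [assign_branches()]).
#' @param atlas optional atlas path (default: single-chunk phantom atlas
#'   when `labels` is NULL, shipped clinical atlas otherwise).
#' @param exclusions branch ids excluded from chunk means.
#' @param seed RNG seed recorded in the provenance stamp.
#' @param ... rejected; guards against misspelled keys.
#' @return list of class `cv_config`.
#' @export
pipeline_config <- function(input, output_dir, seeds, lower, upper = Inf,
                            endpoints = NULL, pitch_mm = 0.284,
                            smoothing = 4, smoothing_iterations = 20,
                            labels = NULL, atlas = NULL,
                            exclusions = integer(0), seed = NULL, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown config key(s): ", paste(names(extra), collapse = ", "))
  if (!is_cv_volume(input) && !(is.character(input) && length(input) == 1))
    stop("input must be a cv_volume or a NIfTI path")
  if (is.character(input) && !file.exists(input))
    stop("input volume not found: ", input)
  if (!is.numeric(pitch_mm) || pitch_mm <= 0)
    stop("pitch_mm must be a positive number")
  if (!is.numeric(smoothing) || smoothing <= 0)
    stop("smoothing must be a positive number")
  if (smoothing_iterations < 0 || smoothing_iterations != round(smoothing_iterations))
    stop("smoothing_iterations must be a nonnegative integer")
  if (!is.numeric(lower)) stop("lower threshold must be numeric")
  if (upper < lower) stop("upper threshold below lower")
  structure(list(input = input, output_dir = output_dir, seeds = seeds,
                 lower = lower, upper = upper, endpoints = endpoints,
                 pitch_mm = pitch_mm, smoothing = smoothing,
                 smoothing_iterations = smoothing_iterations,
                 labels = labels, atlas = atlas, exclusions = exclusions,
                 seed = seed),
            class = "cv_config")
}

config_stamp <- function(config) {
  list(version = as.character(utils::packageVersion("cvmorph")),
       input = if (is.character(config$input)) config$input else "<in-memory volume>",
       lower = config$lower,
       upper = if (is.finite(config$upper)) config$upper else "Inf",
       pitch_mm = config$pitch_mm, smoothing = config$smoothing,
       smoothing_iterations = config$smoothing_iterations,
       exclusions = config$exclusions,
       seed = if (is.null(config$seed)) NA else config$seed)
}

#' Run the full morphometry pipeline
#'
#' Executes segment -> surface -> centerline -> resample -> features ->
#' label -> summarize on one volume, logging stage parameters and counts,
#' and writes every artifact under `output_dir`: `mask.nii.gz`,
#' `surface.vtk`, `centerline.vtk` + `centerline.csv`, `features.csv`,
#' `chunks.csv`, and `pipeline.log`. CSV headers carry the package version
#' and the resolved configuration, so identical reruns are byte-identical.
#' A stage failure aborts with the stage name; artifacts of completed
#' stages remain on disk.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list: `mask`, `mesh`, `centerline`, `features`,
#'   `chunks`, and `paths` of the written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cv_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logpath <- file.path(config$output_dir, "pipeline.log")
  logcon <- file(logpath, "w")
  on.exit(close(logcon))
  note <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, logcon)
    message(msg)
  }
  stamp <- config_stamp(config)
  note("cvmorph %s pipeline; config: %s", stamp$version,
       jsonlite::toJSON(stamp, auto_unbox = TRUE))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s (completed artifacts in %s)",
                   name, conditionMessage(e), config$output_dir), call. = FALSE))
  }
  vol <- stage("load", if (is_cv_volume(config$input)) config$input
               else read_volume(config$input))
  note("load: %s voxels, spacing %s mm", paste(dim(vol$data), collapse = "x"),
       paste(signif(vol$spacing, 4), collapse = "x"))
  mask <- stage("segment", {
    m <- region_grow(vol, config$seeds, config$lower, config$upper)
    largest_connected_component(m)
  })
  note("segment: %d foreground voxels (%.2f mm^3)", sum(mask$data), mask_volume(mask))
  paths <- list(mask = file.path(config$output_dir, "mask.nii.gz"))
  write_volume(mask, paths$mask)
  mesh <- stage("surface", extract_surface(mask, config$smoothing_iterations))
  note("surface: %d vertices, %d triangles, volume %.2f mm^3",
       nrow(mesh$vertices), nrow(mesh$triangles), mesh_volume(mesh))
  paths$surface <- file.path(config$output_dir, "surface.vtk")
  write_vtk_polydata(paths$surface, mesh$vertices, polys = mesh$triangles)
  cl <- stage("centerline", {
    if (is.null(config$endpoints)) stop("no endpoints configured")
    cc <- compute_centerline(mask, config$endpoints)
    resample_centerline(cc, config$pitch_mm)
  })
  note("centerline: %d branch(es), %d points", length(cl$branches),
       sum(vapply(cl$branches, function(b) nrow(b$points), 1L)))
  paths$centerline_vtk <- file.path(config$output_dir, "centerline.vtk")
  paths$centerline_csv <- file.path(config$output_dir, "centerline.csv")
  write_centerline(cl, paths$centerline_vtk, paths$centerline_csv, stamp)
  feats <- stage("features", point_features(mesh, cl, config$smoothing))
  note("features: %d points, %d missing", nrow(feats), sum(feats$missing))
  if (!is.null(config$labels)) {
    cl <- stage("label", assign_branches(cl, config$labels))
    feats$branch_id <- unlist(lapply(cl$branches, `[[`, "label"))
    note("label: %d anatomical branches", length(unique(feats$branch_id)))
  }
  paths$features <- file.path(config$output_dir, "features.csv")
  write_stamped_csv(feats, paths$features, stamp)
  atlas <- stage("summarize", {
    if (!is.null(config$atlas)) load_atlas(config$atlas)
    else if (is.null(config$labels)) mini_atlas(max(feats$branch_id))
    else load_atlas()
  })
  chunks <- stage("summarize", chunk_means(feats, atlas, config$exclusions))
  note("summarize: %d chunks, %d with points", nrow(chunks),
       sum(chunks$point_count > 0))
  paths$chunks <- file.path(config$output_dir, "chunks.csv")
  write_stamped_csv(chunks, paths$chunks, stamp)
  invisible(list(mask = mask, mesh = mesh, centerline = cl, features = feats,
                 chunks = chunks, paths = paths))
}
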