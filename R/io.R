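#' Write polydata (mesh or polylines) as legacy ASCII VTK
#'
#' Minimal writer for the legacy VTK PolyData text format, used to export
#' luminal surfaces and centerlines for inspection in ParaView/3D Slicer.
#'
#' @param path output `.vtk` path.
#' @param points n x 3 matrix of mm coordinates.
#' @param polys optional m x 3 matrix of 1-based triangle indices.
#' @param lines optional list of 1-based index vectors, one per polyline.
#' @param point_data optional named list of per-point numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk_polydata <- function(path, points, polys = NULL, lines = NULL,
                               point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("cvmorph", utils::packageVersion("cvmorph")),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(points))), con)
  writeLines(apply(points, 1, function(p) paste(format(p, digits = 9), collapse = " ")), con)
  if (!is.null(polys)) {
    writeLines(sprintf("POLYGONS %d %d", nrow(polys), 4 * nrow(polys)), con)
    writeLines(apply(polys - 1L, 1, function(t) paste(c(3L, t), collapse = " ")), con)
  }
  if (!is.null(lines)) {
    sz <- sum(vapply(lines, length, 1L)) + length(lines)
    writeLines(sprintf("LINES %d %d", length(lines), sz), con)
    for (ln in lines)
      writeLines(paste(c(length(ln), ln - 1L), collapse = " "), con)
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(points)), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], digits = 9), con)
    }
  }
  invisible(path)
}

# CSV with a version/config provenance header (lines starting with '#').
write_stamped_csv <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cvmorph %s", utils::packageVersion("cvmorph")), con)
  if (!is.null(config))
    writeLines(paste0("# config: ",
                      jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a cvmorph CSV (skipping provenance header lines)
#'
#' @param path CSV written by the pipeline (`#`-prefixed header lines).
#' @return data.frame.
#' @export
read_stamped_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read legacy ASCII VTK PolyData written by [write_vtk_polydata()]
#'
#' Minimal reader for the subset this package writes (POINTS plus POLYGONS
#' triangles); enough to reload an exported luminal surface.
#'
#' @param path `.vtk` path.
#' @return A `cv_mesh` (without normals if the file has no polygons).
#' @export
read_vtk_polydata <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  if (is.na(ip)) stop("no POINTS section in ", path)
  npts <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- matrix(as.numeric(unlist(strsplit(trimws(
    lines[(ip + 1):(ip + npts)]), "\\s+"))), ncol = 3, byrow = TRUE)
  mesh <- structure(list(vertices = pts, triangles = NULL), class = "cv_mesh")
  it <- grep("^POLYGONS", lines)
  if (length(it)) {
    ntri <- as.integer(strsplit(lines[it[1]], "\\s+")[[1]][2])
    tri <- matrix(as.integer(unlist(strsplit(trimws(
      lines[(it[1] + 1):(it[1] + ntri)]), "\\s+"))), ncol = 4, byrow = TRUE)
    mesh$triangles <- tri[, 2:4, drop = FALSE] + 1L
    mesh$normals <- vertex_normals(mesh)
  }
  mesh
}

#' Rebuild a centerline object from its exported point table
#'
#' @param df data.frame as written by [write_centerline()] (`branch_id`,
#'   `parent`, `x`, `y`, `z`, `arclength_mm`, `misr_mm`).
#' @return A `cv_centerline`.
#' @export
centerline_from_csv <- function(df) {
  req <- c("branch_id", "x", "y", "z", "arclength_mm", "misr_mm")
  stopifnot(all(req %in% names(df)))
  branches <- lapply(unique(df$branch_id), function(id) {
    sub <- df[df$branch_id == id, , drop = FALSE]
    list(id = as.integer(id),
         points = unname(as.matrix(sub[, c("x", "y", "z")])),
         misr_mm = sub$misr_mm, arclength_mm = sub$arclength_mm,
         parent = if ("parent" %in% names(sub)) as.integer(sub$parent[1])
           else NA_integer_)
  })
  structure(list(branches = branches), class = "cv_centerline")
}

#' Export a centerline as VTK polylines plus a CSV point table
#'
#' @param cl a `cv_centerline`.
#' @param vtk_path,csv_path output paths (either may be NULL to skip).
#' @param config optional resolved config list stamped into the CSV header.
#' @return invisibly, the per-point data.frame written to `csv_path`.
#' @export
write_centerline <- function(cl, vtk_path = NULL, csv_path = NULL, config = NULL) {
  pts <- do.call(rbind, lapply(cl$branches, `[[`, "points"))
  nb <- vapply(cl$branches, function(b) nrow(b$points), 1L)
  offs <- cumsum(c(0L, nb[-length(nb)]))
  df <- do.call(rbind, lapply(seq_along(cl$branches), function(i) {
    b <- cl$branches[[i]]
    data.frame(branch_id = b$id, parent = b$parent,
               x = b$points[, 1], y = b$points[, 2],
               z = b$points[, 3], arclength_mm = b$arclength_mm,
               misr_mm = b$misr_mm)
  }))
  if (!is.null(vtk_path))
    write_vtk_polydata(vtk_path, pts,
                       lines = lapply(seq_along(nb), function(i) offs[i] + seq_len(nb[i])),
                       point_data = list(misr_mm = df$misr_mm,
                                         branch_id = as.numeric(df$branch_id)))
  if (!is.null(csv_path)) write_stamped_csv(df, csv_path, config)
  invisible(df)
}
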