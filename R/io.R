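# File I/O: VTK legacy-ASCII meshes + fields, CSV trajectories and series,
# JSON metric reports, YAML configurations.  All writers have matching
# readers that validate structure and fail loudly on truncation.

#' Write a mesh (optionally deformed, with cell fields) as legacy VTK
#'
#' Unstructured-grid legacy ASCII VTK: quad cells, optional per-cell scalar
#' fields.  Readable by ParaView/VisIt and by [read_vtk()].
#'
#' @param mesh a [build_bilayer_mesh()] mesh
#' @param path output file
#' @param u optional displacement vector (writes the deformed configuration)
#' @param cell_data named list of per-element numeric/integer vectors
#' @return `path`, invisibly
#' @export
write_vtk <- function(mesh, path, u = NULL, cell_data = list()) {
  n <- nrow(mesh$nodes)
  xy <- mesh$nodes
  if (!is.null(u)) xy <- xy + cbind(u[seq(1, 2 * n, 2)], u[seq(2, 2 * n, 2)])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "foldax bilayer mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.12g %.12g 0", xy[, 1], xy[, 2]), con)
  ne <- nrow(mesh$quads)
  writeLines(sprintf("CELLS %d %d", ne, 5 * ne), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$quads[, 1] - 1L,
                     mesh$quads[, 2] - 1L, mesh$quads[, 3] - 1L,
                     mesh$quads[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("9", ne), con)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", ne), con)
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      if (length(v) != ne) stop("cell field '", nm, "' length != n elements")
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(sprintf("%.12g", as.numeric(v)), con)
    }
  }
  invisible(path)
}

#' Read a legacy VTK unstructured grid written by [write_vtk()]
#'
#' @param path input file
#' @return list: `points` (n x 2), `quads` (ne x 4, 1-based), `cell_data`
#'   (named list)
#' @export
read_vtk <- function(path) {
  ln <- readLines(path)
  fail <- function(what, at)
    stop(sprintf("VTK parse error in '%s': %s (line %d)", path, what, at))
  ip <- grep("^POINTS ", ln)
  if (length(ip) != 1) fail("missing POINTS header", 0)
  n <- as.integer(strsplit(ln[ip], " ")[[1]][2])
  if (ip + n > length(ln)) fail("truncated POINTS block", ip)
  pts <- do.call(rbind, lapply(ln[(ip + 1):(ip + n)], function(s)
    as.numeric(strsplit(trimws(s), "[ ]+")[[1]])))
  if (ncol(pts) != 3 || anyNA(pts)) fail("malformed point row", ip + 1)
  ic <- grep("^CELLS ", ln)
  if (length(ic) != 1) fail("missing CELLS header", 0)
  ne <- as.integer(strsplit(ln[ic], " ")[[1]][2])
  if (ic + ne > length(ln)) fail("truncated CELLS block", ic)
  quads <- do.call(rbind, lapply(ln[(ic + 1):(ic + ne)], function(s) {
    v <- as.integer(strsplit(trimws(s), "[ ]+")[[1]])
    if (length(v) != 5 || v[1] != 4) fail("non-quad cell", ic)
    v[-1] + 1L
  }))
  cd <- list()
  icd <- grep("^CELL_DATA ", ln)
  if (length(icd) == 1) {
    isc <- grep("^SCALARS ", ln)
    isc <- isc[isc > icd]
    for (s0 in isc) {
      nm <- strsplit(ln[s0], " ")[[1]][2]
      if (s0 + 1 + ne > length(ln)) fail("truncated CELL_DATA block", s0)
      v <- as.numeric(ln[(s0 + 2):(s0 + 1 + ne)])
      if (anyNA(v)) fail("malformed scalar value", s0 + 2)
      cd[[nm]] <- v
    }
  }
  list(points = pts[, 1:2, drop = FALSE], quads = quads, cell_data = cd)
}

#' Write / read agent trajectories as CSV
#'
#' Columns: `id`, `step`, `x`, `y`, `theta`, `sigma`, `status`.  Stored
#' values are the raw simulation output; any smoothing for figures is
#' presentation-only and never applied to stored data.
#'
#' @param traj trajectory data.frame from [run_simulation()] or
#'   [agent_sandbox()]
#' @param path file path
#' @return `path` (writer) / the data.frame (reader)
#' @export
write_trajectories <- function(traj, path) {
  cols <- c("id", "step", "x", "y", "theta", "sigma", "status")
  miss <- setdiff(cols, names(traj))
  if (length(miss)) stop("trajectory frame lacks columns: ",
                         paste(miss, collapse = ", "))
  write.csv(traj[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cols <- c("id", "step", "x", "y", "theta", "sigma", "status")
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("trajectory parse error in '%s': missing columns %s",
                 path, paste(miss, collapse = ", ")))
  if (nrow(df) && anyNA(df$x))
    stop(sprintf("trajectory parse error in '%s': non-numeric coordinates",
                 path))
  df$status <- factor(df$status, levels = c("growing", "settled", "stalled"))
  df
}

#' Write / read a metrics report as JSON
#'
#' @param metrics a `foldax_metrics` report
#' @param path file path
#' @return `path` (writer) / a list (reader)
#' @export
write_report <- function(metrics, path) {
  jsonlite::write_json(unclass(metrics), path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write / read a configuration as YAML
#'
#' Round-trips a [simulation_config()] losslessly.
#'
#' @param config a `foldax_config`
#' @param path file path
#' @return `path` (writer) / a `foldax_config` (reader)
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(simulation_config, lst[!vapply(lst, is.null, logical(1))])
}

#' Write all artefacts of a result to a directory
#'
#' Emits `mesh.vtk` (deformed configuration with region and modulus cell
#' fields), `trajectories.csv`, `series.csv`, `metrics.json` and
#' `config.yaml` under `dir`.
#'
#' @param result a `foldax_result`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_vtk(result$mesh, file.path(dir, "mesh.vtk"), u = result$u,
            cell_data = list(region = as.integer(result$elem_region),
                             mu = result$elem_mu))
  write_trajectories(result$trajectories, file.path(dir, "trajectories.csv"))
  write.csv(result$series, file.path(dir, "series.csv"), row.names = FALSE)
  write_report(result$metrics, file.path(dir, "metrics.json"))
  write_config(result$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
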