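# Legacy-VTK unstructured-grid field export and CSV reporting surfaces.

#' Write one snapshot to a legacy VTK unstructured-grid file
#'
#' Vertex-resolution velocity vectors, pressure, temperature (when present)
#' as point data; element-wise viscous dissipation as cell data.
#'
#' @param snapshot A list with `flow` ([flow_state()]) and optionally
#'   `thermal` ([thermal_state()]).
#' @param fe The matching [fe_space()].
#' @param props Effective properties (for the dissipation field).
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_snapshot <- function(snapshot, fe, props, path) {
  mesh <- fe$mesh
  nv <- nrow(mesh$nodes); nt <- nrow(mesh$tri)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0",
     sprintf("hemofem snapshot t=%.6g", snapshot$flow$t),
     "ASCII", "DATASET UNSTRUCTURED_GRID",
     sprintf("POINTS %d double", nv))
  wl(sprintf("%.17g %.17g 0", mesh$nodes[, 1], mesh$nodes[, 2]))
  wl(sprintf("CELLS %d %d", nt, 4L * nt))
  wl(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
             mesh$tri[, 3] - 1L))
  wl(sprintf("CELL_TYPES %d", nt))
  wl(rep("5", nt))
  wl(sprintf("POINT_DATA %d", nv))
  v <- snapshot$flow$velocity[seq_len(nv), , drop = FALSE]
  wl("VECTORS velocity double")
  wl(sprintf("%.10g %.10g 0", v[, 1], v[, 2]))
  wl("SCALARS pressure double 1", "LOOKUP_TABLE default")
  wl(sprintf("%.10g", snapshot$flow$pressure))
  if (!is.null(snapshot$thermal)) {
    wl("SCALARS temperature double 1", "LOOKUP_TABLE default")
    wl(sprintf("%.10g", snapshot$thermal$temperature))
  }
  wl(sprintf("CELL_DATA %d", nt))
  wl("SCALARS viscous_dissipation double 1", "LOOKUP_TABLE default")
  wl(sprintf("%.10g", viscous_dissipation_field(snapshot$flow, props, fe)))
  invisible(path)
}

# Minimal legacy-VTK reader for round-trip testing of our own exports.
read_vtk_snapshot <- function(path) {
  lines <- readLines(path)
  grab <- function(pattern) grep(pattern, lines)[1]
  np <- as.integer(strsplit(lines[grab("^POINTS")], " ")[[1]][2])
  pts <- utils::read.table(text = lines[grab("^POINTS") + seq_len(np)])
  nc <- as.integer(strsplit(lines[grab("^CELLS")], " ")[[1]][2])
  cells <- utils::read.table(text = lines[grab("^CELLS") + seq_len(nc)])
  out <- list(points = unname(as.matrix(pts[, 1:2])),
              tri = unname(as.matrix(cells[, 2:4])) + 1L)
  i <- grab("^VECTORS velocity")
  if (!is.na(i)) {
    out$velocity <- as.matrix(utils::read.table(text = lines[i + seq_len(np)])[, 1:2])
  }
  for (nm in c("pressure", "temperature", "viscous_dissipation")) {
    i <- grab(paste0("^SCALARS ", nm))
    if (!is.na(i)) {
      n <- if (nm == "viscous_dissipation") nc else np
      out[[nm]] <- utils::read.table(text = lines[i + 1L + seq_len(n)])[[1]]
    }
  }
  out
}

#' Export a trajectory: VTK time series plus CSV tables
#'
#' Writes one legacy-VTK unstructured-grid file per stored output time
#' (fields attached), the extremes table as
#' `extremes.csv` (schema `t, v_max, v_min, p_max, p_min, v_max_line,
#' v_min_line, T_max, T_min`) and the reporting-line samples as
#' `line_samples.csv` (schema `t, s, z, x, value`).
#'
#' @param trajectory A `run_trajectory`.
#' @param path Output directory (created if missing).
#' @param prefix File-name prefix for the VTK series.
#' @return Character vector of files written, invisibly.
#' @export
export_fields <- function(trajectory, path, prefix = "fields") {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path)
  fe <- trajectory$fe
  files <- character(0)
  for (sn in trajectory$snapshots) {
    f <- file.path(path, sprintf("%s_t%06.3f.vtk", prefix, sn$t))
    write_vtk_snapshot(sn, fe, trajectory$props, f)
    files <- c(files, f)
  }
  ext <- extremes(trajectory)
  f <- file.path(path, "extremes.csv")
  utils::write.csv(as.data.frame(ext), f, row.names = FALSE)
  files <- c(files, f)
  line <- trajectory$line %||% default_reporting_line(fe)
  ls_all <- do.call(rbind, lapply(trajectory$snapshots, function(sn) {
    ls <- sample_line(sn$flow, fe, line$start, line$end, n = 200)
    cbind(t = sn$t, as.data.frame(ls))
  }))
  f <- file.path(path, "line_samples.csv")
  utils::write.csv(ls_all, f, row.names = FALSE)
  files <- c(files, f)
  invisible(files)
}
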