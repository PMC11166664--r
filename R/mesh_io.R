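# Mesh interchange: Gmsh MSH 2.2 ASCII with boundary tags as physical
# groups, plus a legacy-VTK unstructured-grid writer/reader for field
# export.

BOUNDARY_TAG_IDS <- c(INLET = 1L, OUTLET = 2L, WALL = 3L, RUPTURE = 4L,
                      AXIS = 5L)
REGION_IDS <- c(lumen = 10L, sac = 20L)

#' Write a mesh to a Gmsh MSH (2.2 ASCII) file
#'
#' Boundary tags and region ids are stored as physical groups, so the file
#' round-trips losslessly through [read_mesh()].
#'
#' @param mesh A `vessel_mesh`.
#' @param path Output file path (conventionally `.msh`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "vessel_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("$MeshFormat", "2.2 0 8", "$EndMeshFormat")
  tags_used <- unique(mesh$boundary$tag)
  regions_used <- sort(unique(mesh$region))
  wl("$PhysicalNames", as.character(length(tags_used) + length(regions_used)))
  for (tg in tags_used) wl(sprintf('1 %d "%s"', BOUNDARY_TAG_IDS[[tg]], tg))
  for (rg in regions_used) {
    nm <- names(REGION_IDS)[match(rg * 10L, REGION_IDS)]
    wl(sprintf('2 %d "%s"', rg * 10L, nm))
  }
  wl("$EndPhysicalNames")
  wl("$Nodes", as.character(nrow(mesh$nodes)))
  wl(sprintf("%d %.17g %.17g 0", seq_len(nrow(mesh$nodes)),
             mesh$nodes[, 1], mesh$nodes[, 2]))
  wl("$EndNodes")
  nb <- nrow(mesh$boundary); nt <- nrow(mesh$tri)
  wl("$Elements", as.character(nb + nt))
  wl(sprintf("%d 1 2 %d %d %d %d", seq_len(nb),
             BOUNDARY_TAG_IDS[mesh$boundary$tag],
             BOUNDARY_TAG_IDS[mesh$boundary$tag],
             mesh$boundary$n1, mesh$boundary$n2))
  wl(sprintf("%d 2 2 %d %d %d %d %d", nb + seq_len(nt),
             mesh$region * 10L, mesh$region * 10L,
             mesh$tri[, 1], mesh$tri[, 2], mesh$tri[, 3]))
  wl("$EndElements")
  invisible(path)
}

#' Read a mesh from a Gmsh MSH (2.2 ASCII) file
#'
#' @param path Path to a `.msh` file with physical-group boundary tags.
#' @param mode Mesh mode (`"planar"` or `"axisymmetric"`); MSH 2.2 has no
#'   native slot for this, so it is supplied by the caller.
#' @return A `vessel_mesh`.
#' @export
read_mesh <- function(path, mode = "planar") {
  if (!file.exists(path)) stop("no such mesh file: ", path)
  lines <- readLines(path)
  section <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) return(NULL)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- section("MeshFormat")
  if (is.null(fmt) || !startsWith(fmt[1], "2.2")) {
    stop("unknown mesh format: expected Gmsh MSH 2.2 ASCII")
  }
  phys <- section("PhysicalNames")
  if (is.null(phys)) stop("mesh file has no physical names: boundary tags missing")
  pn <- utils::read.table(text = phys[-1], col.names = c("dim", "id", "name"))
  pn$name <- gsub('"', "", pn$name)
  nod <- section("Nodes")
  nd <- utils::read.table(text = nod[-1])
  nodes <- unname(as.matrix(nd[order(nd[[1]]), 2:3]))
  ele <- section("Elements")
  el <- strsplit(ele[-1], " +")
  types <- vapply(el, function(x) as.integer(x[2]), integer(1))
  lines_el <- el[types == 1L]
  tris_el <- el[types == 2L]
  if (length(lines_el) == 0L) stop("mesh file has no tagged boundary edges")
  getph <- function(x) as.integer(x[4])
  tagname <- function(id) {
    nm <- pn$name[match(id, pn$id)]
    if (any(is.na(nm))) stop("boundary tag id without a physical name")
    nm
  }
  bnd <- data.frame(
    n1 = vapply(lines_el, function(x) as.integer(x[6]), integer(1)),
    n2 = vapply(lines_el, function(x) as.integer(x[7]), integer(1)),
    tag = tagname(vapply(lines_el, getph, integer(1))))
  tri <- t(vapply(tris_el, function(x) as.integer(x[6:8]), integer(3)))
  region <- as.integer(vapply(tris_el, getph, integer(1)) / 10L)
  new_mesh(nodes, tri, bnd, region = region, mode = mode)
}
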