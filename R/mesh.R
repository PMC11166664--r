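#' Mesh sizing parameters
#'
#' Element-size controls for the graded triangular mesher. Defaults follow
#' the study's published mesh-size settings.
#'
#' @param h_max Maximum element size, m (default 0.0169).
#' @param h_min Minimum element size, m (default 0.0032).
#' @param growth_rate Maximum neighbour-size growth rate (default 1.13).
#' @param narrow_resolution Resolution of narrow regions (default 0.8):
#'   minimum number of element layers across a narrow gap is `1/narrow_resolution`.
#' @param curvature_factor Maximum element size relative to the local
#'   boundary curvature radius (default 0.06).
#' @param seed Integer seed for the deterministic pseudo-random thinning used
#'   by the unstructured mesher (default 1).
#' @return A list of class `"mesh_sizing"`.
#' @export
mesh_sizing <- function(h_max = 0.0169, h_min = 0.0032, growth_rate = 1.13,
                        narrow_resolution = 0.8, curvature_factor = 0.06,
                        seed = 1L) {
  stopifnot(h_min > 0, h_max >= h_min, growth_rate >= 1,
            narrow_resolution > 0, curvature_factor > 0)
  structure(list(h_max = h_max, h_min = h_min, growth_rate = growth_rate,
                 narrow_resolution = narrow_resolution,
                 curvature_factor = curvature_factor, seed = as.integer(seed)),
            class = "mesh_sizing")
}

new_mesh <- function(nodes, tri, boundary, region, mode) {
  colnames(nodes) <- c("z", "x")
  mesh <- structure(list(nodes = nodes, tri = tri, boundary = boundary,
                         region = region, mode = mode),
                    class = "vessel_mesh")
  mesh <- orient_mesh(mesh)
  validate_mesh(mesh)
  mesh
}

triangle_areas <- function(mesh) {
  p1 <- mesh$nodes[mesh$tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$tri[, 3], , drop = FALSE]
  ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
      (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])) / 2
}

orient_mesh <- function(mesh) {
  a <- triangle_areas(mesh)
  flip <- a < 0
  if (any(flip)) {
    tmp <- mesh$tri[flip, 2]
    mesh$tri[flip, 2] <- mesh$tri[flip, 3]
    mesh$tri[flip, 3] <- tmp
  }
  mesh
}

# Edge table of a triangulation: each row one undirected edge (sorted pair);
# count = number of adjacent triangles.
edge_table <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  es <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- es[, 1] * (max(tri) + 1) + es[, 2]
  first <- !duplicated(key)
  ukey <- key[first]
  cnt <- tabulate(match(key, ukey))
  list(edges = es[first, , drop = FALSE], key = ukey, count = cnt,
       all_key = key)
}

validate_mesh <- function(mesh) {
  a <- triangle_areas(mesh)
  if (any(a <= 0)) stop("mesh contains non-positively-oriented or degenerate triangles")
  et <- edge_table(mesh$tri)
  bnd_idx <- et$count == 1L
  n_bnd <- sum(bnd_idx)
  if (n_bnd != nrow(mesh$boundary)) {
    stop("boundary tags do not cover the full boundary: mesh has ", n_bnd,
         " boundary edges but ", nrow(mesh$boundary), " tagged edges")
  }
  bkey <- pmin(mesh$boundary$n1, mesh$boundary$n2) * (max(mesh$tri) + 1) +
    pmax(mesh$boundary$n1, mesh$boundary$n2)
  if (!all(sort(bkey) == sort(et$key[bnd_idx]))) {
    stop("tagged boundary edges do not match the triangulation boundary")
  }
  invisible(mesh)
}

#' Mesh quality report
#'
#' Per-triangle quality is the normalised area/edge measure
#' `4 sqrt(3) A / (l1^2 + l2^2 + l3^2)`, equal to 1 for an equilateral
#' triangle and tending to 0 for degenerate ones.
#'
#' @param mesh A `vessel_mesh`.
#' @return A list of class `"mesh_quality"` with fields `n_elements`,
#'   `n_vertices`, `min_quality`, `avg_quality`, `total_area`,
#'   `n_degenerate` and the per-element `quality` vector. Zero-area
#'   triangles are reported through `n_degenerate`, never dropped.
#' @export
quality_report <- function(mesh) {
  stopifnot(inherits(mesh, "vessel_mesh"))
  a <- abs(triangle_areas(mesh))
  p1 <- mesh$nodes[mesh$tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$tri[, 3], , drop = FALSE]
  ssq <- rowSums((p2 - p1)^2) + rowSums((p3 - p2)^2) + rowSums((p1 - p3)^2)
  q <- 4 * sqrt(3) * a / ssq
  structure(list(n_elements = nrow(mesh$tri), n_vertices = nrow(mesh$nodes),
                 min_quality = min(q), avg_quality = mean(q),
                 total_area = sum(a), n_degenerate = sum(a == 0),
                 quality = q),
            class = "mesh_quality")
}

#' @export
print.mesh_quality <- function(x, ...) {
  cat("Mesh quality report\n")
  cat(sprintf("  elements: %d  vertices: %d\n", x$n_elements, x$n_vertices))
  cat(sprintf("  min quality: %.4f  avg quality: %.4f\n",
              x$min_quality, x$avg_quality))
  cat(sprintf("  total area: %.6g m^2  degenerate: %d\n",
              x$total_area, x$n_degenerate))
  invisible(x)
}

#' @export
print.vessel_mesh <- function(x, ...) {
  cat(sprintf("<vessel_mesh> %s, %d vertices, %d triangles, %d boundary edges\n",
              x$mode, nrow(x$nodes), nrow(x$tri), nrow(x$boundary)))
  cat("  tags:", paste(sprintf("%s=%d", names(table(x$boundary$tag)),
                               table(x$boundary$tag)), collapse = " "), "\n")
  invisible(x)
}

# 1D graded node distribution on [a, b] given a pointwise target spacing
# function h(z): places ceil(integral dz/h) + 1 nodes at equal increments of
# the cumulative density, so neighbour spacings follow h up to rounding.
graded_1d <- function(a, b, h_fun, n_fine = 2049) {
  zf <- seq(a, b, length.out = n_fine)
  h <- pmax(h_fun(zf), 1e-12)
  inv <- 1 / h
  cum <- cumsum(c(0, (inv[-1] + inv[-n_fine]) / 2 * diff(zf)))
  n <- max(1L, ceiling(cum[n_fine]))
  stats::approx(cum, zf, xout = seq(0, cum[n_fine], length.out = n + 1L))$y
}

# Spacing target used by the graded meshers: h_min inside the refinement
# ball, growing linearly at rate (growth - 1) with distance, capped at h_max.
sizing_field <- function(sizing, features = NULL) {
  slope <- max(sizing$growth_rate - 1, 0.01)
  function(p) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 2)
    h <- rep(sizing$h_max, nrow(p))
    if (!is.null(features)) {
      for (f in features) {
        d <- f$dist(p)
        h <- pmin(h, pmax(f$h, f$h + slope * d))
      }
    }
    pmax(pmin(h, sizing$h_max), min(sizing$h_min, h))
  }
}

# Structured graded tensor-product mesh of a rectangle [0,L] x [0,H].
structured_rectangle_mesh <- function(L, H, sizing, refine_near = NULL,
                                      mode = "planar",
                                      tags = NULL) {
  slope <- max(sizing$growth_rate - 1, 0.01)
  hz <- function(z) {
    h <- rep(sizing$h_max, length(z))
    if (!is.null(refine_near)) {
      d <- pmax(abs(z - refine_near$point[1]) - refine_near$radius, 0)
      h <- pmin(h, sizing$h_min + slope * d)
    }
    pmax(h, sizing$h_min)
  }
  hx <- function(x) {
    h <- rep(sizing$h_max, length(x))
    if (!is.null(refine_near)) {
      d <- pmax(abs(x - refine_near$point[2]) - refine_near$radius, 0)
      h <- pmin(h, sizing$h_min + slope * d)
    }
    pmax(h, sizing$h_min)
  }
  zs <- graded_1d(0, L, hz)
  xs <- graded_1d(0, H, hx)
  nz <- length(zs); nx <- length(xs)
  nodes <- cbind(rep(zs, times = nx), rep(xs, each = nz))
  idx <- function(i, j) (j - 1L) * nz + i
  i <- rep(seq_len(nz - 1L), times = nx - 1L)
  j <- rep(seq_len(nx - 1L), each = nz - 1L)
  # two triangles per cell, consistent diagonal
  t1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
  t2 <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  tri <- rbind(t1, t2)
  if (is.null(tags)) {
    tags <- list(bottom = if (mode == "axisymmetric") "AXIS" else "WALL",
                 top = "WALL", left = "INLET", right = "OUTLET")
  }
  bnd <- rbind(
    data.frame(n1 = idx(seq_len(nz - 1L), 1L), n2 = idx(seq_len(nz - 1L) + 1L, 1L),
               tag = tags$bottom),
    data.frame(n1 = idx(seq_len(nz - 1L), nx), n2 = idx(seq_len(nz - 1L) + 1L, nx),
               tag = tags$top),
    data.frame(n1 = idx(1L, seq_len(nx - 1L)), n2 = idx(1L, seq_len(nx - 1L) + 1L),
               tag = tags$left),
    data.frame(n1 = idx(nz, seq_len(nx - 1L)), n2 = idx(nz, seq_len(nx - 1L) + 1L),
               tag = tags$right)
  )
  new_mesh(nodes, tri, bnd, region = rep(1L, nrow(tri)), mode = mode)
}

#' Generate a graded conforming triangle mesh of a vessel boundary
#'
#' Rectangular domains (no sac) are meshed with a graded structured
#' tensor-product triangulation. Sac-bearing domains are meshed with the
#' in-package unstructured mesher (Delaunay triangulation with
#' equilibrium-spacing relaxation), graded towards the rupture orifice, the
#' sac arc and the neck corners. Both paths are deterministic for identical
#' inputs.
#'
#' @param boundary A [build_geometry()] result.
#' @param sizing A [mesh_sizing()].
#' @param refine_near Optional `list(point = c(z, x), radius = r)` inside
#'   which the local edge length is held at `h_min`. Defaults to a ball of
#'   radius `3 * orifice_width` around the orifice midpoint when the
#'   geometry has an orifice.
#' @return A `vessel_mesh`: node coordinates, positively oriented triangles,
#'   tagged boundary edges and a per-triangle region id (1 = lumen, 2 = sac).
#' @export
generate_mesh <- function(boundary, sizing = mesh_sizing(), refine_near = NULL) {
  stopifnot(inherits(boundary, "vessel_boundary"), inherits(sizing, "mesh_sizing"))
  params <- boundary$params
  if (is.null(refine_near) && params$has_orifice) {
    d <- sac_center_height(params$sac_radius, params$neck_width)
    apex <- c(params$sac_center_z, params$height + d + params$sac_radius)
    refine_near <- list(point = apex, radius = 3 * params$orifice_width)
  }
  if (!params$has_sac) {
    return(structured_rectangle_mesh(params$length, params$height, sizing,
                                     refine_near, mode = params$mode))
  }
  distmesh_vessel(boundary, sizing, refine_near)
}
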