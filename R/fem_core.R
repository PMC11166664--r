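# Finite-element core: Taylor-Hood (P2 velocity / P1 pressure) spaces on
# triangles, degree-5 quadrature, vectorised assembly over elements.
#
# Internal coordinate convention: column 1 = z (axial), column 2 = x
# (transverse; the radius r in axisymmetric mode). Velocity component 1 is
# axial (u3 in the cylindrical-reduction notation), component 2 transverse
# (u1). Dof ordering of the coupled system: [u_axial(P2), u_transverse(P2),
# p(P1)].

# Degree-5, 7-point quadrature on the reference triangle (weights sum to 1).
tri_quadrature <- function() {
  a1 <- 0.059715871789770; b1 <- 0.470142064105115
  a2 <- 0.797426985353087; b2 <- 0.101286507323456
  lam <- rbind(c(1 / 3, 1 / 3, 1 / 3),
               c(a1, b1, b1), c(b1, a1, b1), c(b1, b1, a1),
               c(a2, b2, b2), c(b2, a2, b2), c(b2, b2, a2))
  w <- c(0.225,
         rep(0.132394152788506, 3),
         rep(0.125939180544827, 3))
  list(lam = lam, w = w, n = 7L)
}

# P2 basis values and barycentric derivatives at given barycentric coords.
p2_basis <- function(lam) {
  l1 <- lam[, 1]; l2 <- lam[, 2]; l3 <- lam[, 3]
  N <- cbind(l1 * (2 * l1 - 1), l2 * (2 * l2 - 1), l3 * (2 * l3 - 1),
             4 * l1 * l2, 4 * l2 * l3, 4 * l3 * l1)
  z <- numeric(length(l1))
  dN <- array(0, c(length(l1), 6L, 3L))
  dN[, 1, 1] <- 4 * l1 - 1
  dN[, 2, 2] <- 4 * l2 - 1
  dN[, 3, 3] <- 4 * l3 - 1
  dN[, 4, 1] <- 4 * l2; dN[, 4, 2] <- 4 * l1
  dN[, 5, 2] <- 4 * l3; dN[, 5, 3] <- 4 * l2
  dN[, 6, 3] <- 4 * l1; dN[, 6, 1] <- 4 * l3
  list(N = N, dN = dN)
}

#' Build the Taylor-Hood function space over a mesh
#'
#' Constructs the P2 (velocity/scalar) and P1 (pressure) numbering —
#' vertices first, then edge midpoints — together with per-element affine
#' geometry, quadrature tables and boundary-edge trace structures used by
#' the assembly routines. All solvers consume this object.
#'
#' @param mesh A `vessel_mesh` from [generate_mesh()] or [read_mesh()].
#' @return A list of class `"fe_space"` (fields include `np` = number of P2
#'   nodes, `nv` = number of vertices, `p2xy` = P2 node coordinates).
#' @export
fe_space <- function(mesh) {
  stopifnot(inherits(mesh, "vessel_mesh"))
  tri <- mesh$tri
  nv <- nrow(mesh$nodes)
  m <- nrow(tri)
  et <- edge_table(tri)
  edges <- et$edges
  ne <- nrow(edges)
  ekey <- edges[, 1] * (nv + 1) + edges[, 2]
  edge_id <- function(a, b) match(pmin(a, b) * (nv + 1) + pmax(a, b), ekey)
  tri6 <- cbind(tri,
                nv + edge_id(tri[, 1], tri[, 2]),
                nv + edge_id(tri[, 2], tri[, 3]),
                nv + edge_id(tri[, 3], tri[, 1]))
  p2xy <- rbind(mesh$nodes,
                (mesh$nodes[edges[, 1], ] + mesh$nodes[edges[, 2], ]) / 2)
  np <- nv + ne
  # per-element affine geometry
  p1 <- mesh$nodes[tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tri[, 3], , drop = FALSE]
  det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  area <- det / 2
  # gradients of barycentric coordinates (m x 3 per component)
  glam_z <- cbind(p2[, 2] - p3[, 2], p3[, 2] - p1[, 2], p1[, 2] - p2[, 2]) / det
  glam_x <- cbind(p3[, 1] - p2[, 1], p1[, 1] - p3[, 1], p2[, 1] - p1[, 1]) / det
  q <- tri_quadrature()
  pb <- p2_basis(q$lam)
  # physical P2 gradients per qp: lists of m x 6 matrices
  dNdz <- vector("list", q$n); dNdx <- vector("list", q$n)
  for (k in seq_len(q$n)) {
    dz <- matrix(0, m, 6); dx <- matrix(0, m, 6)
    for (a in 1:6) {
      for (j in 1:3) {
        c_aj <- pb$dN[k, a, j]
        if (c_aj != 0) {
          dz[, a] <- dz[, a] + c_aj * glam_z[, j]
          dx[, a] <- dx[, a] + c_aj * glam_x[, j]
        }
      }
    }
    dNdz[[k]] <- dz; dNdx[[k]] <- dx
  }
  # transverse coordinate (radius in axisymmetric mode) at qps: m-vector per qp
  xq <- vector("list", q$n)
  for (k in seq_len(q$n)) {
    xq[[k]] <- q$lam[k, 1] * p1[, 2] + q$lam[k, 2] * p2[, 2] + q$lam[k, 3] * p3[, 2]
  }
  axisym <- mesh$mode == "axisymmetric"
  # quadrature weights including area (and r in axisymmetric mode)
  wq <- vector("list", q$n)
  for (k in seq_len(q$n)) {
    wq[[k]] <- q$w[k] * area * (if (axisym) xq[[k]] else 1)
  }
  # boundary edge structures: P2 trace nodes, outward normal, edge qps
  bnd <- mesh$boundary
  bmid <- nv + edge_id(bnd$n1, bnd$n2)
  e1 <- mesh$nodes[bnd$n1, , drop = FALSE]
  e2 <- mesh$nodes[bnd$n2, , drop = FALSE]
  evec <- e2 - e1
  elen <- sqrt(rowSums(evec^2))
  # outward normal: away from the adjacent triangle centroid
  nrm <- cbind(evec[, 2], -evec[, 1]) / elen
  badj <- adjacent_triangle(tri, bnd)
  ctr <- (mesh$nodes[tri[badj, 1], , drop = FALSE] +
            mesh$nodes[tri[badj, 2], , drop = FALSE] +
            mesh$nodes[tri[badj, 3], , drop = FALSE]) / 3
  emid <- (e1 + e2) / 2
  flip <- rowSums(nrm * (ctr - emid)) > 0
  nrm[flip, ] <- -nrm[flip, ]
  structure(list(mesh = mesh, tri6 = tri6, p2xy = p2xy, nv = nv, np = np,
                 ne = ne, m = m, area = area, glam_z = glam_z, glam_x = glam_x,
                 q = q, Nq = pb$N, dNdz = dNdz, dNdx = dNdx, xq = xq, wq = wq,
                 axisym = axisym,
                 bnd = data.frame(n1 = bnd$n1, n2 = bnd$n2, mid = bmid,
                                  tag = bnd$tag, len = elen,
                                  nz = nrm[, 1], nx = nrm[, 2])),
            class = "fe_space")
}

# Index (first) adjacent triangle of each boundary edge.
adjacent_triangle <- function(tri, bnd) {
  nvmax <- max(tri) + 1
  tkey <- cbind(pmin(tri[, 1], tri[, 2]) * nvmax + pmax(tri[, 1], tri[, 2]),
                pmin(tri[, 2], tri[, 3]) * nvmax + pmax(tri[, 2], tri[, 3]),
                pmin(tri[, 3], tri[, 1]) * nvmax + pmax(tri[, 3], tri[, 1]))
  bkey <- pmin(bnd$n1, bnd$n2) * nvmax + pmax(bnd$n1, bnd$n2)
  hit <- match(bkey, as.vector(tkey))
  ((hit - 1) %% nrow(tri)) + 1L
}

# Generic 6x6 (P2 x P2) assembly: `contrib(k, a, b)` returns the m-vector of
# element contributions at quadrature point k for test basis a, trial b
# (already multiplied by the quadrature weight).
asm_p2p2 <- function(fe, contrib) {
  m <- fe$m
  ii <- jj <- xx <- vector("list", 36)
  idx <- 1L
  for (a in 1:6) {
    for (b in 1:6) {
      v <- numeric(m)
      for (k in seq_len(fe$q$n)) v <- v + contrib(k, a, b)
      ii[[idx]] <- fe$tri6[, a]; jj[[idx]] <- fe$tri6[, b]; xx[[idx]] <- v
      idx <- idx + 1L
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(fe$np, fe$np))
}

# P1 x P2 assembly (pressure test, velocity trial).
asm_p1p2 <- function(fe, contrib) {
  m <- fe$m
  ii <- jj <- xx <- vector("list", 18)
  idx <- 1L
  for (a in 1:3) {
    for (b in 1:6) {
      v <- numeric(m)
      for (k in seq_len(fe$q$n)) v <- v + contrib(k, a, b)
      ii[[idx]] <- fe$mesh$tri[, a]; jj[[idx]] <- fe$tri6[, b]; xx[[idx]] <- v
      idx <- idx + 1L
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(fe$nv, fe$np))
}

# P1 x P1 assembly (thermal).
asm_p1p1 <- function(fe, contrib) {
  m <- fe$m
  ii <- jj <- xx <- vector("list", 9)
  idx <- 1L
  for (a in 1:3) {
    for (b in 1:3) {
      v <- numeric(m)
      for (k in seq_len(fe$q$n)) v <- v + contrib(k, a, b)
      ii[[idx]] <- fe$mesh$tri[, a]; jj[[idx]] <- fe$mesh$tri[, b]; xx[[idx]] <- v
      idx <- idx + 1L
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(fe$nv, fe$nv))
}

# P1 basis values at quadrature points are the barycentric coordinates;
# gradients are glam. Values of a P2 field and its gradient at qp k.
p2_field_at_qp <- function(fe, vals, k) {
  V <- matrix(vals[fe$tri6], fe$m, 6)
  V %*% fe$Nq[k, ]
}
p2_grad_at_qp <- function(fe, vals, k) {
  V <- matrix(vals[fe$tri6], fe$m, 6)
  list(dz = rowSums(V * fe$dNdz[[k]]), dx = rowSums(V * fe$dNdx[[k]]))
}
p1_field_at_qp <- function(fe, vals, k) {
  V <- matrix(vals[fe$mesh$tri], fe$m, 3)
  as.vector(V %*% fe$q$lam[k, ])
}
p1_grad <- function(fe, vals) {
  V <- matrix(vals[fe$mesh$tri], fe$m, 3)
  list(dz = rowSums(V * fe$glam_z), dx = rowSums(V * fe$glam_x))
}

# 3-point Gauss rule on boundary edges with the quadratic (P2) trace.
edge_quadrature <- function() {
  t <- c(0.5 - sqrt(0.15), 0.5, 0.5 + sqrt(0.15))
  w <- c(5, 8, 5) / 18
  N <- cbind((1 - t) * (1 - 2 * t), t * (2 * t - 1), 4 * t * (1 - t))
  list(t = t, w = w, N = N)  # trace nodes ordered (n1, n2, mid)
}

# Integral over tagged boundary edges of f(u.n) style quantities.
# Returns per-edge matrices used by flow/thermal boundary terms.
edge_trace <- function(fe, tags) {
  sel <- which(fe$bnd$tag %in% tags)
  if (length(sel) == 0L) return(NULL)
  eq <- edge_quadrature()
  b <- fe$bnd[sel, , drop = FALSE]
  nodes <- cbind(b$n1, b$n2, b$mid)   # P2 trace dofs per edge
  # transverse coordinate at edge qps (axisymmetric weight)
  x1 <- fe$mesh$nodes[b$n1, 2]; x2 <- fe$mesh$nodes[b$n2, 2]
  xqp <- sapply(seq_along(eq$t), function(k) (1 - eq$t[k]) * x1 + eq$t[k] * x2)
  if (is.null(dim(xqp))) xqp <- matrix(xqp, nrow = length(sel))
  w <- if (fe$axisym) xqp else matrix(1, length(sel), length(eq$t))
  list(sel = sel, edges = b, nodes = nodes, eq = eq, wfac = w)
}
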