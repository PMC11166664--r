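# Unstructured graded meshing of the sac-bearing vessel domain.
#
# No triangulation library is assumed: a vectorised Bowyer-Watson Delaunay
# kernel plus a DistMesh-style equilibrium-spacing relaxation produce the
# graded mesh. Everything is deterministic: the only pseudo-randomness is a
# seeded linear-congruential thinning of the initial point lattice.

# --- Delaunay triangulation (Bowyer-Watson, incremental) ------------------

circumcircles <- function(pts, tri) {
  ax <- pts[tri[, 1], 1]; ay <- pts[tri[, 1], 2]
  bx <- pts[tri[, 2], 1]; by <- pts[tri[, 2], 2]
  cx <- pts[tri[, 3], 1]; cy <- pts[tri[, 3], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  cbind(ux, uy, r2)
}

#' Delaunay triangulation of a 2D point set
#'
#' Incremental Bowyer-Watson algorithm with a super-triangle. Intended for
#' the well-spaced point sets produced by the mesher (no exact-arithmetic
#' predicates).
#'
#' @param pts n x 2 matrix of distinct points.
#' @return m x 3 integer matrix of triangle vertex indices.
#' @export
delaunay <- function(pts) {
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points")
  rng <- apply(pts, 2, range)
  span <- max(rng[2, ] - rng[1, ], 1e-9)
  mid <- colMeans(rng)
  big <- 50 * span
  sup <- rbind(c(mid[1] - 2 * big, mid[2] - big),
               c(mid[1] + 2 * big, mid[2] - big),
               c(mid[1], mid[2] + 2 * big))
  allp <- rbind(sup, pts)
  cap <- 3L * n + 16L
  tri <- matrix(NA_integer_, cap, 3)
  cc <- matrix(NA_real_, cap, 3)
  alive <- logical(cap)
  tri[1, ] <- 1:3
  cc[1, ] <- circumcircles(allp, matrix(1:3, 1))
  alive[1] <- TRUE
  ntri <- 1L
  for (ip in seq_len(n)) {
    p <- allp[ip + 3L, ]
    act <- which(alive[seq_len(ntri)])
    bad <- act[(p[1] - cc[act, 1])^2 + (p[2] - cc[act, 2])^2 <
                 cc[act, 3] * (1 + 1e-12)]
    if (length(bad) == 0L) {
      # numerical fallback: point outside all circumcircles (shouldn't occur
      # inside the super-triangle); attach to nearest triangle
      stop("Delaunay insertion failed: point ", ip, " found no cavity")
    }
    e <- rbind(tri[bad, c(1, 2), drop = FALSE],
               tri[bad, c(2, 3), drop = FALSE],
               tri[bad, c(3, 1), drop = FALSE])
    ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    keep <- !(ekey %in% ekey[duplicated(ekey)])
    polyedges <- e[keep, , drop = FALSE]
    alive[bad] <- FALSE
    m <- nrow(polyedges)
    if (ntri + m > cap) {
      grow <- max(cap, ntri + m)
      tri <- rbind(tri, matrix(NA_integer_, grow, 3))
      cc <- rbind(cc, matrix(NA_real_, grow, 3))
      alive <- c(alive, logical(grow))
      cap <- cap + grow
    }
    newidx <- ntri + seq_len(m)
    tri[newidx, 1] <- polyedges[, 1]
    tri[newidx, 2] <- polyedges[, 2]
    tri[newidx, 3] <- ip + 3L
    cc[newidx, ] <- circumcircles(allp, tri[newidx, , drop = FALSE])
    alive[newidx] <- TRUE
    ntri <- ntri + m
  }
  out <- tri[which(alive[seq_len(ntri)]), , drop = FALSE]
  out <- out[rowSums(out <= 3L) == 0L, , drop = FALSE]  # drop super-triangle
  out - 3L
}

# --- DistMesh-style relaxation -------------------------------------------

# Deterministic uniform numbers in [0,1): Lehmer LCG, independent of R's RNG.
lcg_runif <- function(n, seed) {
  state <- as.double((seed %% 2147483646) + 1)
  out <- numeric(n)
  for (i in seq_len(n)) {
    state <- (state * 48271) %% 2147483647
    out[i] <- state / 2147483647
  }
  out
}

# Feature list used by the sizing field of the sac geometry.
vessel_features <- function(params, sizing, refine_near) {
  H <- params$height
  feats <- list()
  if (!is.null(refine_near)) {
    ctr <- refine_near$point; rad <- refine_near$radius
    feats <- c(feats, list(list(
      h = sizing$h_min,
      dist = function(p) pmax(sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2) - rad, 0))))
  }
  if (params$has_sac) {
    R <- params$sac_radius
    d <- sac_center_height(R, params$neck_width)
    centre <- c(params$sac_center_z, H + d)
    # curvature refinement on the arc (clamped below at h_min)
    h_arc <- max(sizing$h_min, sizing$curvature_factor * R)
    feats <- c(feats, list(list(
      h = h_arc,
      dist = function(p) abs(sqrt((p[, 1] - centre[1])^2 + (p[, 2] - centre[2])^2) - R))))
    # neck corners: the wall/arc wedge needs sub-h_min resolution to stay meshable
    for (sgn in c(-1, 1)) {
      corner <- c(params$sac_center_z + sgn * params$neck_width / 2, H)
      feats <- c(feats, list(list(
        h = sizing$h_min * sizing$narrow_resolution / 2,
        dist = function(p, cc = corner)
          sqrt((p[, 1] - cc[1])^2 + (p[, 2] - cc[2])^2))))
    }
  }
  feats
}

distmesh_vessel <- function(boundary, sizing, refine_near,
                            n_iter = 12L, move_factor = 0.2) {
  params <- boundary$params
  h_fun <- sizing_field(sizing, vessel_features(params, sizing, refine_near))
  poly <- boundary_polygon(boundary, max_ds = function(p) h_fun(p))
  bpts <- poly$points
  btags <- poly$tags
  nb <- nrow(bpts)

  # initial interior lattice at spacing ~h_min, thinned to the sizing field
  h0 <- sizing$h_min * 0.95
  zr <- range(bpts[, 1]); xr <- range(bpts[, 2])
  zs <- seq(zr[1] + h0 / 2, zr[2], by = h0)
  xs <- seq(xr[1] + h0 / 2, xr[2], by = h0 * sqrt(3) / 2)
  cand <- cbind(rep(zs, times = length(xs)), rep(xs, each = length(zs)))
  odd <- rep(seq_along(xs) %% 2 == 1, each = length(zs))
  cand[odd, 1] <- cand[odd, 1] + h0 / 2
  keepin <- points_in_polygon(cand, bpts)
  cand <- cand[keepin, , drop = FALSE]
  hc <- h_fun(cand)
  u <- lcg_runif(nrow(cand), sizing$seed)
  cand <- cand[u < (h0 / hc)^2, , drop = FALSE]
  # drop candidates crowding the fixed boundary points
  if (nrow(cand) > 0 && nb > 0) {
    mind <- rep(Inf, nrow(cand))
    for (chunk in split(seq_len(nb), ceiling(seq_len(nb) / 512))) {
      d2 <- outer(cand[, 1], bpts[chunk, 1], "-")^2 +
        outer(cand[, 2], bpts[chunk, 2], "-")^2
      mind <- pmin(mind, sqrt(apply(d2, 1, min)))
    }
    cand <- cand[mind > 0.6 * h_fun(cand), , drop = FALSE]
  }
  pts <- rbind(bpts, cand)
  fixed <- seq_len(nb)

  tri <- NULL
  for (it in seq_len(n_iter)) {
    if (it == 1L || it %% 2L == 0L) {
      tri <- delaunay(pts)
      ctr <- (pts[tri[, 1], ] + pts[tri[, 2], ] + pts[tri[, 3], ]) / 3
      tri <- tri[points_in_polygon(ctr, bpts), , drop = FALSE]
    }
    e <- unique_edges(tri)
    mid <- (pts[e[, 1], ] + pts[e[, 2], ]) / 2
    hv <- h_fun(mid)
    dvec <- pts[e[, 2], ] - pts[e[, 1], ]
    len <- sqrt(rowSums(dvec^2))
    l0 <- hv * 1.2 * sqrt(sum(len^2) / sum(hv^2))
    f <- pmax(l0 - len, 0) / pmax(len, 1e-12)
    fx <- f * dvec[, 1]; fy <- f * dvec[, 2]
    mvx <- numeric(nrow(pts)); mvy <- numeric(nrow(pts))
    agg <- rowsum(c(-fx, fx), c(e[, 1], e[, 2]))
    mvx[as.integer(rownames(agg))] <- agg
    agg <- rowsum(c(-fy, fy), c(e[, 1], e[, 2]))
    mvy[as.integer(rownames(agg))] <- agg
    mvx[fixed] <- 0; mvy[fixed] <- 0
    newpts <- pts + move_factor * cbind(mvx, mvy)
    moved <- which(mvx != 0 | mvy != 0)
    ok <- points_in_polygon(newpts[moved, , drop = FALSE], bpts)
    revert <- moved[!ok]
    newpts[revert, ] <- pts[revert, ]
    pts <- newpts
  }

  # final triangulation with boundary-edge recovery: split any prescribed
  # boundary edge missing from the Delaunay triangulation and retry
  for (round in 1:4) {
    tri <- delaunay(pts)
    ctr <- (pts[tri[, 1], ] + pts[tri[, 2], ] + pts[tri[, 3], ]) / 3
    tri <- tri[points_in_polygon(ctr, bpts), , drop = FALSE]
    miss <- missing_boundary_edges(pts, tri, length(btags))
    if (length(miss) == 0L) break
    if (round == 4L) {
      stop("meshing failure: could not recover ", length(miss),
           " boundary edges near the sac; refine h_min")
    }
    # insert midpoints of missing boundary segments as new fixed points
    res <- split_boundary(pts, btags, miss)
    pts <- res$pts; btags <- res$tags
  }
  nb <- length(btags)
  bnd <- data.frame(n1 = seq_len(nb), n2 = c(seq_len(nb - 1L) + 1L, 1L),
                    tag = btags)
  # drop unused interior points (can result from reverted moves crowding)
  used <- sort(unique(as.vector(tri)))
  if (length(used) < nrow(pts)) {
    remap <- integer(nrow(pts)); remap[used] <- seq_along(used)
    if (any(remap[seq_len(nb)] == 0L)) stop("meshing failure: boundary point unused")
    pts <- pts[used, , drop = FALSE]
    tri <- matrix(remap[tri], ncol = 3)
    bnd$n1 <- remap[bnd$n1]; bnd$n2 <- remap[bnd$n2]
  }
  region <- ifelse((pts[tri[, 1], 2] + pts[tri[, 2], 2] + pts[tri[, 3], 2]) / 3 >
                     params$height, 2L, 1L)
  new_mesh(pts, tri, bnd, region = region, mode = params$mode)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unique_edges <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  es <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  es[!duplicated(es[, 1] * (max(es) + 1) + es[, 2]), , drop = FALSE]
}

# Which prescribed boundary segments (i -> i+1 cyclic over the first nb
# points) are absent from the triangulation edge set?
missing_boundary_edges <- function(pts, tri, nb) {
  e <- unique_edges(tri)
  base <- max(e) + 1
  key <- e[, 1] * base + e[, 2]
  b1 <- seq_len(nb); b2 <- c(seq_len(nb - 1L) + 1L, 1L)
  bkey <- pmin(b1, b2) * base + pmax(b1, b2)
  which(!(bkey %in% key))
}

split_boundary <- function(pts, btags, miss) {
  nb <- length(btags)
  b2 <- c(seq_len(nb - 1L) + 1L, 1L)
  newb <- NULL; newt <- character(0)
  for (i in seq_len(nb)) {
    newb <- rbind(newb, pts[i, ])
    newt <- c(newt, btags[i])
    if (i %in% miss) {
      midp <- (pts[i, ] + pts[b2[i], ]) / 2
      newb <- rbind(newb, midp)
      newt <- c(newt, btags[i])
    }
  }
  interior <- pts[-seq_len(nb), , drop = FALSE]
  # remove interior points too close to the inserted midpoints
  if (nrow(interior) > 0 && length(miss) > 0) {
    for (i in miss) {
      midp <- (pts[i, ] + pts[b2[i], ]) / 2
      seg <- sqrt(sum((pts[b2[i], ] - pts[i, ])^2))
      d <- sqrt((interior[, 1] - midp[1])^2 + (interior[, 2] - midp[2])^2)
      interior <- interior[d > 0.5 * seg, , drop = FALSE]
    }
  }
  list(pts = rbind(newb, interior), tags = newt)
}
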