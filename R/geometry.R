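#' Parametric vessel geometry
#'
#' Describes the simulated domain: a straight vessel segment of axial length
#' `length` and transverse height `height` (the lumen width in the cut plane),
#' optionally carrying a circular-arc aneurysm sac bulging from the upper
#' wall, with a rupture orifice at the sac apex. Coordinates are `z` axial
#' (0 at the inlet) and `x` transverse (0 at the lower wall; the radius in
#' axisymmetric mode).
#'
#' The sac is the major circular segment of a circle of radius `sac_radius`
#' whose chord is the neck opening of width `neck_width` in the upper wall,
#' centred at `sac_center_z`. The orifice is an open gap of arc length
#' `orifice_width` centred at the sac apex. Sac and orifice dimensions are
#' scenario parameters (the anatomy they emulate is a sidewall aneurysm with
#' an apex rupture); all are configurable.
#'
#' @param length Axial length in m (default 0.7).
#' @param height Transverse lumen height in m (default 0.09); the tube radius
#'   in axisymmetric mode.
#' @param mode `"planar"` or `"axisymmetric"`. The sac breaks axisymmetry, so
#'   `axisymmetric` requires `has_sac = FALSE`.
#' @param sac_center_z,sac_radius,neck_width,orifice_width Sac parameters, m.
#' @param has_sac,has_orifice Flags enabling the sac and the rupture orifice.
#' @return A list of class `"vessel_geometry"`.
#' @export
vessel_geometry <- function(length = 0.7, height = 0.09,
                            mode = c("planar", "axisymmetric"),
                            sac_center_z = 0.30, sac_radius = 0.025,
                            neck_width = 0.035, orifice_width = 0.008,
                            has_sac = TRUE, has_orifice = has_sac) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(length), length > 0, is.numeric(height), height > 0)
  if (has_orifice && !has_sac) stop("an orifice requires a sac")
  if (mode == "axisymmetric" && has_sac) {
    stop("the sidewall sac breaks axisymmetry: axisymmetric mode requires has_sac = FALSE")
  }
  if (has_sac) {
    if (neck_width <= 0 || neck_width >= length) stop("0 < neck_width < length required")
    if (sac_radius < neck_width / 2) {
      stop("sac_radius must be at least neck_width / 2 for the neck chord to fit the circle")
    }
    if (sac_center_z - neck_width / 2 <= 0 || sac_center_z + neck_width / 2 >= length) {
      stop("sac neck must lie strictly inside the upper wall")
    }
    if (has_orifice) {
      arc_len <- sac_radius * sac_arc_angle(sac_radius, neck_width)
      if (orifice_width <= 0 || orifice_width >= arc_len) {
        stop("orifice_width must be positive and smaller than the sac arc length (",
             signif(arc_len, 4), " m)")
      }
    }
  }
  structure(list(length = length, height = height, mode = mode,
                 sac_center_z = sac_center_z, sac_radius = sac_radius,
                 neck_width = neck_width, orifice_width = orifice_width,
                 has_sac = has_sac, has_orifice = has_orifice),
            class = "vessel_geometry")
}

# Angle subtended at the circle centre by the sac arc (major arc over the top).
sac_arc_angle <- function(R, neck_width) {
  alpha <- asin((neck_width / 2) / R)  # half-angle of the minor (chord) side
  2 * pi - 2 * alpha
}

# Sac circle centre height above the wall line.
sac_center_height <- function(R, neck_width) sqrt(R^2 - (neck_width / 2)^2)

#' Closed-form area of the sac (major circular segment)
#'
#' @param sac_radius Circle radius in m.
#' @param neck_width Chord (neck) width in m.
#' @return Area in m^2.
#' @export
sac_segment_area <- function(sac_radius, neck_width) {
  theta <- sac_arc_angle(sac_radius, neck_width)
  sac_radius^2 * (theta - sin(theta)) / 2
}

#' Build the tagged boundary description of a vessel geometry
#'
#' Produces the domain boundary as an ordered, counter-clockwise sequence of
#' geometric primitives (straight segments and circular arcs), each carrying
#' a boundary tag: `INLET` (left edge), `OUTLET` (right edge), `WALL`
#' (vessel and sac walls), `RUPTURE` (the open orifice gap on the sac arc)
#' and, in axisymmetric mode, `AXIS` (the symmetry axis x = 0).
#'
#' @param params A [vessel_geometry()].
#' @return A list of class `"vessel_boundary"` with elements `params` and
#'   `primitives` (ordered list of tagged segments/arcs).
#' @export
build_geometry <- function(params) {
  stopifnot(inherits(params, "vessel_geometry"))
  L <- params$length; H <- params$height
  lower_tag <- if (params$mode == "axisymmetric") "AXIS" else "WALL"
  prim <- list(
    list(kind = "line", from = c(0, 0), to = c(L, 0), tag = lower_tag),
    list(kind = "line", from = c(L, 0), to = c(L, H), tag = "OUTLET")
  )
  if (!params$has_sac) {
    prim <- c(prim, list(
      list(kind = "line", from = c(L, H), to = c(0, H), tag = "WALL")
    ))
  } else {
    zc <- params$sac_center_z; R <- params$sac_radius; w <- params$neck_width
    d <- sac_center_height(R, w)
    centre <- c(zc, H + d)
    aR <- atan2(-d, w / 2)            # angle of right neck endpoint
    aL <- atan2(-d, -w / 2) + 2 * pi  # left endpoint, reached CCW over the top
    prim <- c(prim, list(
      list(kind = "line", from = c(L, H), to = c(zc + w / 2, H), tag = "WALL")
    ))
    if (params$has_orifice) {
      half <- (params$orifice_width / 2) / R  # half orifice angle
      apex <- pi / 2
      prim <- c(prim, list(
        list(kind = "arc", centre = centre, radius = R, a0 = aR,
             a1 = apex - half, tag = "WALL"),
        list(kind = "arc", centre = centre, radius = R, a0 = apex - half,
             a1 = apex + half, tag = "RUPTURE"),
        list(kind = "arc", centre = centre, radius = R, a0 = apex + half,
             a1 = aL, tag = "WALL")
      ))
    } else {
      prim <- c(prim, list(
        list(kind = "arc", centre = centre, radius = R, a0 = aR, a1 = aL,
             tag = "WALL")
      ))
    }
    prim <- c(prim, list(
      list(kind = "line", from = c(zc - w / 2, H), to = c(0, H), tag = "WALL")
    ))
  }
  prim <- c(prim, list(
    list(kind = "line", from = c(0, H), to = c(0, 0), tag = "INLET")
  ))
  structure(list(params = params, primitives = prim), class = "vessel_boundary")
}

primitive_length <- function(p) {
  if (p$kind == "line") sqrt(sum((p$to - p$from)^2))
  else p$radius * abs(p$a1 - p$a0)
}

primitive_point <- function(p, s) {
  # s in [0, 1] along the primitive
  if (p$kind == "line") {
    cbind(p$from[1] + s * (p$to[1] - p$from[1]),
          p$from[2] + s * (p$to[2] - p$from[2]))
  } else {
    a <- p$a0 + s * (p$a1 - p$a0)
    cbind(p$centre[1] + p$radius * cos(a), p$centre[2] + p$radius * sin(a))
  }
}

#' Discretise a vessel boundary into a closed tagged polygon
#'
#' @param boundary A [build_geometry()] result.
#' @param max_ds Maximum chord length of the discretisation, m. May be a
#'   function `f(points_matrix) -> spacing vector` for nonuniform spacing.
#' @return A list with `points` (n x 2 matrix, closed loop without repeated
#'   first point) and `tags` (length n; tag of the edge from point i to i+1).
#' @export
boundary_polygon <- function(boundary, max_ds = 0.005) {
  stopifnot(inherits(boundary, "vessel_boundary"))
  pts <- NULL; tags <- character(0)
  for (p in boundary$primitives) {
    len <- primitive_length(p)
    if (is.function(max_ds)) {
      # graded subdivision: equal partition of integral of 1/h along the curve
      sfine <- seq(0, 1, length.out = 257)
      h <- pmax(max_ds(primitive_point(p, sfine)), 1e-12)
      inv <- 1 / h
      cum <- cumsum(c(0, (inv[-1] + inv[-length(inv)]) / 2 * diff(sfine) * len))
      n <- max(1L, ceiling(cum[length(cum)]))
      targets <- seq(0, cum[length(cum)], length.out = n + 1L)
      s <- stats::approx(cum, sfine, xout = targets)$y
    } else {
      n <- max(1L, ceiling(len / max_ds))
      s <- seq(0, 1, length.out = n + 1L)
    }
    newp <- primitive_point(p, s)
    pts <- rbind(pts, newp[-nrow(newp), , drop = FALSE])
    tags <- c(tags, rep(p$tag, nrow(newp) - 1L))
  }
  list(points = pts, tags = tags)
}

#' Shoelace area of a closed polygon
#' @param points n x 2 matrix of vertices in order (not repeated at the end).
#' @return Signed area (positive for counter-clockwise orientation).
#' @export
polygon_area <- function(points) {
  z <- points[, 1]; x <- points[, 2]
  zn <- c(z[-1], z[1]); xn <- c(x[-1], x[1])
  sum(z * xn - zn * x) / 2
}

# Even-odd point-in-polygon, vectorised over query points (n x 2).
points_in_polygon <- function(p, poly) {
  n <- nrow(poly)
  px <- p[, 1]; py <- p[, 2]
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
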