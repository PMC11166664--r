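# Field sampling, extremes tables and reference comparison.

# Locate points in the mesh; returns triangle index and barycentric coords.
locate_points <- function(fe, pts, tol = 1e-9) {
  m <- fe$m
  p1 <- fe$mesh$nodes[fe$mesh$tri[, 1], , drop = FALSE]
  tri_idx <- integer(nrow(pts)); lam <- matrix(0, nrow(pts), 3)
  for (i in seq_len(nrow(pts))) {
    dz <- pts[i, 1] - p1[, 1]; dx <- pts[i, 2] - p1[, 2]
    l2 <- fe$glam_z[, 2] * dz + fe$glam_x[, 2] * dx
    l3 <- fe$glam_z[, 3] * dz + fe$glam_x[, 3] * dx
    l1 <- 1 - l2 - l3
    ok <- which(l1 >= -tol & l2 >= -tol & l3 >= -tol)
    if (length(ok) == 0L) {
      stop(sprintf("point (%.6g, %.6g) lies outside the mesh",
                   pts[i, 1], pts[i, 2]))
    }
    j <- ok[1]
    tri_idx[i] <- j
    lam[i, ] <- pmin(pmax(c(l1[j], l2[j], l3[j]), 0), 1)
  }
  list(tri = tri_idx, lam = lam / rowSums(lam))
}

eval_p2 <- function(fe, vals, loc) {
  pb <- p2_basis(loc$lam)
  V <- matrix(vals[fe$tri6[loc$tri, ]], length(loc$tri), 6)
  rowSums(V * pb$N)
}

eval_p1 <- function(fe, vals, loc) {
  V <- matrix(vals[fe$mesh$tri[loc$tri, ]], length(loc$tri), 3)
  rowSums(V * loc$lam)
}

#' Sample a field along a straight segment
#'
#' Finite-element interpolation (quadratic for velocity-based fields, linear
#' for pressure/temperature) at `n` equispaced points from `start` to `end`.
#'
#' @param state A [flow_state()] or [thermal_state()]; or a bare numeric
#'   vector of P1 (length `nv`) or P2 (length `np`) nodal values.
#' @param fe The matching [fe_space()].
#' @param start,end Segment endpoints `c(z, x)`, inside the domain.
#' @param n Number of sample points (>= 2).
#' @param field For a `flow_state`: `"speed"` (default), `"u3"`, `"u1"` or
#'   `"pressure"`.
#' @return A tibble of class `"line_sample"` with columns
#'   `s` (arc length), `z`, `x`, `value` and an attribute `t` (time).
#' @export
sample_line <- function(state, fe, start, end, n = 200, field = "speed") {
  stopifnot(n >= 2)
  s <- seq(0, 1, length.out = n)
  pts <- cbind(start[1] + s * (end[1] - start[1]),
               start[2] + s * (end[2] - start[2]))
  loc <- locate_points(fe, pts)
  tsnap <- NA_real_
  if (inherits(state, "flow_state")) {
    tsnap <- state$t
    vals <- switch(field,
      speed = sqrt(eval_p2(fe, state$velocity[, 1], loc)^2 +
                     eval_p2(fe, state$velocity[, 2], loc)^2),
      u3 = eval_p2(fe, state$velocity[, 1], loc),
      u1 = eval_p2(fe, state$velocity[, 2], loc),
      pressure = eval_p1(fe, state$pressure, loc),
      stop("unknown field: ", field))
  } else if (inherits(state, "thermal_state")) {
    tsnap <- state$t
    vals <- eval_p1(fe, state$temperature, loc)
  } else if (is.numeric(state) && length(state) == fe$nv) {
    vals <- eval_p1(fe, state, loc)
  } else if (is.numeric(state) && length(state) == fe$np) {
    vals <- eval_p2(fe, state, loc)
  } else {
    stop("state must be a flow_state, thermal_state, or nodal vector")
  }
  if (any(!is.finite(vals))) stop("non-finite sampled values")
  out <- tibble::tibble(s = s * sqrt(sum((end - start)^2)),
                        z = pts[, 1], x = pts[, 2], value = vals)
  class(out) <- c("line_sample", class(out))
  attr(out, "t") <- tsnap
  out
}

default_reporting_line <- function(fe) {
  L <- max(fe$mesh$nodes[, 1])
  H <- if (fe$axisym) 0 else max(fe$mesh$nodes[, 2]) / 2
  list(start = c(0.1 * L, H), end = c(L, H))
}

#' Per-time extremes of velocity, pressure and temperature
#'
#' For each requested output time the domain-wide maximum/minimum of the
#' speed and pressure (and temperature when present) are scanned from the
#' stored fields. Because no-slip walls force the domain-wide minimum speed
#' to zero, line-restricted extremes along the reporting centerline (beyond
#' the inlet development region) are also emitted as `v_max_line` /
#' `v_min_line`; published line-graph tables correspond to the latter.
#'
#' @param trajectory A `run_trajectory` (from [run_scenario()] or
#'   [simulate_transient()]).
#' @param times Requested times, s (default: all stored). Each must match a
#'   stored snapshot within `dt / 2`.
#' @param line Optional `list(start, end)` overriding the reporting line.
#' @param n_line Number of line sample points.
#' @return A tibble of class `"extremes_table"`.
#' @export
extremes <- function(trajectory, times = NULL, line = NULL, n_line = 400) {
  snaps <- trajectory$snapshots
  if (length(snaps) == 0L) stop("empty trajectory")
  fe <- trajectory$fe
  stored <- vapply(snaps, function(s) s$t, numeric(1))
  if (is.null(times)) times <- stored
  dt <- trajectory$dt %||% min(diff(sort(unique(stored))), Inf)
  if (is.null(line)) line <- default_reporting_line(fe)
  rows <- lapply(times, function(tt) {
    j <- which.min(abs(stored - tt))
    if (abs(stored[j] - tt) > dt / 2 + 1e-12) {
      stop("no stored snapshot within dt/2 of t = ", tt)
    }
    sn <- snaps[[j]]
    speed <- sqrt(rowSums(sn$flow$velocity^2))
    ls <- sample_line(sn$flow, fe, line$start, line$end, n = n_line,
                      field = "speed")
    row <- tibble::tibble(
      t = stored[j],
      v_max = max(speed), v_min = min(speed),
      p_max = max(sn$flow$pressure), p_min = min(sn$flow$pressure),
      v_max_line = max(ls$value), v_min_line = min(ls$value))
    if (!is.null(sn$thermal)) {
      row$T_max <- max(sn$thermal$temperature)
      row$T_min <- min(sn$thermal$temperature)
    }
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$t), ]
  stopifnot(all(out$v_min <= out$v_max), all(out$p_min <= out$p_max))
  class(out) <- c("extremes_table", class(out))
  out
}

#' Published reference extremes table
#'
#' The study's reported per-time maxima/minima of line-graph velocity and
#' pressure, shipped as package data. The velocity columns are line-graph
#' (not domain-wide) readings; see [compare_extremes()].
#'
#' @return A tibble with columns `t, v_max, v_min, p_max, p_min`.
#' @export
reference_extremes <- function() {
  path <- system.file("extdata", "reference_extremes.csv", package = "hemofem")
  tibble::as_tibble(utils::read.csv(path))
}

#' Compare an extremes table against a reference
#'
#' Signed relative deviation `(report - reference) / reference` per cell for
#' the times shared by both tables. The reference velocity extremes are
#' line-graph readings, so by default they are compared against the
#' line-restricted columns of the report; pressures are compared
#' domain-wide.
#'
#' @param report An [extremes()] table.
#' @param reference A reference table (default [reference_extremes()]).
#' @param velocity `"line"` (default) or `"domain"`: which report velocity
#'   columns to compare.
#' @return A tibble with one row per time and the four signed relative
#'   deviations `dv_max, dv_min, dp_max, dp_min`.
#' @export
compare_extremes <- function(report, reference = reference_extremes(),
                             velocity = c("line", "domain")) {
  velocity <- match.arg(velocity)
  tmatch <- match(round(reference$t, 9), round(report$t, 9))
  if (any(is.na(tmatch))) {
    stop("report lacks times required by the reference: ",
         paste(reference$t[is.na(tmatch)], collapse = ", "))
  }
  rep_v_max <- if (velocity == "line") report$v_max_line else report$v_max
  rep_v_min <- if (velocity == "line") report$v_min_line else report$v_min
  tibble::tibble(
    t = reference$t,
    dv_max = (rep_v_max[tmatch] - reference$v_max) / reference$v_max,
    dv_min = (rep_v_min[tmatch] - reference$v_min) / reference$v_min,
    dp_max = (report$p_max[tmatch] - reference$p_max) / reference$p_max,
    dp_min = (report$p_min[tmatch] - reference$p_min) / reference$p_min)
}
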