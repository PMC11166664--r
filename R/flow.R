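#' Flow boundary conditions
#'
#' @param v0 Inlet speed, m s-1 (default 0.08, chosen inside the study's
#'   reported velocity range; the inflow magnitude itself is a scenario
#'   parameter).
#' @param p_out Outlet normal-traction magnitude, Pa (default 13000, the
#'   typical internal artery pressure).
#' @param p_rupture External pressure at the rupture orifice, Pa (default
#'   12990, the lowest reported line-graph pressure); must not exceed
#'   `p_out`.
#' @param inlet_profile `"plug"` (uniform `v0`, kept discontinuous at the
#'   wall corners) or `"parabolic"` (same mean speed, used for
#'   verification).
#' @param backflow_beta Dimensionless backflow-suppression coefficient on
#'   open boundaries (default 0.5).
#' @return A list of class `"flow_bcs"`.
#' @export
flow_bcs <- function(v0 = 0.08, p_out = 13000, p_rupture = 12990,
                     inlet_profile = c("plug", "parabolic"),
                     backflow_beta = 0.5) {
  inlet_profile <- match.arg(inlet_profile)
  stopifnot(v0 >= 0, backflow_beta >= 0)
  if (p_rupture > p_out) {
    stop("p_rupture must not exceed p_out (the orifice leaks outward)")
  }
  structure(list(v0 = v0, p_out = p_out, p_rupture = p_rupture,
                 inlet_profile = inlet_profile, backflow_beta = backflow_beta),
            class = "flow_bcs")
}

#' Flow solver configuration
#'
#' @param dt Time step, s (default 0.01).
#' @param t_end Final time, s (default 2.4).
#' @param time_scheme `"bdf2"` (second-order backward differencing with one
#'   implicit-Euler startup step, the default) or `"euler"`.
#' @param picard_tol Relative increment tolerance of the Picard
#'   linearisation (default 1e-8).
#' @param picard_max Maximum Picard iterations per step (default 25).
#' @param include_convection Set `FALSE` for the Stokes limit.
#' @param relax Picard under-relaxation factor in (0, 1] (default 1).
#' @return A list of class `"flow_config"`.
#' @export
flow_config <- function(dt = 0.01, t_end = 2.4,
                        time_scheme = c("bdf2", "euler"),
                        picard_tol = 1e-8, picard_max = 60L,
                        include_convection = TRUE, relax = 1) {
  time_scheme <- match.arg(time_scheme)
  stopifnot(dt > 0, t_end >= dt, picard_tol > 0, picard_max >= 1,
            relax > 0, relax <= 1)
  structure(list(dt = dt, t_end = t_end, time_scheme = time_scheme,
                 picard_tol = picard_tol, picard_max = as.integer(picard_max),
                 include_convection = include_convection, relax = relax),
            class = "flow_config")
}

#' Discrete flow state
#'
#' @param fe An `fe_space` (see [fe_space()]; built internally by the
#'   solvers).
#' @param t Time, s.
#' @param velocity `np x 2` matrix of P2 nodal velocities, columns
#'   `(u3, u1)` = (axial, transverse), m s-1.
#' @param pressure Length-`nv` vector of P1 nodal pressures, Pa.
#' @return A list of class `"flow_state"`.
#' @export
flow_state <- function(fe, t = 0, velocity = NULL, pressure = NULL) {
  if (is.null(velocity)) velocity <- matrix(0, fe$np, 2)
  if (is.null(pressure)) pressure <- numeric(fe$nv)
  stopifnot(nrow(velocity) == fe$np, length(pressure) == fe$nv)
  colnames(velocity) <- c("u3", "u1")
  structure(list(t = t, velocity = velocity, pressure = pressure),
            class = "flow_state")
}

# --- assembly -------------------------------------------------------------

# Constant (solution-independent) operator blocks: viscous stress, velocity
# mass, pressure/continuity coupling. Cached per (fe, props).
flow_operators <- function(fe, props) {
  mu <- props$mu; rho <- props$rho
  dz <- fe$dNdz; dx <- fe$dNdx; wq <- fe$wq; Nq <- fe$Nq
  A11 <- asm_p2p2(fe, function(k, a, b)
    mu * wq[[k]] * (2 * dz[[k]][, a] * dz[[k]][, b] + dx[[k]][, a] * dx[[k]][, b]))
  A22 <- asm_p2p2(fe, function(k, a, b)
    mu * wq[[k]] * (dz[[k]][, a] * dz[[k]][, b] + 2 * dx[[k]][, a] * dx[[k]][, b]))
  A12 <- asm_p2p2(fe, function(k, a, b)
    mu * wq[[k]] * (dx[[k]][, a] * dz[[k]][, b]))
  if (fe$axisym) {
    # hoop-strain contribution 2 mu u_r v_r / r^2 (r-weighted): note
    # wq already carries one factor of r
    A22 <- A22 + asm_p2p2(fe, function(k, a, b)
      2 * mu * wq[[k]] / fe$xq[[k]]^2 * Nq[k, a] * Nq[k, b])
  }
  M <- asm_p2p2(fe, function(k, a, b) rho * wq[[k]] * Nq[k, a] * Nq[k, b])
  B1 <- asm_p1p2(fe, function(k, a, b) wq[[k]] * fe$q$lam[k, a] * dz[[k]][, b])
  B2 <- asm_p1p2(fe, function(k, a, b) wq[[k]] * fe$q$lam[k, a] * dx[[k]][, b])
  if (fe$axisym) {
    B2 <- B2 + asm_p1p2(fe, function(k, a, b)
      wq[[k]] / fe$xq[[k]] * fe$q$lam[k, a] * Nq[k, b])
  }
  list(A11 = A11, A12 = A12, A22 = A22, M = M, B1 = B1, B2 = B2)
}

# Newton contribution of the convection term: blocks of
# rho * (u . grad w, v), i.e. D[c,d] = rho * int N_a N_b dw_c/dx_d.
# Returned with the matching right-hand-side vector D w (Newton in
# quasi-linear form: [C(w) + D(w)] u = b + D(w) w).
newton_convection <- function(fe, rho, w) {
  blocks <- list()
  for (c_comp in 1:2) {
    g <- list()
    for (k in seq_len(fe$q$n)) g[[k]] <- p2_grad_at_qp(fe, w[, c_comp], k)
    blocks[[paste0("D", c_comp, 1)]] <- asm_p2p2(fe, function(k, a, b)
      rho * fe$wq[[k]] * fe$Nq[k, a] * fe$Nq[k, b] * g[[k]]$dz)
    blocks[[paste0("D", c_comp, 2)]] <- asm_p2p2(fe, function(k, a, b)
      rho * fe$wq[[k]] * fe$Nq[k, a] * fe$Nq[k, b] * g[[k]]$dx)
  }
  rhs <- c(as.vector(blocks$D11 %*% w[, 1] + blocks$D12 %*% w[, 2]),
           as.vector(blocks$D21 %*% w[, 1] + blocks$D22 %*% w[, 2]))
  list(blocks = blocks, rhs = rhs)
}

# Convection block N(w): rho * (w . grad u, v), identical for both velocity
# components. w is an np x 2 matrix (axial, transverse).
convection_block <- function(fe, rho, w) {
  W1 <- matrix(w[fe$tri6, 1], fe$m, 6)
  W2 <- matrix(w[fe$tri6, 2], fe$m, 6)
  wz <- lapply(seq_len(fe$q$n), function(k) W1 %*% fe$Nq[k, ])
  wx <- lapply(seq_len(fe$q$n), function(k) W2 %*% fe$Nq[k, ])
  asm_p2p2(fe, function(k, a, b)
    rho * fe$wq[[k]] * fe$Nq[k, a] *
      (wz[[k]] * fe$dNdz[[k]][, b] + wx[[k]] * fe$dNdx[[k]][, b]))
}

#' Assemble the linearised flow system
#'
#' Builds the coupled Taylor-Hood system for one Picard iterate: momentum
#' with the full symmetric-gradient viscous stress `mu (grad v + grad v^T)`,
#' zero body force, convection linearised about `w`, and the discrete
#' continuity constraint. In axisymmetric mode all integrals are
#' r-weighted and the hoop terms are included. Boundary conditions are
#' applied separately by [apply_flow_bcs()].
#'
#' @param fe An [fe_space()].
#' @param props [effective_bundle()] properties (`mu > 0` required).
#' @param w `np x 2` matrix: velocity about which convection is linearised.
#' @param mass_coef Coefficient multiplying the velocity mass matrix
#'   (0 for steady problems, `1.5/dt` for BDF2, `1/dt` for implicit Euler).
#' @param include_convection Logical.
#' @param ops Optional precomputed [flow_operators()] cache.
#' @return List with the system matrix `A` (dofs `[u3, u1, p]`), the
#'   right-hand side `b`, and the cached operators.
#' @export
assemble_flow_system <- function(fe, props, w = NULL, mass_coef = 0,
                                 include_convection = TRUE, ops = NULL) {
  if (props$mu <= 0) stop("dynamic viscosity must be positive")
  if (is.null(ops)) ops <- flow_operators(fe, props)
  np <- fe$np; nv <- fe$nv
  Avv11 <- ops$A11
  Avv22 <- ops$A22
  if (mass_coef != 0) {
    Avv11 <- Avv11 + mass_coef * ops$M
    Avv22 <- Avv22 + mass_coef * ops$M
  }
  if (include_convection && !is.null(w) && any(w != 0)) {
    Nw <- convection_block(fe, props$rho, w)
    Avv11 <- Avv11 + Nw
    Avv22 <- Avv22 + Nw
  }
  A <- rbind(
    cbind(Avv11, ops$A12, -Matrix::t(ops$B1)),
    cbind(Matrix::t(ops$A12), Avv22, -Matrix::t(ops$B2)),
    cbind(ops$B1, ops$B2, Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                               x = numeric(0), dims = c(nv, nv)))
  )
  list(A = A, b = numeric(2 * np + nv), ops = ops, fe = fe, props = props)
}

# Dirichlet velocity values per P2 node for the given boundary conditions.
# Returns list(idx = constrained dof indices, val = values). Priority:
# INLET > WALL > AXIS (the plug inlet keeps its corner discontinuity).
dirichlet_velocity <- function(fe, bcs) {
  np <- fe$np
  tag_nodes <- function(tags) {
    sel <- fe$bnd$tag %in% tags
    unique(c(fe$bnd$n1[sel], fe$bnd$n2[sel], fe$bnd$mid[sel]))
  }
  inlet <- tag_nodes("INLET")
  wall <- setdiff(tag_nodes("WALL"), inlet)
  axis <- setdiff(tag_nodes("AXIS"), c(inlet, wall))
  idx <- c(); val <- c()
  if (length(wall)) {
    idx <- c(idx, wall, np + wall); val <- c(val, numeric(2 * length(wall)))
  }
  if (length(axis)) {  # symmetry axis: radial velocity only
    idx <- c(idx, np + axis); val <- c(val, numeric(length(axis)))
  }
  if (length(inlet)) {
    x <- fe$p2xy[inlet, 2]
    H <- max(fe$mesh$nodes[, 2])
    u_ax <- if (bcs$inlet_profile == "plug") {
      rep(bcs$v0, length(inlet))
    } else if (fe$axisym) {
      2 * bcs$v0 * (1 - (x / H)^2)
    } else {
      6 * bcs$v0 * (x / H) * (1 - x / H)   # max = 1.5 v0 at midline
    }
    idx <- c(idx, inlet, np + inlet)
    val <- c(val, u_ax, numeric(length(inlet)))
  }
  list(idx = idx, val = val)
}

#' Apply boundary conditions to an assembled flow system
#'
#' Strong no-slip on `WALL`, strong inlet velocity (`v0` plug or parabolic
#' with the same mean), radial-velocity symmetry on `AXIS`, and weak normal
#' traction `-p0 n` on `OUTLET` (`p_out`) and `RUPTURE` (`p_rupture`) with
#' the backflow-suppression penalty
#' `beta rho max(-w.n, 0) (u, v)` on those open boundaries. If no open
#' boundary is present the pressure nullspace is detected and one pressure
#' dof is pinned.
#'
#' @param sys Output of [assemble_flow_system()].
#' @param bcs A [flow_bcs()].
#' @param w Linearisation velocity (for the backflow term).
#' @return List with constrained matrix/rhs and the constraint bookkeeping.
#' @export
apply_flow_bcs <- function(sys, bcs, w = NULL) {
  fe <- sys$fe
  np <- fe$np; nv <- fe$nv
  known <- unique(fe$bnd$tag)
  bad <- setdiff(known, c("INLET", "OUTLET", "WALL", "RUPTURE", "AXIS"))
  if (length(bad)) stop("untagged/unknown boundary portions: ",
                        paste(bad, collapse = ", "))
  A <- sys$A; b <- sys$b
  # weak traction on open boundaries
  open <- list(OUTLET = bcs$p_out, RUPTURE = bcs$p_rupture)
  has_open <- FALSE
  for (tag in names(open)) {
    tr <- edge_trace(fe, tag)
    if (is.null(tr)) next
    has_open <- TRUE
    p0 <- open[[tag]]
    eq <- tr$eq
    for (k in seq_along(eq$t)) {
      wk <- eq$w[k] * tr$edges$len * tr$wfac[, k]
      for (a in 1:3) {
        contrib_z <- -p0 * tr$edges$nz * eq$N[k, a] * wk
        contrib_x <- -p0 * tr$edges$nx * eq$N[k, a] * wk
        b[tr$nodes[, a]] <- b[tr$nodes[, a]] + contrib_z
        b[np + tr$nodes[, a]] <- b[np + tr$nodes[, a]] + contrib_x
      }
    }
    # backflow suppression (penalises re-entrant flow)
    if (!is.null(w) && bcs$backflow_beta > 0) {
      ii <- jj <- xx <- list()
      for (k in seq_along(eq$t)) {
        wk <- eq$w[k] * tr$edges$len * tr$wfac[, k]
        wn <- (w[tr$nodes[, 1], 1] * eq$N[k, 1] + w[tr$nodes[, 2], 1] * eq$N[k, 2] +
                 w[tr$nodes[, 3], 1] * eq$N[k, 3]) * tr$edges$nz +
          (w[tr$nodes[, 1], 2] * eq$N[k, 1] + w[tr$nodes[, 2], 2] * eq$N[k, 2] +
             w[tr$nodes[, 3], 2] * eq$N[k, 3]) * tr$edges$nx
        pen <- bcs$backflow_beta * sys$props$rho * pmax(-wn, 0) * wk
        for (a in 1:3) for (bb in 1:3) {
          v <- pen * eq$N[k, a] * eq$N[k, bb]
          ii <- c(ii, list(tr$nodes[, a], np + tr$nodes[, a]))
          jj <- c(jj, list(tr$nodes[, bb], np + tr$nodes[, bb]))
          xx <- c(xx, list(v, v))
        }
      }
      A <- A + Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                    x = unlist(xx), dims = dim(A))
    }
  }
  dir <- dirichlet_velocity(fe, bcs)
  pinned_pressure <- FALSE
  if (!has_open) {
    # all-Dirichlet velocity: the pressure is defined up to a constant
    pinned_pressure <- TRUE
    dir$idx <- c(dir$idx, 2 * np + 1L)
    dir$val <- c(dir$val, 0)
  }
  list(A = A, b = b, dir = dir, pinned_pressure = pinned_pressure,
       fe = fe, props = sys$props)
}

# Solve a constrained linear system by elimination of Dirichlet dofs.
solve_constrained <- function(A, b, dir) {
  n <- length(b)
  free <- setdiff(seq_len(n), dir$idx)
  xc <- numeric(n)
  xc[dir$idx] <- dir$val
  rhs <- b[free] - as.vector(A[free, dir$idx, drop = FALSE] %*% dir$val)
  x <- numeric(n)
  x[dir$idx] <- dir$val
  sol <- Matrix::solve(A[free, free], rhs)
  x[free] <- as.vector(sol)
  if (any(!is.finite(x))) stop("linear solve produced non-finite values")
  x
}

unpack_solution <- function(fe, x) {
  np <- fe$np
  list(velocity = cbind(u3 = x[seq_len(np)], u1 = x[np + seq_len(np)]),
       pressure = x[2 * np + seq_len(fe$nv)])
}

# One Picard-converged solve of the (possibly time-discrete) system.
picard_solve <- function(fe, props, bcs, config, mass_coef, rhs_time = NULL,
                         w0 = NULL, ops = NULL) {
  np <- fe$np
  w <- if (is.null(w0)) matrix(0, np, 2) else w0
  history <- numeric(0)
  delta_prev <- NULL
  omega <- config$relax
  newton <- FALSE       # Picard (Aitken-relaxed) start, Newton finish
  for (it in seq_len(config$picard_max)) {
    sys <- assemble_flow_system(fe, props, w = w, mass_coef = mass_coef,
                                include_convection = config$include_convection,
                                ops = ops)
    ops <- sys$ops
    if (!is.null(rhs_time)) sys$b <- sys$b + rhs_time
    if (newton) {
      nc <- newton_convection(fe, props$rho, w)
      iu <- seq_len(np)
      sys$A[iu, iu] <- sys$A[iu, iu] + nc$blocks$D11
      sys$A[iu, np + iu] <- sys$A[iu, np + iu] + nc$blocks$D12
      sys$A[np + iu, iu] <- sys$A[np + iu, iu] + nc$blocks$D21
      sys$A[np + iu, np + iu] <- sys$A[np + iu, np + iu] + nc$blocks$D22
      sys$b[seq_len(2 * np)] <- sys$b[seq_len(2 * np)] + nc$rhs
    }
    con <- apply_flow_bcs(sys, bcs, w = w)
    x <- solve_constrained(con$A, con$b, con$dir)
    sol <- unpack_solution(fe, x)
    delta <- sol$velocity - w
    if (!newton && config$relax >= 1 && !is.null(delta_prev)) {
      dd <- delta_prev - delta
      nd2 <- sum(dd^2)
      if (nd2 > 0) omega <- min(max(omega * sum(delta_prev * dd) / nd2, 0.1), 2)
    }
    unew <- w + (if (newton) 1 else omega) * delta
    delta_prev <- delta
    denom <- max(sqrt(sum(unew^2)), 1e-14)
    incr_abs <- sqrt(sum((unew - w)^2))
    incr <- incr_abs / denom
    history <- c(history, incr)
    w <- unew
    # absolute floor: below ~1e-10 m/s the increment is linear-solver noise
    converged <- incr < config$picard_tol || incr_abs < 1e-10
    if (converged || !config$include_convection) break
    if (!newton && incr < 1e-3) { newton <- TRUE; delta_prev <- NULL }
  }
  if (config$include_convection && incr >= config$picard_tol &&
      incr_abs >= 1e-10 && it == config$picard_max) {
    stop("Picard iteration did not converge: residual history ",
         paste(signif(history, 3), collapse = ", "))
  }
  list(velocity = w, pressure = sol$pressure, iterations = it,
       final_increment = incr, pinned = con$pinned_pressure, ops = ops)
}

#' Advance the flow by one time step
#'
#' BDF2 time discretisation (implicit-Euler startup) with Picard-lagged
#' convection, solved to the configured relative-increment tolerance.
#'
#' @param fe An [fe_space()].
#' @param props Effective properties.
#' @param bcs A [flow_bcs()].
#' @param config A [flow_config()].
#' @param state Current [flow_state()].
#' @param prev_state State one step earlier (`NULL` on the first step:
#'   implicit Euler is used).
#' @param ops Optional cached operators.
#' @return The new `flow_state` (with `iterations`, `final_increment` and
#'   cached `ops` attached as attributes).
#' @export
step_flow <- function(fe, props, bcs, config, state, prev_state = NULL,
                      ops = NULL) {
  dt <- config$dt
  if (is.null(ops)) ops <- flow_operators(fe, props)
  un <- state$velocity
  use_bdf2 <- config$time_scheme == "bdf2" && !is.null(prev_state)
  if (use_bdf2) {
    mass_coef <- 1.5 / dt
    ustar <- (2 * un - 0.5 * prev_state$velocity) / dt
    w0 <- 2 * un - prev_state$velocity       # extrapolated initial iterate
  } else {
    mass_coef <- 1 / dt
    ustar <- un / dt
    w0 <- un
  }
  rhs_time <- c(as.vector(ops$M %*% ustar[, 1]), as.vector(ops$M %*% ustar[, 2]),
                numeric(fe$nv))
  res <- picard_solve(fe, props, bcs, config, mass_coef, rhs_time = rhs_time,
                      w0 = w0, ops = ops)
  if (any(!is.finite(res$velocity))) stop("non-finite velocity: aborting")
  out <- flow_state(fe, t = state$t + dt, velocity = res$velocity,
                    pressure = res$pressure)
  attr(out, "iterations") <- res$iterations
  attr(out, "final_increment") <- res$final_increment
  attr(out, "ops") <- res$ops
  out
}

#' Solve the steady flow problem
#'
#' Picard iteration on the steady Navier-Stokes (or Stokes) system; used by
#' the verification scenarios (Poiseuille limits, manufactured solutions).
#'
#' @inheritParams step_flow
#' @return A converged [flow_state()] at `t = Inf`.
#' @export
solve_steady_flow <- function(fe, props, bcs, config = flow_config()) {
  res <- picard_solve(fe, props, bcs, config, mass_coef = 0)
  st <- flow_state(fe, t = Inf, velocity = res$velocity, pressure = res$pressure)
  attr(st, "iterations") <- res$iterations
  attr(st, "ops") <- res$ops
  st
}

#' L2 norm of the discrete velocity divergence
#'
#' In axisymmetric mode the divergence includes the `u1 / r` term.
#'
#' @param state A [flow_state()].
#' @param fe The matching [fe_space()].
#' @return Nonnegative scalar, m s-1 (times sqrt(area)).
#' @export
divergence_norm <- function(state, fe) {
  tot <- 0
  for (k in seq_len(fe$q$n)) {
    g1 <- p2_grad_at_qp(fe, state$velocity[, 1], k)
    g2 <- p2_grad_at_qp(fe, state$velocity[, 2], k)
    div <- g1$dz + g2$dx
    if (fe$axisym) {
      div <- div + as.vector(p2_field_at_qp(fe, state$velocity[, 2], k)) / fe$xq[[k]]
    }
    tot <- tot + sum(fe$wq[[k]] * div^2)
  }
  sqrt(tot)
}

#' Volumetric flux through a tagged boundary
#'
#' Planar mode: flux per unit depth, `m^2 s^-1`; axisymmetric mode: full
#' volumetric flux including the `2 pi r` weight, `m^3 s^-1`. Positive
#' outward.
#'
#' @param state A [flow_state()].
#' @param fe The matching [fe_space()].
#' @param tag Boundary tag (`INLET`, `OUTLET`, `WALL`, `RUPTURE`, `AXIS`).
#' @return Signed flux.
#' @export
boundary_flux <- function(state, fe, tag) {
  if (!tag %in% fe$bnd$tag) stop("unknown or absent boundary tag: ", tag)
  tr <- edge_trace(fe, tag)
  eq <- tr$eq
  tot <- 0
  for (k in seq_along(eq$t)) {
    wk <- eq$w[k] * tr$edges$len * tr$wfac[, k]
    un <- (state$velocity[tr$nodes[, 1], 1] * eq$N[k, 1] +
             state$velocity[tr$nodes[, 2], 1] * eq$N[k, 2] +
             state$velocity[tr$nodes[, 3], 1] * eq$N[k, 3]) * tr$edges$nz +
      (state$velocity[tr$nodes[, 1], 2] * eq$N[k, 1] +
         state$velocity[tr$nodes[, 2], 2] * eq$N[k, 2] +
         state$velocity[tr$nodes[, 3], 2] * eq$N[k, 3]) * tr$edges$nx
    tot <- tot + sum(un * wk)
  }
  if (fe$axisym) 2 * pi * tot else tot
}

# Relative mass-balance defect: |sum of open/inlet boundary fluxes| / |inlet|.
mass_balance <- function(state, fe) {
  tags <- intersect(c("INLET", "OUTLET", "RUPTURE"), unique(fe$bnd$tag))
  fl <- vapply(tags, function(tg) boundary_flux(state, fe, tg), numeric(1))
  inlet <- abs(fl[["INLET"]])
  list(fluxes = fl, defect = abs(sum(fl)) / max(inlet, 1e-300))
}
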