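#' Thermal boundary conditions
#'
#' All solid borders are thermally insulated (zero diffusive flux, the
#' natural condition); the inlet carries a Dirichlet temperature; open
#' boundaries (outlet, rupture) are advective outflows with zero diffusive
#' flux. A pinned outlet temperature is available for the steady-conduction
#' verification variant.
#'
#' @param T_inlet Inlet temperature, K (default 310: body temperature and
#'   the centre of the study's reported contour range).
#' @param T_outlet Optional Dirichlet outlet temperature, K (verification
#'   only; `NULL` keeps the advective outflow).
#' @return A list of class `"thermal_bcs"`.
#' @export
thermal_bcs <- function(T_inlet = 310, T_outlet = NULL) {
  stopifnot(T_inlet > 0)
  structure(list(T_inlet = T_inlet, T_outlet = T_outlet), class = "thermal_bcs")
}

#' Thermal solver configuration
#'
#' @param include_dissipation Include the viscous-dissipation source
#'   `mu * Phi` (default TRUE).
#' @param include_pressure_work Include an experimental pressure-work source
#'   `alpha_p * T * Dp/Dt` (default FALSE; the fluid is modelled
#'   incompressible, so this term is off by default).
#' @param alpha_p Thermal expansion coefficient used by the pressure-work
#'   term, K-1 (default 0).
#' @param dt Time step, s.
#' @param time_scheme `"bdf2"` or `"euler"`.
#' @return A list of class `"thermal_config"`.
#' @export
thermal_config <- function(include_dissipation = TRUE,
                           include_pressure_work = FALSE, alpha_p = 0,
                           dt = 0.01, time_scheme = c("bdf2", "euler")) {
  time_scheme <- match.arg(time_scheme)
  stopifnot(dt > 0)
  structure(list(include_dissipation = include_dissipation,
                 include_pressure_work = include_pressure_work,
                 alpha_p = alpha_p, dt = dt, time_scheme = time_scheme),
            class = "thermal_config")
}

#' Discrete thermal state
#'
#' @param fe An [fe_space()].
#' @param t Time, s.
#' @param temperature Length-`nv` P1 nodal temperature vector, K.
#' @return A list of class `"thermal_state"`.
#' @export
thermal_state <- function(fe, t = 0, temperature = NULL) {
  if (is.null(temperature)) temperature <- rep(310, fe$nv)
  stopifnot(length(temperature) == fe$nv)
  structure(list(t = t, temperature = temperature), class = "thermal_state")
}

# Velocity-gradient invariant Phi at quadrature point k (per element).
dissipation_phi_at_qp <- function(fe, velocity, k) {
  g1 <- p2_grad_at_qp(fe, velocity[, 1], k)  # axial component (u3)
  g2 <- p2_grad_at_qp(fe, velocity[, 2], k)  # transverse component (u1)
  phi <- 2 * g2$dx^2 + 2 * g1$dz^2 + (g2$dz + g1$dx)^2
  if (fe$axisym) {
    ur <- as.vector(p2_field_at_qp(fe, velocity[, 2], k))
    phi <- phi + 2 * (ur / fe$xq[[k]])^2
  }
  phi
}

#' Viscous-dissipation power density per element
#'
#' Element-averaged `mu * Phi` where `Phi` is the velocity-gradient
#' invariant: in planar mode
#' `2 (du1/dx)^2 + 2 (du3/dz)^2 + (du1/dz + du3/dx)^2`, with the additional
#' `2 (u1/r)^2` hoop term in axisymmetric mode. Nonnegative everywhere.
#'
#' @param state A [flow_state()].
#' @param props Effective properties ([effective_bundle()]).
#' @param fe The matching [fe_space()].
#' @return Vector of length `n_elements`, W m-3.
#' @export
viscous_dissipation_field <- function(state, props, fe) {
  num <- numeric(fe$m); den <- numeric(fe$m)
  for (k in seq_len(fe$q$n)) {
    phi <- dissipation_phi_at_qp(fe, state$velocity, k)
    num <- num + fe$wq[[k]] * phi
    den <- den + fe$wq[[k]]
  }
  props$mu * num / den
}

#' Total viscous-dissipation power
#'
#' Integral of `mu * Phi` over the domain: W per unit depth (planar) or W
#' (axisymmetric, including the `2 pi` factor).
#'
#' @inheritParams viscous_dissipation_field
#' @export
dissipation_power <- function(state, props, fe) {
  tot <- 0
  for (k in seq_len(fe$q$n)) {
    tot <- tot + sum(fe$wq[[k]] * dissipation_phi_at_qp(fe, state$velocity, k))
  }
  props$mu * tot * (if (fe$axisym) 2 * pi else 1)
}

# SUPG stabilisation parameter per element (Shakib/Tezduyar form).
supg_tau <- function(fe, props, wmean, dt = NULL) {
  p1 <- fe$mesh$nodes[fe$mesh$tri[, 1], , drop = FALSE]
  p2 <- fe$mesh$nodes[fe$mesh$tri[, 2], , drop = FALSE]
  p3 <- fe$mesh$nodes[fe$mesh$tri[, 3], , drop = FALSE]
  h <- sqrt(pmax(rowSums((p2 - p1)^2), rowSums((p3 - p2)^2),
                 rowSums((p1 - p3)^2)))
  alpha <- props$k / props$rho_cp
  term_t <- if (is.null(dt)) 0 else (2 / dt)^2
  1 / sqrt(term_t + (2 * wmean / h)^2 + 9 * (4 * alpha / h^2)^2)
}

# Assemble thermal matrices for a given advecting velocity field.
# Returns M (capacity incl. SUPG), K (conduction), C (advection incl. SUPG)
# and the SUPG test-augmentation data for sources.
thermal_operators <- function(fe, props, velocity, dt = NULL) {
  rc <- props$rho_cp; kk <- props$k
  W1 <- matrix(velocity[fe$tri6, 1], fe$m, 6)
  W2 <- matrix(velocity[fe$tri6, 2], fe$m, 6)
  wz <- lapply(seq_len(fe$q$n), function(k) as.vector(W1 %*% fe$Nq[k, ]))
  wx <- lapply(seq_len(fe$q$n), function(k) as.vector(W2 %*% fe$Nq[k, ]))
  wmean <- sqrt(Reduce(`+`, lapply(seq_len(fe$q$n), function(k)
    fe$q$w[k] * (wz[[k]]^2 + wx[[k]]^2))))
  tau <- supg_tau(fe, props, wmean, dt)
  # test function: psi_a + tau * (w . grad psi_a); grad psi constant/element
  test_a <- function(k, a) fe$q$lam[k, a] +
    tau * (wz[[k]] * fe$glam_z[, a] + wx[[k]] * fe$glam_x[, a])
  K <- asm_p1p1(fe, function(k, a, b)
    kk * fe$wq[[k]] * (fe$glam_z[, a] * fe$glam_z[, b] +
                         fe$glam_x[, a] * fe$glam_x[, b]))
  M <- asm_p1p1(fe, function(k, a, b)
    rc * fe$wq[[k]] * test_a(k, a) * fe$q$lam[k, b])
  C <- asm_p1p1(fe, function(k, a, b)
    rc * fe$wq[[k]] * test_a(k, a) *
      (wz[[k]] * fe$glam_z[, b] + wx[[k]] * fe$glam_x[, b]))
  list(M = M, K = K, C = C, test_a = test_a, tau = tau, wz = wz, wx = wx)
}

# Source vector: integral of src(qp) * (psi_a + tau w.grad psi_a).
thermal_source_vector <- function(fe, tops, src_at_qp) {
  out <- numeric(fe$nv)
  for (k in seq_len(fe$q$n)) {
    s <- src_at_qp(k)
    if (all(s == 0)) next
    for (a in 1:3) {
      out <- out + rowsum_into(fe$mesh$tri[, a],
                               fe$wq[[k]] * s * tops$test_a(k, a), fe$nv)
    }
  }
  out
}

rowsum_into <- function(idx, vals, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

thermal_dirichlet <- function(fe, bcs) {
  sel <- fe$bnd$tag == "INLET"
  idx <- unique(c(fe$bnd$n1[sel], fe$bnd$n2[sel]))
  val <- rep(bcs$T_inlet, length(idx))
  if (!is.null(bcs$T_outlet)) {
    sel <- fe$bnd$tag == "OUTLET"
    oidx <- setdiff(unique(c(fe$bnd$n1[sel], fe$bnd$n2[sel])), idx)
    idx <- c(idx, oidx); val <- c(val, rep(bcs$T_outlet, length(oidx)))
  }
  list(idx = idx, val = val)
}

#' Advance the temperature field by one time step
#'
#' Implicit (BDF2 with Euler startup) SUPG-stabilised advection-diffusion
#' step of the energy balance
#' `rho_cp (dT/dt + v . grad T) = k lap T + mu Phi`, on the flow solution at
#' the matching time. Walls, outlet and rupture carry the natural
#' zero-diffusive-flux condition; the inlet temperature is pinned.
#'
#' @param fe An [fe_space()].
#' @param props Effective properties.
#' @param config A [thermal_config()].
#' @param bcs A [thermal_bcs()].
#' @param tstate Current [thermal_state()].
#' @param fstate [flow_state()] at the new time level.
#' @param prev_tstate Previous thermal state (`NULL`: Euler startup).
#' @param prev_pressure Previous pressure (for the optional pressure-work
#'   source).
#' @return The new `thermal_state`.
#' @export
step_thermal <- function(fe, props, config, bcs, tstate, fstate,
                         prev_tstate = NULL, prev_pressure = NULL) {
  dt <- config$dt
  tops <- thermal_operators(fe, props, fstate$velocity, dt = dt)
  use_bdf2 <- config$time_scheme == "bdf2" && !is.null(prev_tstate)
  if (use_bdf2) {
    lhs_coef <- 1.5 / dt
    hist <- (2 * tstate$temperature - 0.5 * prev_tstate$temperature) / dt
  } else {
    lhs_coef <- 1 / dt
    hist <- tstate$temperature / dt
  }
  A <- lhs_coef * tops$M + tops$C + tops$K
  b <- as.vector(tops$M %*% hist)
  if (config$include_dissipation) {
    b <- b + thermal_source_vector(fe, tops, function(k)
      props$mu * dissipation_phi_at_qp(fe, fstate$velocity, k))
  }
  if (config$include_pressure_work && config$alpha_p != 0 &&
      !is.null(prev_pressure)) {
    gp <- p1_grad(fe, fstate$pressure)
    dpdt <- (fstate$pressure - prev_pressure) / dt
    b <- b + thermal_source_vector(fe, tops, function(k) {
      Tq <- p1_field_at_qp(fe, tstate$temperature, k)
      config$alpha_p * Tq *
        (p1_field_at_qp(fe, dpdt, k) + tops$wz[[k]] * gp$dz + tops$wx[[k]] * gp$dx)
    })
  }
  dir <- thermal_dirichlet(fe, bcs)
  Tn <- solve_constrained(A, b, dir)
  if (any(!is.finite(Tn))) stop("non-finite temperature: aborting")
  # variationally consistent reactions at Dirichlet nodes: the net discrete
  # conductive inflow through the pinned boundary (energy-audit diagnostic)
  reactions <- as.vector(A %*% Tn - b)[dir$idx]
  # advective CFL advisory
  courant <- max(abs(fstate$velocity)) * dt /
    min(sqrt(4 * fe$area / sqrt(3)))
  if (is.finite(courant) && courant > 5) {
    message(sprintf("advective Courant number %.1f > 5 at t = %.3f s",
                    courant, fstate$t))
  }
  out <- thermal_state(fe, t = tstate$t + dt, temperature = Tn)
  attr(out, "dirichlet_reaction") <- sum(reactions)
  out
}

#' Solve the steady conduction/advection-diffusion problem
#'
#' Steady counterpart of [step_thermal()] (no capacity term); used by the
#' pinned-temperature conduction verification variant.
#'
#' @inheritParams step_thermal
#' @param fstate Flow state supplying the advecting velocity (a zero field
#'   gives pure conduction).
#' @return A `thermal_state` at `t = Inf`.
#' @export
solve_steady_thermal <- function(fe, props, config, bcs, fstate) {
  tops <- thermal_operators(fe, props, fstate$velocity, dt = NULL)
  A <- tops$C + tops$K
  b <- numeric(fe$nv)
  if (config$include_dissipation) {
    b <- b + thermal_source_vector(fe, tops, function(k)
      props$mu * dissipation_phi_at_qp(fe, fstate$velocity, k))
  }
  dir <- thermal_dirichlet(fe, bcs)
  if (is.null(bcs$T_outlet) && all(fstate$velocity == 0)) {
    stop("steady pure conduction with only one pinned boundary is singular; ",
         "set T_outlet")
  }
  thermal_state(fe, t = Inf, temperature = solve_constrained(A, b, dir))
}

#' Total thermal energy content
#'
#' `integral rho_cp T dOmega`: J per unit depth (planar) or J
#' (axisymmetric, including `2 pi`).
#'
#' @param tstate A [thermal_state()].
#' @param props Effective properties.
#' @param fe The matching [fe_space()].
#' @export
thermal_energy <- function(tstate, props, fe) {
  tot <- 0
  for (k in seq_len(fe$q$n)) {
    tot <- tot + sum(fe$wq[[k]] * p1_field_at_qp(fe, tstate$temperature, k))
  }
  props$rho_cp * tot * (if (fe$axisym) 2 * pi else 1)
}

#' Advective heat flux through a tagged boundary
#'
#' `integral rho_cp T (v . n) ds`, positive outward: W per unit depth
#' (planar) or W (axisymmetric).
#'
#' @param tstate,fstate Thermal and flow states at the same time.
#' @param props Effective properties.
#' @param fe The matching [fe_space()].
#' @param tag Boundary tag.
#' @export
advective_heat_flux <- function(tstate, fstate, props, fe, tag) {
  if (!tag %in% fe$bnd$tag) stop("unknown or absent boundary tag: ", tag)
  tr <- edge_trace(fe, tag)
  eq <- tr$eq
  tot <- 0
  Tn <- tstate$temperature
  for (k in seq_along(eq$t)) {
    wk <- eq$w[k] * tr$edges$len * tr$wfac[, k]
    un <- (fstate$velocity[tr$nodes[, 1], 1] * eq$N[k, 1] +
             fstate$velocity[tr$nodes[, 2], 1] * eq$N[k, 2] +
             fstate$velocity[tr$nodes[, 3], 1] * eq$N[k, 3]) * tr$edges$nz +
      (fstate$velocity[tr$nodes[, 1], 2] * eq$N[k, 1] +
         fstate$velocity[tr$nodes[, 2], 2] * eq$N[k, 2] +
         fstate$velocity[tr$nodes[, 3], 2] * eq$N[k, 3]) * tr$edges$nx
    # P1 temperature trace (linear along the edge)
    Tq <- Tn[tr$edges$n1] * (1 - eq$t[k]) + Tn[tr$edges$n2] * eq$t[k]
    tot <- tot + sum(un * Tq * wk)
  }
  props$rho_cp * tot * (if (fe$axisym) 2 * pi else 1)
}
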