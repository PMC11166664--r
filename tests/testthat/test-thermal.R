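test_that("viscous dissipation vanishes for uniform flow and matches pure shear", {
  fe <- fe_space(channel_mesh(L = 1, H = 1, h = 0.2))
  props <- blood_props()
  st <- flow_state(fe)
  st$velocity[, 1] <- 0.3
  expect_lt(max(viscous_dissipation_field(st, props, fe)), 1e-18)
  gamma <- 7
  st$velocity[, 1] <- gamma * fe$p2xy[, 2]   # u3 = gamma * x
  st$velocity[, 2] <- 0
  phi <- viscous_dissipation_field(st, props, fe)
  expect_equal(unname(range(phi)), rep(props$mu * gamma^2, 2), tolerance = 1e-12)
  expect_true(all(phi >= 0))
})

test_that("Poiseuille dissipation balances pressure work dp * Q", {
  H <- 0.09; U <- 0.08; L <- 0.7
  fe <- fe_space(channel_mesh(h = 0.012))
  props <- blood_props()
  st <- flow_state(fe)
  # exact plane-Poiseuille interpolant
  x <- fe$p2xy[, 2]
  st$velocity[, 1] <- 6 * U * (x / H) * (1 - x / H)
  P <- dissipation_power(st, props, fe)
  dp <- 12 * props$mu * U / H^2 * L
  Q <- U * H
  expect_equal(P, dp * Q, tolerance = 0.02)
})

test_that("uniform temperature is invariant under insulated advection", {
  msh <- rupture_mesh_coarse()
  fe <- fe_space(msh)
  props <- hybrid_props()
  # an arbitrary incompressible-ish velocity field advects a uniform
  # temperature without changing it (all boundaries natural except the
  # inlet, which carries the same value)
  fstate <- flow_state(fe)
  fstate$velocity[, 1] <- 0.08
  bcs <- thermal_bcs(T_inlet = 310)
  cfg <- thermal_config(include_dissipation = FALSE, dt = 0.01)
  ts <- thermal_state(fe, temperature = rep(310, fe$nv))
  prev <- NULL
  for (i in 1:20) {
    new <- step_thermal(fe, props, cfg, bcs, ts, fstate, prev)
    prev <- ts; ts <- new
  }
  expect_lt(max(abs(ts$temperature - 310)), 1e-9)
})

test_that("insulated diffusion conserves energy and obeys the maximum principle", {
  fe <- fe_space(channel_mesh(L = 0.2, H = 0.09, h = 0.015))
  fe$bnd$tag[] <- "WALL"        # fully closed, fully insulated
  props <- blood_props()
  # conductive test fluid: the strip homogenises within the simulated window
  props$k <- 500; props$alpha <- props$k / props$rho_cp
  fstate <- flow_state(fe)      # no flow
  cfg <- thermal_config(include_dissipation = FALSE, dt = 50)
  bcs <- thermal_bcs(T_inlet = 310)
  T0 <- ifelse(fe$mesh$nodes[, 1] < 0.1, 305, 315)   # two-temperature strip
  ts <- thermal_state(fe, temperature = T0)
  E0 <- thermal_energy(ts, props, fe)
  prev <- NULL
  mn <- min(T0); mx <- max(T0)
  for (i in 1:40) {
    new <- step_thermal(fe, props, cfg, bcs, ts, fstate, prev)
    prev <- ts; ts <- new
    expect_gte(min(ts$temperature), mn - 1e-6)
    expect_lte(max(ts$temperature), mx + 1e-6)
  }
  expect_equal(thermal_energy(ts, props, fe), E0, tolerance = 1e-8)
  # long-time limit: uniform at the energy-weighted mean
  expect_lt(diff(range(ts$temperature)), 0.5)
})

test_that("with dissipation on, closed insulated energy is nondecreasing", {
  fe <- fe_space(channel_mesh(L = 0.2, H = 0.09, h = 0.02))
  fe$bnd$tag[] <- "WALL"
  props <- blood_props()
  props$mu <- 0.5    # strong shear heating makes the growth visible
  fstate <- flow_state(fe)
  fstate$velocity[, 1] <- 20 * fe$p2xy[, 2]   # frozen shear field
  cfg <- thermal_config(include_dissipation = TRUE, dt = 0.5)
  bcs <- thermal_bcs(T_inlet = 310)
  ts <- thermal_state(fe, temperature = rep(310, fe$nv))
  E <- thermal_energy(ts, props, fe)
  prev <- NULL
  for (i in 1:10) {
    new <- step_thermal(fe, props, cfg, bcs, ts, fstate, prev)
    prev <- ts; ts <- new
    E1 <- thermal_energy(ts, props, fe)
    expect_gte(E1, E)
    E <- E1
  }
})

test_that("steady conduction with pinned ends is exactly linear", {
  fe <- fe_space(channel_mesh(L = 0.5, H = 0.09, h = 0.02))
  props <- hybrid_props()
  ts <- solve_steady_thermal(fe, props,
                             thermal_config(include_dissipation = FALSE),
                             thermal_bcs(T_inlet = 310, T_outlet = 320),
                             flow_state(fe))
  exact <- 310 + 10 * fe$mesh$nodes[, 1] / 0.5
  expect_lt(max(abs(ts$temperature - exact)) / 10, 1e-6)
})

test_that("open-domain energy budget closes: dE/dt = advection in - out + dissipation + inlet conduction", {
  # a high-conductivity test fluid keeps the Peclet number moderate so the
  # advected front is resolved; the inlet Dirichlet boundary also conducts,
  # measured by the variationally consistent reaction
  fe <- fe_space(channel_mesh(L = 0.2, H = 0.09, h = 0.01))
  props <- blood_props()
  props$k <- 500; props$alpha <- props$k / props$rho_cp
  U <- 0.01
  fstate <- flow_state(fe)
  x <- fe$p2xy[, 2]
  fstate$velocity[, 1] <- 6 * U * (x / 0.09) * (1 - x / 0.09)
  bcs <- thermal_bcs(T_inlet = 315)      # hot inflow into a 310 K domain
  dt <- 0.05
  cfg <- thermal_config(include_dissipation = TRUE, dt = dt,
                        time_scheme = "euler")
  ts <- thermal_state(fe, temperature = rep(310, fe$nv))
  E <- thermal_energy(ts, props, fe)
  rhs_cum <- 0
  for (i in 1:40) {
    new <- step_thermal(fe, props, cfg, bcs, ts, fstate)
    adv <- advective_heat_flux(new, fstate, props, fe, "INLET") +
      advective_heat_flux(new, fstate, props, fe, "OUTLET")
    rhs_cum <- rhs_cum + dt * (-adv + dissipation_power(fstate, props, fe) +
                                 attr(new, "dirichlet_reaction"))
    ts <- new
  }
  E1 <- thermal_energy(ts, props, fe)
  expect_equal(E1 - E, rhs_cum, tolerance = 0.01)
  expect_gt(E1, E)   # hot inflow heats the domain
})

test_that("dissipation heating is negligible at study scales", {
  # the strongest shear in the vessel is of order 6 U / H; over the full
  # simulated window it heats the blood by far less than the 0.01 K
  # contour-band width
  props <- hybrid_props()
  U <- 0.08; H <- 0.09; t_end <- 2.4
  shear <- 6 * U / H
  dT <- props$mu * shear^2 * t_end / props$rho_cp
  expect_lt(dT, 1e-6)
})
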