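# Flow-solver unit and property tests. Heavier closed-form verification
# (full-size Poiseuille limits, conservation over the whole transient) lives
# in test-acceptance.R; these use small meshes.

test_that("rest state is a fixed point of steady and transient solves", {
  fe <- fe_space(channel_mesh(h = 0.03))
  props <- blood_props()
  # at zero gauge pressure the rest state is reproduced to machine zero
  bcs0 <- flow_bcs(v0 = 0, p_out = 0, p_rupture = 0)
  st <- solve_steady_flow(fe, props, bcs0)
  expect_lt(max(abs(st$velocity)), 1e-13)
  # at the 13 kPa absolute level the velocity noise floor is set by the
  # pressure scale times round-off
  bcs <- flow_bcs(v0 = 0, p_out = 13000, p_rupture = 13000)
  st <- solve_steady_flow(fe, props, bcs)
  expect_lt(max(abs(st$velocity)), 1e-10)
  expect_equal(unname(range(st$pressure)), c(13000, 13000), tolerance = 1e-9)
  st0 <- flow_state(fe); st0$pressure[] <- 13000
  st1 <- step_flow(fe, props, bcs, flow_config(dt = 0.01), st0)
  expect_lt(max(abs(st1$velocity)), 1e-10)
})

test_that("inlet profiles: plug carries v0 at every inlet node, parabolic peaks at 1.5 v0", {
  fe <- fe_space(channel_mesh(h = 0.03))
  props <- blood_props()
  st <- solve_steady_flow(fe, props, flow_bcs(v0 = 0.05, inlet_profile = "plug"))
  dir <- hemofem:::dirichlet_velocity(fe, flow_bcs(v0 = 0.05))
  inlet_nodes <- which(abs(fe$p2xy[, 1]) < 1e-12)
  expect_true(all(abs(st$velocity[inlet_nodes, 1] - 0.05) < 1e-12))
  stp <- solve_steady_flow(fe, props,
                           flow_bcs(v0 = 0.05, inlet_profile = "parabolic"))
  expect_equal(max(stp$velocity[inlet_nodes, 1]), 1.5 * 0.05, tolerance = 1e-6)
})

test_that("zero viscosity is rejected and untagged boundaries are a hard error", {
  fe <- fe_space(channel_mesh(h = 0.05))
  props <- blood_props(); props$mu <- 0
  expect_error(assemble_flow_system(fe, props), "viscosity")
  fe_bad <- fe
  fe_bad$bnd$tag[1] <- "MYSTERY"
  sys <- assemble_flow_system(fe_bad, blood_props())
  expect_error(apply_flow_bcs(sys, flow_bcs()), "MYSTERY")
})

test_that("closed cavity detects the pressure nullspace and pins one dof", {
  geo <- vessel_geometry(length = 0.1, height = 0.1, has_sac = FALSE,
                         has_orifice = FALSE)
  msh <- generate_mesh(build_geometry(geo), mesh_sizing(h_max = 0.025, h_min = 0.025))
  msh$boundary$tag[] <- "WALL"
  fe <- fe_space(msh)
  sys <- assemble_flow_system(fe, blood_props())
  con <- apply_flow_bcs(sys, flow_bcs(v0 = 0))
  expect_true(con$pinned_pressure)
  st <- solve_steady_flow(fe, blood_props(), flow_bcs(v0 = 0))
  expect_lt(max(abs(st$velocity)), 1e-12)
  expect_lt(diff(range(st$pressure)), 1e-9)
})

test_that("divergence norm matches closed forms for interpolated fields", {
  fe <- fe_space(channel_mesh(L = 1, H = 1, h = 0.2))
  st <- flow_state(fe)
  st$velocity[, 1] <- 1; st$velocity[, 2] <- 2      # uniform
  expect_lt(divergence_norm(st, fe), 1e-12)
  st$velocity[, 1] <- fe$p2xy[, 1]                  # v = (z, -x)
  st$velocity[, 2] <- -fe$p2xy[, 2]
  expect_lt(divergence_norm(st, fe), 1e-12)
  st$velocity[, 2] <- fe$p2xy[, 2]                  # v = (z, x): div = 2
  expect_equal(divergence_norm(st, fe), 2 * sqrt(1), tolerance = 1e-12)
})

test_that("boundary flux reproduces plug inflow and uniform throughflow", {
  fe <- fe_space(channel_mesh(h = 0.03))
  st <- flow_state(fe)
  st$velocity[, 1] <- 0.07
  expect_equal(boundary_flux(st, fe, "INLET"), -0.07 * 0.09, tolerance = 1e-12)
  expect_equal(boundary_flux(st, fe, "OUTLET"), 0.07 * 0.09, tolerance = 1e-12)
  expect_equal(boundary_flux(st, fe, "INLET") + boundary_flux(st, fe, "OUTLET"),
               0, tolerance = 1e-12)
  expect_error(boundary_flux(st, fe, "NOPE"), "unknown")
})

test_that("Stokes limit matches the full solver as v0 -> 0", {
  fe <- fe_space(channel_mesh(h = 0.03))
  props <- blood_props()
  bcs <- flow_bcs(v0 = 1e-6, inlet_profile = "parabolic")
  full <- solve_steady_flow(fe, props, bcs, flow_config())
  stokes <- solve_steady_flow(fe, props, bcs,
                              flow_config(include_convection = FALSE))
  rel <- max(abs(full$velocity - stokes$velocity)) / max(abs(full$velocity))
  expect_lt(rel, 0.01)   # convection is negligible at Re << 1
})

test_that("Stokes pressure drop scales as the closed form under mu and v0 scaling", {
  fe <- fe_space(channel_mesh(L = 0.3, h = 0.02))
  dpL <- function(mu_scale, v_scale) {
    props <- blood_props(); props$mu <- props$mu * mu_scale
    bcs <- flow_bcs(v0 = 0.001 * v_scale, inlet_profile = "parabolic")
    st <- solve_steady_flow(fe, props, bcs, flow_config())
    cl <- sample_line(st, fe, c(0.05, 0.045), c(0.25, 0.045), n = 51,
                      field = "pressure")
    -stats::coef(stats::lm(cl$value ~ cl$z))[[2]]
  }
  base <- dpL(1, 1)
  scaled <- dpL(10, 1 / 10)
  expect_equal(scaled, base, tolerance = 5e-3)
  expect_equal(dpL(10, 1), 10 * base, tolerance = 5e-3)
})

test_that("pressure drop scales with the hybrid viscosity ratio", {
  fe <- fe_space(channel_mesh(L = 0.3, h = 0.02))
  run <- function(props) {
    st <- solve_steady_flow(fe, props,
                            flow_bcs(v0 = 0.02, inlet_profile = "parabolic"))
    cl <- sample_line(st, fe, c(0.05, 0.045), c(0.25, 0.045), n = 51,
                      field = "pressure")
    -stats::coef(stats::lm(cl$value ~ cl$z))[[2]]
  }
  base <- run(blood_props())
  hyb <- hybrid_props(0.02, 0.02)
  ratio <- run(hyb) / base
  expect_equal(ratio, hyb$mu / blood_props()$mu, tolerance = 5e-3)
})

test_that("BDF2 shows second-order self-convergence on a smooth ramp", {
  fe <- fe_space(channel_mesh(L = 0.2, H = 0.09, h = 0.03))
  props <- blood_props()
  run_dt <- function(dt) {
    cfg <- flow_config(dt = dt, t_end = 0.2)
    # smoothly ramped inflow keeps the solution regular in time, so the
    # temporal error is observable without the impulsive-start layer
    st <- flow_state(fe); st$pressure[] <- 13000
    prev <- NULL; ops <- NULL
    for (i in seq_len(round(0.2 / dt))) {
      tnew <- i * dt
      bcs <- flow_bcs(v0 = 0.02 * sin(pi * tnew / 0.4)^2,
                      inlet_profile = "parabolic")
      new <- step_flow(fe, props, bcs, cfg, st, prev, ops)
      ops <- attr(new, "ops"); prev <- st; st <- new
    }
    st$velocity
  }
  ref <- run_dt(0.0025)
  e1 <- sqrt(sum((run_dt(0.02) - ref)^2))
  e2 <- sqrt(sum((run_dt(0.01) - ref)^2))
  expect_gt(e1 / e2, 3)   # ~4x drop per halving for second order
  expect_lt(e1 / e2, 6)
})
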