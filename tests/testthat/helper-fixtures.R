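# Shared fixtures: small meshes and property bundles built in code.

blood_props <- function() {
  mats <- material_table()
  props_from_names(load = loading(0, 0), table = mats)
}

hybrid_props <- function(phi1 = 0.01, phi2 = 0.01) {
  mats <- material_table()
  props_from_names(load = loading(phi1, phi2), table = mats)
}

channel_mesh <- function(L = 0.7, H = 0.09, h = 0.015, mode = "planar") {
  geo <- vessel_geometry(length = L, height = H, mode = mode,
                         has_sac = FALSE, has_orifice = FALSE)
  generate_mesh(build_geometry(geo), mesh_sizing(h_max = h, h_min = h))
}

unit_square_fe <- function(n = 8) {
  msh <- channel_mesh(L = 1, H = 1, h = 1 / n)
  fe_space(msh)
}

# Coarse-but-resolved rupture mesh: default orifice refinement, coarser far
# field (keeps transient tests fast).
rupture_mesh_coarse <- function() {
  geo <- vessel_geometry()
  generate_mesh(build_geometry(geo), mesh_sizing(h_max = 0.025, h_min = 0.0032))
}

# Direct-arithmetic mixture-law oracle, coded independently of the package
# implementation (plain formula transcription).
oracle_mixture <- function(phi1, phi2, tab) {
  f <- function(nm, col) tab[[col]][tab$name == nm]
  rho <- (1 - phi2) * ((1 - phi1) * f("blood", "rho") + phi1 * f("gold", "rho")) +
    phi2 * f("silver", "rho")
  rc <- (1 - phi2) * ((1 - phi1) * f("blood", "rho") * f("blood", "cp") +
                        phi1 * f("gold", "rho") * f("gold", "cp")) +
    phi2 * f("silver", "rho") * f("silver", "cp")
  mu <- f("blood", "mu") / ((1 - phi1)^2.5 * (1 - phi2)^2.5)
  mx <- function(kf, ks, phi) {
    kf * (ks + 2 * kf - 2 * phi * (kf - ks)) / (ks + 2 * kf + phi * (kf - ks))
  }
  knf <- mx(f("blood", "k"), f("gold", "k"), phi1)
  k <- mx(knf, f("silver", "k"), phi2)
  list(rho = rho, rho_cp = rc, mu = mu, k = k)
}
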