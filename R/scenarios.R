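# Scenario configuration, the transient driver, the builtin registry and
# run reports.

default_config <- function() {
  list(
    kind = "transient",
    geometry = list(length = 0.7, height = 0.09, mode = "planar",
                    sac_center_z = 0.30, sac_radius = 0.025,
                    neck_width = 0.035, orifice_width = 0.008,
                    has_sac = TRUE, has_orifice = TRUE),
    mesh = list(h_max = 0.0169, h_min = 0.0032, growth_rate = 1.13,
                narrow_resolution = 0.8, curvature_factor = 0.06, seed = 1L),
    materials = list(base = "blood", s1 = "gold", s2 = "silver",
                     phi1 = 0.01, phi2 = 0.01, silver_cp = "printed",
                     table = NULL),
    flow = list(v0 = 0.08, p_out = 13000, p_rupture = 12990,
                inlet_profile = "plug", backflow_beta = 0.5, steady = FALSE),
    solver = list(dt = 0.01, t_end = 2.4, time_scheme = "bdf2",
                  picard_tol = 1e-8, picard_max = 60L,
                  include_convection = TRUE, relax = 1),
    thermal = list(enabled = TRUE, T_inlet = 310, T_outlet = NULL,
                   include_dissipation = TRUE, include_pressure_work = FALSE,
                   alpha_p = 0),
    output = list(times = c(0, 0.4, 0.8, 1.2, 2.4), dir = NULL,
                  keep_fields = TRUE),
    checks = character(0)
  )
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    key <- if (path == "") nm else paste0(path, "$", nm)
    if (!nm %in% names(base)) stop("unknown configuration key: ", key)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(override[[nm]])) stop("key ", key, " must be a section")
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], key)
    } else if (is.null(override[[nm]])) {
      base[nm] <- list(NULL)   # assigning NULL directly would drop the key
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  geo <- do.call(vessel_geometry, cfg$geometry)   # runs geometry invariants
  mesh_sizing(cfg$mesh$h_max, cfg$mesh$h_min, cfg$mesh$growth_rate,
              cfg$mesh$narrow_resolution, cfg$mesh$curvature_factor,
              cfg$mesh$seed)
  loading(cfg$materials$phi1, cfg$materials$phi2)
  flow_bcs(cfg$flow$v0, cfg$flow$p_out, cfg$flow$p_rupture,
           cfg$flow$inlet_profile, cfg$flow$backflow_beta)
  if (!cfg$flow$steady) {
    flow_config(cfg$solver$dt, cfg$solver$t_end, cfg$solver$time_scheme,
                cfg$solver$picard_tol, cfg$solver$picard_max,
                cfg$solver$include_convection, cfg$solver$relax)
    if (any(cfg$output$times > cfg$solver$t_end + 1e-12)) {
      stop("output times must not exceed solver$t_end")
    }
  }
  if (!cfg$kind %in% c("transient", "steady_flow", "steady_thermal", "mms")) {
    stop("unknown scenario kind: ", cfg$kind)
  }
  invisible(cfg)
}

#' Load a scenario configuration
#'
#' Reads a YAML configuration file, overlays it on the defaults (the
#' `paper_rupture` scenario) or on a named builtin selected by its
#' `scenario:` key, validates all cross-field invariants, and returns the
#' fully resolved configuration. Unknown keys are a hard error.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Optional named list applied after the file.
#' @return The resolved configuration list (class `"scenario_config"`).
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such configuration file: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  base_name <- user$scenario %||% "paper_rupture"
  user$scenario <- NULL
  reg <- builtin_scenarios()
  if (!base_name %in% names(reg)) {
    stop("unknown scenario '", base_name, "'; builtins: ",
         paste(names(reg), collapse = ", "))
  }
  cfg <- reg[[base_name]]
  cfg <- merge_config(cfg, user)
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  cfg$checks <- as.character(unlist(cfg$checks))
  cfg$output$times <- as.numeric(unlist(cfg$output$times))
  validate_config(cfg)
  cfg$scenario <- base_name
  class(cfg) <- "scenario_config"
  cfg
}

#' Serialise a configuration to YAML
#'
#' @param cfg A `scenario_config` (or plain list).
#' @param path Optional file to write; otherwise the YAML string is
#'   returned.
#' @export
dump_config <- function(cfg, path = NULL) {
  x <- unclass(cfg)
  txt <- yaml::as.yaml(x)
  if (!is.null(path)) {
    writeLines(txt, path)
    invisible(path)
  } else {
    txt
  }
}

#' Builtin scenario registry
#'
#' Named, fully resolved configurations: the study analogue
#' (`paper_rupture`), its particle-free counterpart differing only in the
#' volume fractions (`paper_rupture_no_particles`), and the verification
#' scenarios, each of which exercises one documented closed form.
#'
#' @return Named list of configuration lists.
#' @export
builtin_scenarios <- function() {
  base <- default_config()
  reg <- list()
  reg$paper_rupture <- base
  np <- base
  np$materials$phi1 <- 0; np$materials$phi2 <- 0
  reg$paper_rupture_no_particles <- np
  pc <- default_config()
  pc$kind <- "steady_flow"
  pc$geometry$has_sac <- FALSE; pc$geometry$has_orifice <- FALSE
  pc$mesh$h_max <- 0.012; pc$mesh$h_min <- 0.012
  pc$materials$phi1 <- 0; pc$materials$phi2 <- 0
  pc$flow$inlet_profile <- "parabolic"; pc$flow$steady <- TRUE
  pc$thermal$enabled <- FALSE
  pc$output$times <- numeric(0)
  pc$checks <- "poiseuille_channel"
  reg$poiseuille_channel <- pc
  tube <- pc
  tube$geometry$length <- 0.35; tube$geometry$height <- 0.045
  tube$geometry$mode <- "axisymmetric"
  tube$mesh$h_max <- 0.006; tube$mesh$h_min <- 0.006
  tube$checks <- "poiseuille_tube"
  reg$poiseuille_tube_axisym <- tube
  ut <- default_config()
  ut$mesh$h_max <- 0.025   # far field coarsened; orifice kept at h_min
  ut$thermal$include_dissipation <- FALSE
  ut$checks <- "uniform_thermal"
  reg$uniform_thermal <- ut
  cs <- default_config()
  cs$kind <- "steady_thermal"
  cs$geometry$has_sac <- FALSE; cs$geometry$has_orifice <- FALSE
  cs$geometry$length <- 0.5
  cs$mesh$h_max <- 0.02; cs$mesh$h_min <- 0.02
  cs$flow$v0 <- 0
  cs$thermal$T_outlet <- 320
  cs$thermal$include_dissipation <- FALSE
  cs$output$times <- numeric(0)
  cs$checks <- "conduction_strip"
  reg$conduction_strip <- cs
  mm <- default_config()
  mm$kind <- "mms"
  mm$checks <- "mms_convergence"
  reg$mms_convergence <- mm
  reg
}

#' March the coupled flow/thermal problem in time
#'
#' Transient driver: starts from rest (`v = 0`, `p = p_out`, `T = T_inlet`),
#' advances with BDF2 (implicit-Euler startup) at fixed `dt`, logs per-step
#' Picard iterations, increments, the divergence norm and the boundary
#' mass-balance defect, and stores snapshots at the requested output times.
#'
#' @param fe An [fe_space()].
#' @param props Effective properties.
#' @param bcs A [flow_bcs()].
#' @param config A [flow_config()].
#' @param thermal `NULL`, or
#'   `list(bcs = thermal_bcs(), config = thermal_config())`.
#' @param output_times Times at which to store snapshots.
#' @param verbose Print per-step log lines.
#' @return A list of class `"run_trajectory"`: `snapshots` (each
#'   `list(t, flow, thermal)`), `log` (tibble), `fe`, `props`, `dt`.
#' @export
simulate_transient <- function(fe, props, bcs, config, thermal = NULL,
                               output_times = NULL, verbose = FALSE) {
  dt <- config$dt
  nstep <- round(config$t_end / dt)
  fstate <- flow_state(fe)
  fstate$pressure[] <- bcs$p_out
  tstate <- NULL; prev_t <- NULL
  if (!is.null(thermal)) {
    tstate <- thermal_state(fe, t = 0,
                            temperature = rep(thermal$bcs$T_inlet, fe$nv))
  }
  snaps <- list(); logs <- list()
  want <- function(tt) {
    !is.null(output_times) && any(abs(output_times - tt) <= dt / 2 + 1e-12)
  }
  if (want(0) || is.null(output_times)) {
    snaps[[length(snaps) + 1L]] <- list(t = 0, flow = fstate, thermal = tstate)
  }
  prev_f <- NULL; ops <- NULL
  for (i in seq_len(nstep)) {
    newf <- step_flow(fe, props, bcs, config, fstate, prev_f, ops)
    ops <- attr(newf, "ops")
    prev_f <- fstate; fstate <- newf
    if (!is.null(thermal)) {
      newt <- step_thermal(fe, props, thermal$config, thermal$bcs,
                           tstate, fstate, prev_t)
      prev_t <- tstate; tstate <- newt
    }
    mb <- mass_balance(fstate, fe)
    logs[[i]] <- tibble::tibble(
      step = i, t = fstate$t,
      picard_iterations = attr(newf, "iterations"),
      picard_increment = attr(newf, "final_increment"),
      div_norm = divergence_norm(fstate, fe),
      mass_defect = mb$defect,
      flux_inlet = mb$fluxes[["INLET"]],
      flux_outlet = mb$fluxes["OUTLET"] %||% NA_real_,
      flux_rupture = if ("RUPTURE" %in% names(mb$fluxes))
        mb$fluxes[["RUPTURE"]] else NA_real_)
    if (verbose) {
      cat(sprintf("t=%.3f picard=%d incr=%.2e div=%.2e massdef=%.2e\n",
                  fstate$t, attr(newf, "iterations"),
                  attr(newf, "final_increment"),
                  logs[[i]]$div_norm, mb$defect))
    }
    if (want(fstate$t)) {
      snaps[[length(snaps) + 1L]] <- list(t = fstate$t, flow = fstate,
                                          thermal = tstate)
    }
  }
  structure(list(snapshots = snaps, log = do.call(rbind, logs), fe = fe,
                 props = props, dt = dt), class = "run_trajectory")
}

scenario_checks <- function(name, ctx) {
  tol_row <- function(check, measured, target, tol) {
    tibble::tibble(check = check, measured = measured, target = target,
                   tol = tol, pass = abs(measured - target) <= tol * abs(target))
  }
  switch(name,
    poiseuille_channel = {
      fe <- ctx$fe; st <- ctx$steady_flow
      U <- ctx$cfg$flow$v0; H <- ctx$cfg$geometry$height
      L <- ctx$cfg$geometry$length
      mid <- sample_line(st, fe, c(L / 2, 0), c(L / 2, H), n = 201)
      cl <- sample_line(st, fe, c(0.15 * L, H / 2), c(0.8 * L, H / 2),
                        n = 101, field = "pressure")
      dpL <- -stats::coef(stats::lm(cl$value ~ cl$z))[[2]]
      rbind(tol_row("u_max / U (plane Poiseuille)", max(mid$value) / U, 1.5, 0.01),
            tol_row("dp/L (plane Poiseuille)", dpL,
                    12 * ctx$props$mu * U / H^2, 0.02))
    },
    poiseuille_tube = {
      fe <- ctx$fe; st <- ctx$steady_flow
      U <- ctx$cfg$flow$v0; R <- ctx$cfg$geometry$height
      L <- ctx$cfg$geometry$length
      mid <- sample_line(st, fe, c(L / 2, 0), c(L / 2, R), n = 201)
      cl <- sample_line(st, fe, c(0.15 * L, 0), c(0.8 * L, 0),
                        n = 101, field = "pressure")
      dpL <- -stats::coef(stats::lm(cl$value ~ cl$z))[[2]]
      rbind(tol_row("u_max / U (Hagen-Poiseuille)", max(mid$value) / U, 2, 0.01),
            tol_row("dp/L (Hagen-Poiseuille)", dpL,
                    8 * ctx$props$mu * U / R^2, 0.02))
    },
    uniform_thermal = {
      drift <- max(vapply(ctx$trajectory$snapshots, function(sn)
        max(abs(sn$thermal$temperature - ctx$cfg$thermal$T_inlet)), numeric(1)))
      tibble::tibble(check = "max |T - T_inlet| (insulated uniform run)",
                     measured = drift, target = 0, tol = 1e-9,
                     pass = drift <= 1e-9)
    },
    conduction_strip = {
      fe <- ctx$fe; ts <- ctx$steady_thermal
      L <- ctx$cfg$geometry$length
      T0 <- ctx$cfg$thermal$T_inlet; T1 <- ctx$cfg$thermal$T_outlet
      exact <- T0 + (T1 - T0) * fe$mesh$nodes[, 1] / L
      err <- max(abs(ts$temperature - exact)) / abs(T1 - T0)
      tibble::tibble(check = "linear steady-conduction profile",
                     measured = err, target = 0, tol = 1e-6, pass = err <= 1e-6)
    },
    mms_convergence = {
      tab <- ctx$mms
      ord <- tab$order_u[nrow(tab)]
      tibble::tibble(check = "velocity convergence order (formal 3)",
                     measured = ord, target = 3, tol = NA_real_,
                     pass = ord >= 3 - 0.2)
    },
    stop("unknown check: ", name))
}

#' Run a scenario end to end
#'
#' Builds the geometry, mesh and effective properties from a configuration,
#' runs the flow (and thermal) stages, evaluates the scenario's
#' verification checks, optionally writes VTK/CSV artifacts, and returns a
#' run report. Deterministic: identical configurations produce identical
#' outputs.
#'
#' @param config A `scenario_config` from [load_config()], or a builtin
#'   name such as `"paper_rupture"`.
#' @param overrides Optional named list of configuration overrides.
#' @param verbose Print progress.
#' @return A list of class `"run_report"`: `scenario`, `config`, `quality`
#'   (mesh quality), `log`, `extremes`, `verdicts`, `trajectory` (when
#'   `output$keep_fields`), `timing` (s).
#' @export
run_scenario <- function(config = "paper_rupture", overrides = NULL,
                         verbose = FALSE) {
  t0 <- Sys.time()
  if (is.character(config)) {
    reg <- builtin_scenarios()
    if (!config %in% names(reg)) {
      stop("unknown scenario '", config, "'")
    }
    cfg <- reg[[config]]
    if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
    validate_config(cfg)
    cfg$scenario <- config
  } else {
    cfg <- config
    if (!is.null(overrides)) {
      sc <- cfg$scenario; cfg$scenario <- NULL
      cfg <- merge_config(unclass(cfg), overrides)
      validate_config(cfg)
      cfg$scenario <- sc
    }
  }
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("scenario stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  ctx <- list(cfg = cfg)
  report <- list(scenario = cfg$scenario %||% "custom", config = cfg)
  if (cfg$kind == "mms") {
    ctx$mms <- stage("mms", mms_study())
    report$mms <- ctx$mms
    report$verdicts <- scenario_checks("mms_convergence", ctx)
    report$timing <- as.numeric(Sys.time() - t0, units = "secs")
    class(report) <- "run_report"
    return(report)
  }
  geo <- stage("geometry", do.call(vessel_geometry, cfg$geometry))
  bnd <- stage("geometry", build_geometry(geo))
  sizing <- mesh_sizing(cfg$mesh$h_max, cfg$mesh$h_min, cfg$mesh$growth_rate,
                        cfg$mesh$narrow_resolution, cfg$mesh$curvature_factor,
                        cfg$mesh$seed)
  msh <- stage("mesh", generate_mesh(bnd, sizing))
  fe <- stage("mesh", fe_space(msh))
  mat <- if (is.null(cfg$materials$table)) {
    material_table(silver_cp = cfg$materials$silver_cp)
  } else {
    material_table(cfg$materials$table, silver_cp = cfg$materials$silver_cp)
  }
  props <- stage("properties", props_from_names(
    cfg$materials$base, cfg$materials$s1, cfg$materials$s2,
    loading(cfg$materials$phi1, cfg$materials$phi2), mat))
  bcs <- flow_bcs(cfg$flow$v0, cfg$flow$p_out, cfg$flow$p_rupture,
                  cfg$flow$inlet_profile, cfg$flow$backflow_beta)
  ctx$fe <- fe; ctx$props <- props
  report$quality <- quality_report(msh)
  reynolds <- props$rho * cfg$flow$v0 * cfg$geometry$height / props$mu
  if (reynolds > 2000 && verbose) {
    message(sprintf("Reynolds number %.0f: laminar model outside its comfort zone",
                    reynolds))
  }
  report$reynolds <- reynolds
  if (cfg$kind == "steady_flow") {
    fcfg <- flow_config(picard_tol = cfg$solver$picard_tol,
                        picard_max = max(cfg$solver$picard_max, 50L),
                        include_convection = cfg$solver$include_convection,
                        relax = cfg$solver$relax)
    ctx$steady_flow <- stage("flow", solve_steady_flow(fe, props, bcs, fcfg))
    report$steady_flow <- ctx$steady_flow
  } else if (cfg$kind == "steady_thermal") {
    fstate <- flow_state(fe)   # quiescent fluid
    tcfg <- thermal_config(cfg$thermal$include_dissipation,
                           cfg$thermal$include_pressure_work,
                           cfg$thermal$alpha_p, cfg$solver$dt,
                           cfg$solver$time_scheme)
    tbcs <- thermal_bcs(cfg$thermal$T_inlet, cfg$thermal$T_outlet)
    ctx$steady_thermal <- stage("thermal",
                                solve_steady_thermal(fe, props, tcfg, tbcs, fstate))
    report$steady_thermal <- ctx$steady_thermal
  } else {
    fcfg <- flow_config(cfg$solver$dt, cfg$solver$t_end, cfg$solver$time_scheme,
                        cfg$solver$picard_tol, cfg$solver$picard_max,
                        cfg$solver$include_convection, cfg$solver$relax)
    thermal <- NULL
    if (isTRUE(cfg$thermal$enabled)) {
      thermal <- list(
        bcs = thermal_bcs(cfg$thermal$T_inlet, cfg$thermal$T_outlet),
        config = thermal_config(cfg$thermal$include_dissipation,
                                cfg$thermal$include_pressure_work,
                                cfg$thermal$alpha_p, cfg$solver$dt,
                                cfg$solver$time_scheme))
    }
    traj <- stage("flow", simulate_transient(fe, props, bcs, fcfg,
                                             thermal = thermal,
                                             output_times = cfg$output$times,
                                             verbose = verbose))
    ctx$trajectory <- traj
    report$log <- traj$log
    report$extremes <- stage("postprocess", extremes(traj, cfg$output$times))
    if (!is.null(cfg$output$dir)) {
      stage("export", export_fields(traj, cfg$output$dir))
      utils::write.csv(as.data.frame(traj$log),
                       file.path(cfg$output$dir, "run_log.csv"),
                       row.names = FALSE)
    }
    if (isTRUE(cfg$output$keep_fields)) report$trajectory <- traj
  }
  if (length(cfg$checks)) {
    report$verdicts <- do.call(rbind, lapply(cfg$checks, scenario_checks, ctx))
  }
  report$timing <- as.numeric(Sys.time() - t0, units = "secs")
  class(report) <- "run_report"
  report
}

#' Run every verification scenario and collect verdicts
#'
#' @param scenarios Character vector of builtin verification scenarios.
#' @param verbose Print progress.
#' @return A tibble of verdicts with a `scenario` column.
#' @export
verify_all <- function(scenarios = c("poiseuille_channel",
                                     "poiseuille_tube_axisym",
                                     "conduction_strip", "uniform_thermal",
                                     "mms_convergence"),
                       verbose = FALSE) {
  do.call(rbind, lapply(scenarios, function(s) {
    rep <- run_scenario(s, verbose = verbose)
    cbind(scenario = s, rep$verdicts)
  }))
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$scenario, "\n")
  if (!is.null(x$quality)) {
    cat(sprintf("  mesh: %d elements (min quality %.3f)\n",
                x$quality$n_elements, x$quality$min_quality))
  }
  if (!is.null(x$extremes)) {
    cat("  extremes:\n")
    print(as.data.frame(x$extremes), row.names = FALSE)
  }
  if (!is.null(x$verdicts)) {
    cat("  verification verdicts:\n")
    print(as.data.frame(x$verdicts), row.names = FALSE)
  }
  cat(sprintf("  timing: %.1f s\n", x$timing))
  invisible(x)
}
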