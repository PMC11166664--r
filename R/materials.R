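#' Thermophysical constants of the carrier fluid and nanoparticle species
#'
#' Returns the material table bundled with the package: whole blood as the
#' carrier fluid plus gold (Au) and silver (Ag) nanoparticles. Units are
#' `cp` J kg-1 K-1, `k` W m-1 K-1, `mu` Pa s, `rho` kg m-3.
#'
#' The published silver heat capacity in this table (2354 J kg-1 K-1) is
#' roughly ten times the handbook value for bulk silver (~235). The table is
#' shipped as printed; pass `silver_cp = "handbook"` to substitute 235.
#'
#' @param path Optional path to a user-supplied CSV with columns
#'   `name, cp, k, mu, rho`. Defaults to the bundled table.
#' @param silver_cp `"printed"` (default) keeps the tabulated 2354;
#'   `"handbook"` replaces it with 235.
#' @return A tibble with one row per material.
#' @export
#' @examples
#' material_table()
material_table <- function(path = NULL, silver_cp = c("printed", "handbook")) {
  silver_cp <- match.arg(silver_cp)
  if (is.null(path)) {
    path <- system.file("extdata", "materials.csv", package = "hemofem")
  }
  if (!file.exists(path)) stop("material table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "cp", "k", "mu", "rho")
  if (!all(need %in% names(tab))) {
    stop("material CSV must have columns: ", paste(need, collapse = ", "))
  }
  tab <- tab[, need]
  for (col in c("cp", "k", "mu", "rho")) {
    if (!is.numeric(tab[[col]]) || any(!is.finite(tab[[col]])) || any(tab[[col]] <= 0)) {
      stop("material column '", col, "' must be strictly positive and finite")
    }
  }
  if (silver_cp == "handbook" && "silver" %in% tab$name) {
    tab$cp[tab$name == "silver"] <- 235
  }
  tibble::as_tibble(tab)
}

#' Look up one material record by name
#'
#' @param name Material name as in the table (e.g. `"blood"`).
#' @param table A material table as returned by [material_table()].
#' @return A one-row list with fields `name, cp, k, mu, rho`.
#' @export
material_record <- function(name, table = material_table()) {
  row <- table[table$name == name, ]
  if (nrow(row) != 1L) stop("material '", name, "' not found (or duplicated) in table")
  as.list(row)
}

#' Nanoparticle volume fractions
#'
#' Constructs and validates the particle loading of the two-species
#' suspension. Species 1 is gold, species 2 is silver (fixed order: the
#' two-step mixture laws are not symmetric under species exchange).
#'
#' @param phi1 Volume fraction of species 1 (gold), dimensionless.
#' @param phi2 Volume fraction of species 2 (silver), dimensionless.
#' @return A list of class `"loading"`.
#' @export
loading <- function(phi1 = 0.01, phi2 = 0.01) {
  if (!is.numeric(phi1) || !is.numeric(phi2) || length(phi1) != 1L || length(phi2) != 1L) {
    stop("phi1 and phi2 must be scalar numerics")
  }
  if (!is.finite(phi1) || !is.finite(phi2)) stop("volume fractions must be finite")
  if (phi1 < 0 || phi2 < 0) stop("volume fractions must be nonnegative")
  if (phi1 >= 1 || phi2 >= 1) stop("volume fractions must be below 1")
  if (phi1 + phi2 >= 0.5) {
    stop("phi1 + phi2 must stay below 0.5: the dilute-suspension mixture laws ",
         "are not meaningful at such loadings")
  }
  structure(list(phi1 = phi1, phi2 = phi2), class = "loading")
}

as_loading <- function(load) {
  if (inherits(load, "loading")) return(load)
  if (is.list(load) && all(c("phi1", "phi2") %in% names(load))) {
    return(loading(load$phi1, load$phi2))
  }
  stop("expected a loading object (see loading())")
}

#' Effective density of the two-species suspension
#'
#' Two-step volume-weighted mixture:
#' `(1 - phi2) * ((1 - phi1) * rho_f + phi1 * rho_s1) + phi2 * rho_s2`.
#'
#' @param base,s1,s2 Material records (carrier fluid, species 1, species 2),
#'   see [material_record()].
#' @param load A [loading()] object.
#' @return Density in kg m-3.
#' @export
effective_density <- function(base, s1, s2, load) {
  load <- as_loading(load)
  (1 - load$phi2) * ((1 - load$phi1) * base$rho + load$phi1 * s1$rho) +
    load$phi2 * s2$rho
}

#' Effective volumetric heat capacity of the suspension
#'
#' Same two-step volume weighting as [effective_density()], applied to
#' `rho * cp` of each constituent.
#'
#' @inheritParams effective_density
#' @return Volumetric heat capacity in J m-3 K-1.
#' @export
effective_heat_capacity <- function(base, s1, s2, load) {
  load <- as_loading(load)
  (1 - load$phi2) * ((1 - load$phi1) * base$rho * base$cp +
                       load$phi1 * s1$rho * s1$cp) +
    load$phi2 * s2$rho * s2$cp
}

#' Effective dynamic viscosity (two-step Brinkman)
#'
#' `mu_f / ((1 - phi1)^2.5 * (1 - phi2)^2.5)`. Strictly increasing in each
#' volume fraction.
#'
#' @param base Carrier-fluid material record.
#' @param load A [loading()] object.
#' @return Dynamic viscosity in Pa s.
#' @export
effective_viscosity <- function(base, load) {
  load <- as_loading(load)
  base$mu / ((1 - load$phi1)^2.5 * (1 - load$phi2)^2.5)
}

maxwell_step <- function(k_fluid, k_solid, phi) {
  if (k_fluid <= 0 || k_solid <= 0) stop("conductivities must be positive")
  k_fluid * (k_solid + 2 * k_fluid - 2 * phi * (k_fluid - k_solid)) /
    (k_solid + 2 * k_fluid + phi * (k_fluid - k_solid))
}

#' Effective thermal conductivity (two-step Maxwell)
#'
#' Maxwell's dilute-sphere-suspension law applied twice: species 1 in the
#' carrier fluid gives the intermediate conductivity `k_nf`, then species 2
#' in that intermediate fluid gives the hybrid value.
#'
#' @inheritParams effective_density
#' @return Thermal conductivity in W m-1 K-1.
#' @export
effective_conductivity <- function(base, s1, s2, load) {
  load <- as_loading(load)
  k_nf <- maxwell_step(base$k, s1$k, load$phi1)
  maxwell_step(k_nf, s2$k, load$phi2)
}

#' All effective suspension properties at once
#'
#' Aggregates the four mixture laws plus the derived kinematic viscosity
#' `nu = mu / rho` and thermal diffusivity `alpha = k / (rho cp)`.
#'
#' @inheritParams effective_density
#' @return A list of class `"effective_properties"` with fields
#'   `rho, rho_cp, mu, k, nu, alpha` (SI units).
#' @export
#' @examples
#' mats <- material_table()
#' effective_bundle(material_record("blood", mats),
#'                  material_record("gold", mats),
#'                  material_record("silver", mats),
#'                  loading(0.01, 0.01))
effective_bundle <- function(base, s1, s2, load) {
  load <- as_loading(load)
  rho <- effective_density(base, s1, s2, load)
  rho_cp <- effective_heat_capacity(base, s1, s2, load)
  mu <- effective_viscosity(base, load)
  k <- effective_conductivity(base, s1, s2, load)
  props <- list(rho = rho, rho_cp = rho_cp, mu = mu, k = k,
                nu = mu / rho, alpha = k / rho_cp,
                loading = load)
  stopifnot(all(vapply(props[c("rho", "rho_cp", "mu", "k", "nu", "alpha")],
                       function(x) is.finite(x) && x > 0, logical(1))))
  class(props) <- "effective_properties"
  props
}

#' @export
print.effective_properties <- function(x, ...) {
  cat("Effective hybrid-suspension properties (phi1 =", x$loading$phi1,
      ", phi2 =", x$loading$phi2, ")\n")
  cat(sprintf("  rho    = %.6g kg m-3\n", x$rho))
  cat(sprintf("  rho*cp = %.6g J m-3 K-1\n", x$rho_cp))
  cat(sprintf("  mu     = %.6g Pa s\n", x$mu))
  cat(sprintf("  k      = %.6g W m-1 K-1\n", x$k))
  cat(sprintf("  nu     = %.6g m2 s-1\n", x$nu))
  cat(sprintf("  alpha  = %.6g m2 s-1\n", x$alpha))
  invisible(x)
}

#' Effective properties straight from material names
#'
#' Convenience wrapper around [effective_bundle()] looking the three
#' constituents up by name.
#'
#' @param base,s1,s2 Material names in `table`.
#' @param load A [loading()].
#' @param table A material table ([material_table()]).
#' @return An `effective_properties` bundle.
#' @export
props_from_names <- function(base = "blood", s1 = "gold", s2 = "silver",
                             load = loading(0.01, 0.01), table = material_table()) {
  effective_bundle(material_record(base, table),
                   material_record(s1, table),
                   material_record(s2, table), load)
}
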