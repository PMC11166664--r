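# Tidiers and plotting methods for run results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a run report into its extremes table
#'
#' @param x A `run_report`.
#' @param ... Unused.
#' @return The extremes tibble (or verdicts for verification-only runs).
#' @export
tidy.run_report <- function(x, ...) {
  if (!is.null(x$extremes)) return(tibble::as_tibble(x$extremes))
  if (!is.null(x$verdicts)) return(tibble::as_tibble(x$verdicts))
  tibble::tibble()
}

#' One-row summary of a run report
#'
#' @param x A `run_report`.
#' @param ... Unused.
#' @export
glance.run_report <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario,
    n_elements = x$quality$n_elements %||% NA_integer_,
    min_quality = x$quality$min_quality %||% NA_real_,
    reynolds = x$reynolds %||% NA_real_,
    max_mass_defect = if (!is.null(x$log)) max(x$log$mass_defect) else NA_real_,
    checks_passed = if (!is.null(x$verdicts)) sum(x$verdicts$pass) else NA_integer_,
    checks_total = if (!is.null(x$verdicts)) nrow(x$verdicts) else NA_integer_,
    timing = x$timing)
}

#' Plot an extremes table over time
#'
#' @param object An `extremes_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.extremes_table <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- as.data.frame(object)
  long <- do.call(rbind, lapply(
    intersect(c("v_max", "v_min_line", "p_max", "p_min"), names(df)),
    function(v) data.frame(t = df$t, quantity = v, value = df[[v]])))
  long$panel <- ifelse(startsWith(long$quantity, "v"), "speed [m/s]",
                       "pressure [Pa]")
  ggplot2::ggplot(long, ggplot2::aes(x = t, y = value, colour = quantity)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time [s]", y = NULL)
}

#' Plot a line sample
#'
#' @param object A `line_sample` from [sample_line()].
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.line_sample <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(as.data.frame(object), ggplot2::aes(x = s, y = value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "arc length [m]", y = "value")
}

#' Plot a mesh
#'
#' @param mesh A `vessel_mesh`.
#' @param colour Edge colour.
#' @return A ggplot object.
#' @export
plot_mesh <- function(mesh, colour = "grey30") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  tri <- mesh$tri
  df <- data.frame(
    z = as.vector(t(cbind(mesh$nodes[tri[, 1], 1], mesh$nodes[tri[, 2], 1],
                          mesh$nodes[tri[, 3], 1]))),
    x = as.vector(t(cbind(mesh$nodes[tri[, 1], 2], mesh$nodes[tri[, 2], 2],
                          mesh$nodes[tri[, 3], 2]))),
    id = rep(seq_len(nrow(tri)), each = 3))
  ggplot2::ggplot(df, ggplot2::aes(x = z, y = x, group = id)) +
    ggplot2::geom_polygon(fill = NA, colour = colour, linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "z [m]", y = "x [m]")
}
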