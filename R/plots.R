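# ggplot2 display methods for the main result types.

#' Plot a kinetic fit over its data
#'
#' @param object A `kinetic_fit` with attached data.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kinetic_fit
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  stopifnot(!is.null(object$data))
  d <- object$data
  tgrid <- seq(min(d$time_min), max(d$time_min), length.out = 200)
  curve <- if (object$model == "double") {
    biphasic_fraction(tgrid, object$k_fast, object$k_slow, object$frac_fast,
                      object$plateau)
  } else {
    object$plateau * (1 - exp(-object$k_fast * tgrid))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min, y = .data$fraction)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = tibble::tibble(time_min = tgrid,
                                             fraction = curve),
                       colour = "steelblue") +
    ggplot2::labs(x = "time (min)", y = "fraction modified",
                  title = sprintf("%s-exponential fit, k_fast = %.3g /min",
                                  object$model, object$k_fast)) +
    ggplot2::theme_minimal()
}

#' Plot an activity-pH profile fit
#'
#' Observed rates (log scale) with the fitted single- or double-pKa curve.
#'
#' @param object A `ph_fit` with attached data.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ph_fit
#' @export
autoplot.ph_fit <- function(object, ...) {
  stopifnot(!is.null(object$data))
  d <- object$data
  grid <- seq(min(d$pH), max(d$pH), length.out = 200)
  k <- if (object$model == "double_pka") {
    model_double_pka(grid, object$k_int, object$pka_acid, object$pka_nuc)
  } else {
    model_single_pka(grid, object$k_int, object$pka_acid)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pH, y = .data$k_obs)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = tibble::tibble(pH = grid, k_obs = k),
                       colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "k_obs (1/min)",
                  title = sprintf("apparent pKa = %.2f", object$pka_acid)) +
    ggplot2::theme_minimal()
}

#' Plot a free-energy surface, optionally with a path
#'
#' @param object An [fe_surface()].
#' @param path Optional `path_string` to overlay.
#' @param ... Unused.
#' @return A ggplot (filled contour of G with the string images on top).
#' @method autoplot fe_surface
#' @export
autoplot.fe_surface <- function(object, path = NULL, ...) {
  d <- tidy.fe_surface(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$xi_pt, y = .data$xi_at)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$G)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$G), colour = "white",
                          alpha = 0.3, bins = 20) +
    ggplot2::scale_fill_viridis_c(name = "G (kcal/mol)") +
    ggplot2::labs(x = expression(xi[PT] ~ "(Å)"),
                  y = expression(xi[AT] ~ "(Å)")) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    pd <- tibble::tibble(xi_pt = path$images[, 1], xi_at = path$images[, 2])
    p <- p + ggplot2::geom_path(data = pd, colour = "white") +
      ggplot2::geom_point(data = pd, colour = "white", size = 0.8)
  }
  p
}

#' Plot a reaction profile with labeled stationary states
#'
#' @param object A `reaction_profile`.
#' @param ... Unused.
#' @return A ggplot of G against the normalized arc coordinate.
#' @method autoplot reaction_profile
#' @export
autoplot.reaction_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$arc, y = .data$G)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$states, colour = "firebrick") +
    ggplot2::geom_text(data = object$states,
                       ggplot2::aes(label = .data$label),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "arc length (normalized)", y = "G (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Plot a reconstructed PMF
#'
#' @param object An `fe_pmf` from [pmf_2d()].
#' @param ... Unused.
#' @return A ggplot raster of the occupied bins.
#' @method autoplot fe_pmf
#' @export
autoplot.fe_pmf <- function(object, ...) {
  d <- tidy.fe_pmf(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$xi_pt, y = .data$xi_at,
                                  fill = .data$G)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "G (kcal/mol)") +
    ggplot2::labs(x = expression(xi[PT] ~ "(Å)"),
                  y = expression(xi[AT] ~ "(Å)")) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
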