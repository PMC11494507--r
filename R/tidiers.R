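#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a kinetic fit
#'
#' One row per fitted parameter, broom-style.
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  if (x$model == "double") {
    tibble::tibble(
      term = c("k_fast", "k_slow", "frac_fast", "plateau"),
      estimate = c(x$k_fast, x$k_slow, x$frac_fast, x$plateau),
      std.error = c(x$se_k_fast, x$se_k_slow, NA_real_, NA_real_))
  } else {
    tibble::tibble(term = c("k", "plateau"),
                   estimate = c(x$k_fast, x$plateau),
                   std.error = c(x$se_k_fast, NA_real_))
  }
}

#' @rdname tidy.kinetic_fit
#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(model = x$model, residual_rms = x$residual_rms,
                 converged = x$converged, n = x$n_points,
                 shared_plateau = x$shared_plateau)
}

#' Tidy an activity-pH profile fit
#'
#' @param x A `ph_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @method tidy ph_fit
#' @export
tidy.ph_fit <- function(x, ...) {
  terms <- c("k_int", "pka_acid")
  est <- c(x$k_int, x$pka_acid)
  se <- c(NA_real_, x$se_pka_acid)
  if (!is.null(x$pka_nuc)) {
    terms <- c(terms, "pka_nuc")
    est <- c(est, x$pka_nuc)
    se <- c(se, x$se_pka_nuc)
  }
  tibble::tibble(term = terms, estimate = est, std.error = se)
}

#' @rdname tidy.ph_fit
#' @method glance ph_fit
#' @export
glance.ph_fit <- function(x, ...) {
  tibble::tibble(model = x$model, residual_rms_log10 = x$residual_rms,
                 converged = x$converged, identifiable = x$identifiable,
                 note = x$note, n = x$n)
}

#' Tidy a reaction profile
#'
#' @param x A `reaction_profile`.
#' @param ... Unused.
#' @return The dense profile tibble (`arc`, `xi_pt`, `xi_at`, `G`).
#' @method tidy reaction_profile
#' @export
tidy.reaction_profile <- function(x, ...) x$profile

#' @rdname tidy.reaction_profile
#' @method glance reaction_profile
#' @export
glance.reaction_profile <- function(x, ...) {
  tibble::tibble(rate_controlling_barrier = x$rate_controlling_barrier,
                 n_states = nrow(x$states), converged = x$converged)
}
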