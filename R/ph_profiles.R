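# Activity-pH models for general-acid catalysis. The observed rate falls
# above the apparent pKa of the general acid (C10 N3-H must be protonated to
# donate its proton), so the single-pKa model multiplies the intrinsic rate
# by the protonated fraction.

#' Single-pKa activity model
#'
#' `k_obs = k_int / (1 + 10^(pH - pka_acid))`: the intrinsic rate times the
#' Henderson-Hasselbalch protonated fraction of the general acid. At
#' `pH = pka_acid` the rate is half the intrinsic rate; well below the pKa
#' it plateaus at `k_int`.
#'
#' @param pH pH value(s).
#' @param k_int Intrinsic rate constant (1/min), > 0.
#' @param pka_acid Apparent pKa of the general acid.
#' @return Observed rate constant(s), 1/min.
#' @export
model_single_pka <- function(pH, k_int, pka_acid) {
  stopifnot(k_int > 0)
  k_int / (1 + 10^(pH - pka_acid))
}

#' Double-pKa (bell-shaped) activity model
#'
#' `k_obs = k_int * [1/(1 + 10^(pH - pka_acid))] * [1/(1 + 10^(pka_nuc - pH))]`:
#' the general acid must be protonated *and* the nucleophile deprotonated.
#' Reduces to the single-pKa model as `pka_nuc -> -Inf`; symmetric factors
#' peak midway between the two pKas.
#'
#' @inheritParams model_single_pka
#' @param pka_nuc Apparent pKa of the nucleophile; expected below
#'   `pka_acid` (warns otherwise).
#' @return Observed rate constant(s), 1/min.
#' @export
model_double_pka <- function(pH, k_int, pka_acid, pka_nuc) {
  stopifnot(k_int > 0)
  if (pka_nuc >= pka_acid)
    warning("pka_nuc >= pka_acid: the bell-shaped profile will be strongly ",
            "suppressed")
  k_int / ((1 + 10^(pH - pka_acid)) * (1 + 10^(pka_nuc - pH)))
}

#' Fit an activity-pH profile
#'
#' Least-squares fit of the single- or double-pKa model on the log10 rate
#' scale (rates span orders of magnitude), with multi-start over a pKa grid
#' from 3 to 10. Flat, pH-independent data are flagged unidentifiable
#' (apparent pKa standard error above 2 units), mirroring the "no pH
#' dependence observed" situation of the C10(n1c) variant.
#'
#' @param ds pH-rate dataset: data frame with columns `pH` and `k_obs`
#'   (replicates as extra rows); `k_obs > 0`.
#' @param model `"single_pka"` (default) or `"double_pka"`.
#' @return A `ph_fit` object: list with `model`, `k_int`, `pka_acid`,
#'   `pka_nuc` (double only), standard errors, `residual_rms` (log10
#'   scale), `identifiable`, `converged`, `note`.
#' @export
fit_ph_profile <- function(ds, model = c("single_pka", "double_pka")) {
  model <- match.arg(model)
  stopifnot(is.data.frame(ds), all(c("pH", "k_obs") %in% names(ds)))
  if (any(ds$k_obs <= 0)) stop("k_obs must be positive")
  if (any(ds$pH < 0 | ds$pH > 14)) stop("pH must lie in [0, 14]")
  n_ph <- length(unique(ds$pH))
  need <- if (model == "single_pka") 4L else 5L
  if (n_ph < need)
    stop("need at least ", need, " distinct pH values for the ", model,
         " model")
  d <- data.frame(pH = ds$pH, y = log10(ds$k_obs))
  if (stats::sd(d$y) < 1e-12) {
    fit <- .ph_fit_degenerate(model, mean_logk = mean(d$y))
    return(fit)
  }
  lk0 <- max(d$y)
  pka_grid <- 3:10
  best <- NULL
  if (model == "single_pka") {
    for (p0 in pka_grid) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ lk - log10(1 + 10^(pH - pka)), data = d,
          start = list(lk = lk0, pka = p0),
          lower = c(-20, 0), upper = c(20, 14),
          control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::residuals(fit)^2)
        if (is.null(best) || rss < best$rss - 1e-12)
          best <- list(fit = fit, rss = rss)
      }
    }
  } else {
    grid2 <- expand.grid(pa = pka_grid, pn = pka_grid)
    grid2 <- grid2[grid2$pn < grid2$pa, , drop = FALSE]
    for (i in seq_len(nrow(grid2))) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ lk - log10(1 + 10^(pH - pka)) - log10(1 + 10^(pkn - pH)),
          data = d,
          start = list(lk = lk0, pka = grid2$pa[i], pkn = grid2$pn[i]),
          lower = c(-20, 0, -25), upper = c(20, 14, 14),
          control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        cf <- stats::coef(fit)
        # the bell model is near-degenerate under swapping the two pKas;
        # keep the conventional labeling pka_nuc < pka_acid
        if (cf["pkn"] >= cf["pka"]) next
        rss <- sum(stats::residuals(fit)^2)
        if (is.null(best) || rss < best$rss - 1e-12)
          best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) return(.ph_fit_degenerate(model, mean_logk = mean(d$y)))
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e)
                   stats::setNames(rep(NA_real_, length(cf)), names(cf)))
  se_pka <- unname(se["pka"])
  identifiable <- is.finite(se_pka) && se_pka <= 2
  structure(
    list(model = model,
         k_int = 10^unname(cf["lk"]),
         pka_acid = unname(cf["pka"]),
         pka_nuc = if (model == "double_pka") unname(cf["pkn"]) else NULL,
         se_log10_k_int = unname(se["lk"]),
         se_pka_acid = se_pka,
         se_pka_nuc = if (model == "double_pka") unname(se["pkn"]) else NULL,
         residual_rms = sqrt(best$rss / nrow(d)),
         n = nrow(d), converged = TRUE,
         identifiable = identifiable,
         note = if (identifiable) NA_character_ else "no pH dependence",
         data = tibble::as_tibble(ds)),
    class = "ph_fit"
  )
}

.ph_fit_degenerate <- function(model, mean_logk) {
  structure(
    list(model = model, k_int = 10^mean_logk, pka_acid = NA_real_,
         pka_nuc = NULL, se_log10_k_int = NA_real_,
         se_pka_acid = Inf, se_pka_nuc = NULL,
         residual_rms = NA_real_, n = NA_integer_, converged = FALSE,
         identifiable = FALSE, note = "no pH dependence", data = NULL),
    class = "ph_fit"
  )
}

#' @export
print.ph_fit <- function(x, ...) {
  cat(sprintf("<ph_fit: %s>%s\n", x$model,
              if (!x$identifiable) " [pKa unidentifiable: no pH dependence]" else ""))
  cat(sprintf("  k_int = %.4g /min, pKa(acid) = %.3f (se %.2g)\n",
              x$k_int, x$pka_acid, x$se_pka_acid))
  if (!is.null(x$pka_nuc))
    cat(sprintf("  pKa(nuc) = %.3f (se %.2g)\n", x$pka_nuc, x$se_pka_nuc))
  invisible(x)
}

#' Relative-rate table against a reference condition
#'
#' Divides every (variant, pH) mean rate by the rate of a reference
#' condition (by default the unmodified ribozyme at pH 6.0) and rounds the
#' displayed ratio to two significant figures; full precision is kept in
#' `rel_rate`. The ratios are invariant to the unit of the input rates.
#'
#' @param rates Data frame with columns `variant`, `pH`, `k` (mean rate per
#'   condition).
#' @param ref_variant,ref_pH Reference condition (default "unmodified",
#'   pH 6.0).
#' @return Tibble `variant`, `pH`, `k`, `rel_rate`, `rel_rate_display`.
#' @export
relative_rate_table <- function(rates, ref_variant = "unmodified",
                                ref_pH = 6.0) {
  stopifnot(is.data.frame(rates),
            all(c("variant", "pH", "k") %in% names(rates)))
  ref <- rates$k[rates$variant == ref_variant & rates$pH == ref_pH]
  if (length(ref) != 1L || !is.finite(ref))
    stop("reference rate for (", ref_variant, ", pH ", ref_pH,
         ") is missing")
  out <- tibble::as_tibble(rates)
  out$rel_rate <- out$k / ref
  out$rel_rate_display <- signif(out$rel_rate, 2)
  out
}

#' Mechanism model for one ribozyme variant
#'
#' Collects the quantities that summarize the two-step general-acid
#' mechanism for a variant: the rate-controlling barrier, relative intrinsic
#' rates (calculated and experimental), and the general-acid pKa in solution,
#' its environment shift, and their sum in the ribozyme. The ribozyme pKa is
#' always constructed as `pka_soln + dpka_shift`.
#'
#' @param variant_id Label.
#' @param dG_barrier Rate-controlling barrier, kcal/mol.
#' @param pka_soln Solution pKa of the general-acid nucleobase.
#' @param dpka_shift Environment-induced pKa shift.
#' @param k_int_rel_calc,k_int_rel_expt Relative intrinsic rates (unitless).
#' @param pka_apparent_expt Experimental apparent pKa (NA when no pH
#'   dependence is observed).
#' @param pka_nuc Optional nucleophile pKa for bell-shaped profiles.
#' @return A one-row tibble of class `mechanism_model`.
#' @export
mechanism_model <- function(variant_id, dG_barrier, pka_soln, dpka_shift,
                            k_int_rel_calc = NA_real_,
                            k_int_rel_expt = NA_real_,
                            pka_apparent_expt = NA_real_,
                            pka_nuc = NA_real_) {
  out <- tibble::tibble(
    variant_id = variant_id, dG_barrier = dG_barrier,
    k_int_rel_calc = k_int_rel_calc, k_int_rel_expt = k_int_rel_expt,
    pka_soln = pka_soln, dpka_shift = dpka_shift,
    pka_ribozyme = ribozyme_pka(pka_soln, dpka_shift),
    pka_apparent_expt = pka_apparent_expt, pka_nuc = pka_nuc
  )
  class(out) <- c("mechanism_model", class(out))
  out
}

#' Computed activity-pH profile from barrier and calculated pKa
#'
#' Reconstructs the activity-pH curve of a variant from first principles:
#' the intrinsic rate from the rate-controlling barrier via transition-state
#' theory, multiplied by the protonated-acid fraction using the calculated
#' ribozyme pKa (and optionally a deprotonated-nucleophile factor). The
#' curve's half-maximal pH equals the ribozyme pKa.
#'
#' @param mm A [mechanism_model()] row.
#' @param ctx A [thermo_ctx()] (default 298.15 K, the simulation
#'   temperature).
#' @param ph_grid pH values for the curve.
#' @param use_nucleophile Multiply in the nucleophile deprotonation factor
#'   when `pka_nuc` is available (default FALSE: single-pKa form).
#' @return Tibble `pH`, `k_model` (1/s) with attribute `variant_id`.
#' @export
build_computed_profile <- function(mm, ctx = thermo_ctx(),
                                   ph_grid = seq(4.5, 9.5, by = 0.05),
                                   use_nucleophile = FALSE) {
  stopifnot(inherits(mm, "mechanism_model"), nrow(mm) == 1L,
            is.finite(mm$dG_barrier), is.finite(mm$pka_ribozyme))
  k_int <- eyring_rate(mm$dG_barrier, ctx)
  k <- k_int / (1 + 10^(ph_grid - mm$pka_ribozyme))
  if (use_nucleophile && is.finite(mm$pka_nuc))
    k <- k / (1 + 10^(mm$pka_nuc - ph_grid))
  out <- tibble::tibble(pH = ph_grid, k_model = k)
  attr(out, "variant_id") <- mm$variant_id
  out
}

#' Align a computed profile to an experimental one
#'
#' Scales a computed activity-pH curve by the scalar
#' `max(experimental) / max(computed)` so its maximum matches the
#' experimental fit. When several variants are displayed together the scalar
#' derived from the reference (unmodified MTR1) curve is applied to all of
#' them; pass that scalar through `scalar` for the non-reference curves.
#'
#' @param computed Tibble with columns `pH`, `k_model`.
#' @param experimental Tibble with columns `pH` and `k_model` (or `k_obs`);
#'   ignored when `scalar` is given.
#' @param scalar Optional pre-computed normalization scalar.
#' @return The computed tibble with `k_model` rescaled; attribute `scalar`
#'   records the factor.
#' @export
normalize_profiles <- function(computed, experimental = NULL, scalar = NULL) {
  stopifnot(is.data.frame(computed), "k_model" %in% names(computed))
  if (is.null(scalar)) {
    stopifnot(is.data.frame(experimental))
    kexp <- if ("k_model" %in% names(experimental)) experimental$k_model
    else experimental$k_obs
    if (length(intersect(round(computed$pH, 6), round(experimental$pH, 6))) == 0L)
      stop("computed and experimental curves must overlap in pH")
    mc <- max(computed$k_model)
    if (mc <= 0 || max(kexp) <= 0) stop("curve maximum is zero")
    scalar <- max(kexp) / mc
  }
  out <- computed
  out$k_model <- out$k_model * scalar
  attr(out, "scalar") <- scalar
  out
}
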