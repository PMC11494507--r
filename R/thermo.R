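# Physical constants (CODATA); energies in kcal/mol throughout.
.KB_SI <- 1.380649e-23      # J/K
.H_SI <- 6.62607015e-34     # J s
.R_KCAL <- 1.98720425e-3    # kcal / (mol K)

#' Thermodynamic context
#'
#' Bundles the temperature and transmission coefficient used by the
#' transition-state-theory conversions. Free-energy work is referenced to the
#' simulation temperature (298.15 K); experimental kinetics were measured at
#' 37 C (310.15 K). Keeping both in an explicit context object avoids mixing
#' them silently.
#'
#' @param temperature Absolute temperature in Kelvin. Default 298.15.
#' @param transmission_coefficient Unitless Eyring transmission coefficient
#'   (kappa). Default 1.
#' @return A `thermo_ctx` object (list with `temperature`,
#'   `transmission_coefficient`, and derived `RT` and `RT_ln10` in kcal/mol).
#' @examples
#' ctx <- thermo_ctx()
#' ctx$RT_ln10  # 1.364 kcal/mol at 298.15 K
#' @export
thermo_ctx <- function(temperature = 298.15, transmission_coefficient = 1) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0,
            is.numeric(transmission_coefficient), transmission_coefficient > 0)
  structure(
    list(
      temperature = temperature,
      transmission_coefficient = transmission_coefficient,
      RT = .R_KCAL * temperature,
      RT_ln10 = .R_KCAL * temperature * log(10)
    ),
    class = "thermo_ctx"
  )
}

#' @export
print.thermo_ctx <- function(x, ...) {
  cat(sprintf("<thermo_ctx> T = %.2f K, kappa = %g, RT = %.4f kcal/mol\n",
              x$temperature, x$transmission_coefficient, x$RT))
  invisible(x)
}

#' Eyring transition-state-theory rate
#'
#' Converts an activation free energy into a first-order rate constant,
#' `k = kappa * (kB T / h) * exp(-dG / RT)`. At 298.15 K the prefactor
#' `kB T / h` is 6.212e12 /s. A barrier of 16.3 kcal/mol (the unmodified
#' MTR1 rate-controlling barrier) gives roughly 7 /s.
#'
#' @param dG_barrier Activation free energy in kcal/mol (scalar or vector).
#' @param ctx A [thermo_ctx()].
#' @return Rate constant(s) in 1/s.
#' @export
eyring_rate <- function(dG_barrier, ctx = thermo_ctx()) {
  stopifnot(inherits(ctx, "thermo_ctx"), is.numeric(dG_barrier))
  prefactor <- ctx$transmission_coefficient * .KB_SI * ctx$temperature / .H_SI
  prefactor * exp(-dG_barrier / ctx$RT)
}

#' Relative rate from two free-energy barriers
#'
#' Ratio of TST rates for barriers `dG_a` and `dG_b`:
#' `exp((dG_a - dG_b) / RT)`; the Eyring prefactors cancel, so the ratio is
#' the rate of the *b* process relative to the *a* process. For the barriers
#' 16.3 (MTR1) and 15.7 kcal/mol (C10(n1c,c5n)) at 298.15 K this is 2.75.
#'
#' @param dG_a,dG_b Barriers in kcal/mol.
#' @inheritParams eyring_rate
#' @return Unitless fold ratio `k_b / k_a`.
#' @export
relative_rate_from_barriers <- function(dG_a, dG_b, ctx = thermo_ctx()) {
  stopifnot(inherits(ctx, "thermo_ctx"))
  exp((dG_a - dG_b) / ctx$RT)
}

#' pKa shift from an alchemical free-energy difference
#'
#' `dpKa = ddG / (RT ln 10)`. At 298.15 K, `RT ln 10` = 1.364 kcal/mol, so a
#' 2.86 kcal/mol protonation free-energy shift corresponds to 2.1 pKa units.
#'
#' @param ddG Free-energy difference in kcal/mol.
#' @inheritParams eyring_rate
#' @return pKa shift (unitless).
#' @seealso [ddg_from_delta_pka()] for the inverse.
#' @export
delta_pka_from_ddg <- function(ddG, ctx = thermo_ctx()) {
  stopifnot(inherits(ctx, "thermo_ctx"))
  ddG / ctx$RT_ln10
}

#' @rdname delta_pka_from_ddg
#' @param dpKa pKa shift (unitless).
#' @export
ddg_from_delta_pka <- function(dpKa, ctx = thermo_ctx()) {
  stopifnot(inherits(ctx, "thermo_ctx"))
  dpKa * ctx$RT_ln10
}

#' pKa of a group in the ribozyme environment
#'
#' Solution pKa plus the environment-induced shift; for unmodified MTR1,
#' 4.2 + 2.1 = 6.3.
#'
#' @param pka_soln Solution pKa of the free nucleotide.
#' @param dpka Shift induced by the folded ribozyme environment.
#' @return Ribozyme pKa.
#' @export
ribozyme_pka <- function(pka_soln, dpka) pka_soln + dpka

#' Bronsted analysis of nucleophile reactivity
#'
#' Slope of log10(rate) versus nucleophile pKa (beta_nuc). With exactly two
#' points the exact two-point slope is returned; with more, an ordinary
#' least-squares fit with standard errors. A beta_nuc magnitude near 0.5
#' indicates substantial bond formation to the nucleophile in the transition
#' state — for adenosine (pKa 3.7, relative rate 1.0) versus
#' 7-deazaadenosine (pKa 5.3, relative rate 6.1) the slope is 0.49.
#'
#' @param data Data frame with columns `pka_nuc` and `rate` (absolute or
#'   relative rates; the slope is invariant to the rate unit).
#' @return A tibble with one row: `beta_nuc`, `intercept`, `se_beta`
#'   (NA for two points), `n`.
#' @export
bronsted_beta <- function(data) {
  stopifnot(is.data.frame(data), all(c("pka_nuc", "rate") %in% names(data)))
  pka <- data$pka_nuc
  rate <- data$rate
  if (length(pka) < 2L) stop("bronsted_beta() needs at least 2 points")
  if (any(rate <= 0)) stop("rates must be positive")
  if (length(unique(pka)) < 2L) stop("at least two distinct pKa values required")
  y <- log10(rate)
  if (length(pka) == 2L) {
    beta <- diff(y) / diff(pka)
    return(tibble::tibble(beta_nuc = beta, intercept = y[1] - beta * pka[1],
                          se_beta = NA_real_, n = 2L))
  }
  fit <- stats::lm(y ~ pka)
  # noise-free inputs give an exact fit; the s.e. columns are still wanted
  cf <- suppressWarnings(stats::coef(summary(fit)))
  tibble::tibble(beta_nuc = cf["pka", "Estimate"],
                 intercept = cf["(Intercept)", "Estimate"],
                 se_beta = cf["pka", "Std. Error"],
                 n = length(pka))
}
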