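# Generators for every input the analysis stages consume, each with known
# ground truth so parameter recovery can be tested end to end.

#' Generate a biphasic first-order progress curve
#'
#' Simulates a gel-densitometry time course of the fraction of target RNA
#' alkylated, following the two-phase saturating model
#' `f(t) = plateau * (frac_fast * (1 - exp(-k_fast t)) +
#' (1 - frac_fast) * (1 - exp(-k_slow t)))`:
#' a fast phase reporting alkyl transfer itself and a slow phase from the
#' fraction of ribozyme initially folded in an inactive conformation.
#' Gaussian noise (gel quantification error) is added to the fractions;
#' values are reported unclipped.
#'
#' @param times Strictly increasing sample times, minutes, all >= 0.
#' @param k_fast,k_slow Phase rate constants, 1/min; `k_fast >= k_slow > 0`.
#' @param frac_fast Fraction of the amplitude in the fast phase, in [0, 1].
#' @param plateau Maximal fraction modified, in (0, 1].
#' @param noise_sd Additive Gaussian s.d. on the fraction (default 0).
#' @param seed Integer seed (default NULL: leave RNG state alone).
#' @param variant_id,pH Metadata labels attached to the output.
#' @return Tibble with columns `time_min`, `fraction`, `variant`, `pH`.
#' @examples
#' tc <- gen_time_course(seq(0, 30, length.out = 20), k_fast = 0.60,
#'                       k_slow = 0.01, frac_fast = 0.8, noise_sd = 0.02,
#'                       seed = 1)
#' @export
gen_time_course <- function(times, k_fast, k_slow, frac_fast = 1,
                            plateau = 1, noise_sd = 0, seed = NULL,
                            variant_id = "unmodified", pH = 6.0) {
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  stopifnot(all(times >= 0), k_fast > 0, k_slow > 0, k_fast >= k_slow,
            frac_fast >= 0, frac_fast <= 1, plateau > 0, plateau <= 1,
            noise_sd >= 0)
  f <- biphasic_fraction(times, k_fast, k_slow, frac_fast, plateau)
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd > 0) f <- f + stats::rnorm(length(times), sd = noise_sd)
  tibble::tibble(time_min = as.numeric(times), fraction = f,
                 variant = variant_id, pH = pH)
}

#' @rdname gen_time_course
#' @param t Times (minutes) at which to evaluate the noise-free model.
#' @export
biphasic_fraction <- function(t, k_fast, k_slow, frac_fast, plateau = 1) {
  plateau * (frac_fast * (1 - exp(-k_fast * t)) +
               (1 - frac_fast) * (1 - exp(-k_slow * t)))
}

#' Generate replicate pH-rate data
#'
#' Draws observed rate constants across a pH grid from the single- or
#' double-pKa activity model (see [model_single_pka()]), multiplied by
#' log-normal noise with a given coefficient of variation — rates span
#' orders of magnitude, so the noise is multiplicative.
#'
#' @param k_int Intrinsic rate constant, 1/min.
#' @param pka_acid Apparent pKa of the general acid.
#' @param pka_nuc Optional apparent pKa of the nucleophile; when given, the
#'   double-pKa (bell-shaped) model is used.
#' @param ph_grid pH values at which rates are measured.
#' @param cv Relative s.d. of the multiplicative log-normal noise (>= 0).
#' @param n_reps Replicates per pH value.
#' @param seed Integer seed (default NULL).
#' @param variant_id Metadata label.
#' @return Tibble with columns `variant`, `pH`, `replicate`, `k_obs`
#'   (1/min), plus the noise-free `k_true`.
#' @export
gen_ph_rate_data <- function(k_int, pka_acid, pka_nuc = NULL,
                             ph_grid = seq(5.5, 8.5, by = 0.5), cv = 0,
                             n_reps = 3L, seed = NULL,
                             variant_id = "unmodified") {
  stopifnot(k_int > 0, length(ph_grid) >= 1L, n_reps >= 1L)
  if (cv < 0) stop("coefficient of variation must be >= 0")
  k_true <- if (is.null(pka_nuc)) {
    model_single_pka(ph_grid, k_int, pka_acid)
  } else {
    model_double_pka(ph_grid, k_int, pka_acid, pka_nuc)
  }
  if (!is.null(seed)) set.seed(seed)
  out <- tidyr::expand_grid(pH = as.numeric(ph_grid),
                            replicate = seq_len(n_reps))
  out$k_true <- rep(k_true, each = n_reps)
  if (cv > 0) {
    # log-normal with E[noise] = 1 and sd/mean = cv
    sdlog <- sqrt(log1p(cv^2))
    out$k_obs <- out$k_true *
      stats::rlnorm(nrow(out), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    out$k_obs <- out$k_true
  }
  dplyr::bind_cols(tibble::tibble(variant = variant_id), out)[
    , c("variant", "pH", "replicate", "k_obs", "k_true")]
}

#' Build a free-energy surface from Gaussian components
#'
#' Sums axis-aligned Gaussian components (negative depths carve basins,
#' positive depths raise ridges or bumps) on a uniform grid over the
#' (xi_PT, xi_AT) reaction plane, then shifts the energy so the
#' reactant-basin minimum is zero.
#'
#' @param components Data frame with columns `center_pt`, `center_at`
#'   (Angstrom), `depth` (kcal/mol; negative = basin), `width_pt`,
#'   `width_at` (Gaussian sigmas, Angstrom).
#' @param extent_pt,extent_at Length-2 grid ranges (Angstrom); must cover
#'   the reactant and product anchors of interest.
#' @param spacing Grid spacing, Angstrom (> 0).
#' @param reactant Approximate reactant-basin position used to locate the
#'   zero of energy (default: center of the first negative-depth component).
#' @return An [fe_surface()] with attribute `reactant_min` (the refined
#'   basin minimum, a list with `point` and pre-shift `value`).
#' @export
gen_surface <- function(components,
                        extent_pt = c(-3, 3), extent_at = c(-4, 4),
                        spacing = 0.05, reactant = NULL) {
  stopifnot(is.data.frame(components))
  if (nrow(components) == 0L) stop("component list must not be empty")
  stopifnot(all(c("center_pt", "center_at", "depth", "width_pt", "width_at")
                %in% names(components)), spacing > 0)
  out_of_grid <- components$center_pt < extent_pt[1] |
    components$center_pt > extent_pt[2] |
    components$center_at < extent_at[1] |
    components$center_at > extent_at[2]
  if (any(out_of_grid))
    warning(sum(out_of_grid), " component(s) centered outside the grid")
  ax <- seq(extent_pt[1], extent_pt[2], by = spacing)
  ay <- seq(extent_at[1], extent_at[2], by = spacing)
  G <- matrix(0, length(ax), length(ay))
  for (i in seq_len(nrow(components))) {
    gx <- exp(-(ax - components$center_pt[i])^2 /
                (2 * components$width_pt[i]^2))
    gy <- exp(-(ay - components$center_at[i])^2 /
                (2 * components$width_at[i]^2))
    G <- G + components$depth[i] * outer(gx, gy)
  }
  s <- fe_surface(ax, ay, G)
  if (is.null(reactant)) {
    neg <- which(components$depth < 0)
    anchor <- if (length(neg)) neg[1] else 1L
    reactant <- c(components$center_pt[anchor], components$center_at[anchor])
  }
  rmin <- .grid_descend(s, reactant)
  s$values <- s$values - rmin$value
  s$padded <- .pad_grid(s$values)
  attr(s, "reactant_min") <- rmin
  s
}

#' Canonical MTR1-like free-energy surface preset
#'
#' A synthetic stand-in for the computed MTR1 reaction surface: reactant
#' basin near (-1.5, -2.5), intermediate after proton transfer, product near
#' (1.5, 2.5), a proton-transfer saddle (TS1) and a rate-controlling alkyl
#' transfer saddle (TS2) placed at `ts2_at` on the xi_AT axis (default
#' -0.24 Angstrom, an "early" TS). Component depths are rescaled linearly so
#' the minimax grid barrier from the reactant basin equals `barrier`
#' (scaling G leaves the minimax path unchanged, so the calibration is exact
#' up to grid resolution).
#'
#' @param barrier Requested rate-controlling barrier, kcal/mol (default
#'   16.3, the unmodified-MTR1 value).
#' @param ts2_at xi_AT position of the rate-controlling saddle (default
#'   -0.24).
#' @param spacing Grid spacing, Angstrom.
#' @return An [fe_surface()] with attributes `basins` (named list of R, I, P
#'   anchor points), `barrier` (the calibrated value) and `ts2` (nominal TS2
#'   position).
#' @export
mtr1_surface <- function(barrier = 16.3, ts2_at = -0.24, spacing = 0.05) {
  basins <- list(R = c(-1.5, -2.5), I = c(1.2, -1.7), P = c(1.5, 2.5))
  # the intermediate/product basin tails pull the realized col ~0.02 A
  # up-channel from the bump center, so the channel and bump sit at
  # ts2_at - 0.02 to place the saddle at ts2_at
  c_at <- ts2_at - 0.02
  comps <- tibble::tribble(
    ~center_pt, ~center_at, ~depth, ~width_pt, ~width_at,
    -1.5, -2.5, -1.00, 0.55, 0.55,   # reactant basin
     1.2, -1.7, -0.58, 0.50, 0.50,   # intermediate (post proton transfer)
     1.5,  2.5, -1.05, 0.60, 0.80,   # product basin
    -0.15, -2.1, -0.45, 1.20, 0.45,  # proton-transfer channel (R -> I)
     1.35, c_at, -0.25, 0.35, 2.80,  # alkyl-transfer channel (I -> P)
    -0.15, -2.1, 0.05, 0.30, 0.30,   # TS1 bump
     1.35, c_at, 0.12, 0.25, 0.25    # TS2 bump (rate-controlling saddle)
  )
  s0 <- gen_surface(comps, spacing = spacing, reactant = basins$R)
  b0 <- minimax_barrier(s0, basins$R, basins$P)$barrier
  comps$depth <- comps$depth * barrier / b0
  s <- gen_surface(comps, spacing = spacing, reactant = basins$R)
  attr(s, "basins") <- basins
  attr(s, "barrier") <- barrier
  attr(s, "ts2") <- c(1.35, ts2_at)
  attr(s, "components") <- comps
  s
}

#' Sample umbrella windows by overdamped Langevin dynamics
#'
#' Generates biased trajectories on a free-energy surface plus harmonic
#' window restraints `0.5 * k * |xi - center|^2`, using the Euler-Maruyama
#' overdamped Langevin update
#' `xi <- xi - (dt / gamma) * grad(G + bias) + sqrt(2 kT dt / gamma) * eta`.
#' The first 10% of steps are discarded as burn-in. Proposed moves leaving
#' the grid hull are rejected (the walker stays put), so restraint centers
#' should sit well inside the grid. Trajectories are exactly reproducible
#' from the seed.
#'
#' @param surface An [fe_surface()].
#' @param windows Data frame with columns `center_pt`, `center_at`
#'   (Angstrom) and `k_pt`, `k_at` (force constants, kcal/mol/A^2 > 0).
#' @param kT Thermal energy, kcal/mol (default 0.5925, i.e. 298.15 K).
#' @param n_steps Steps per window (post burn-in samples = 0.9 * n_steps).
#' @param step_size Time step in reduced units (default 1e-3).
#' @param friction Friction coefficient, reduced units (default 1).
#' @param seed Integer seed (default NULL).
#' @return Tibble with columns `window`, `step`, `xi_pt`, `xi_at`; attribute
#'   `windows` carries the window table, `burn_in` the discarded count.
#' @export
gen_biased_trajectories <- function(surface, windows, kT = 0.5924849,
                                    n_steps = 2000L, step_size = 1e-3,
                                    friction = 1, seed = NULL) {
  stopifnot(inherits(surface, "fe_surface"), is.data.frame(windows),
            all(c("center_pt", "center_at", "k_pt", "k_at") %in% names(windows)),
            all(windows$k_pt > 0), all(windows$k_at > 0),
            kT > 0, n_steps > 0, step_size > 0, friction > 0)
  axr <- range(surface$axis_pt); ayr <- range(surface$axis_at)
  if (any(windows$center_pt < axr[1] | windows$center_pt > axr[2] |
          windows$center_at < ayr[1] | windows$center_at > ayr[2]))
    stop("window centers must lie inside the grid")
  if (!is.null(seed)) set.seed(seed)
  burn <- floor(0.1 * n_steps)
  sigma <- sqrt(2 * kT * step_size / friction)
  res <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    c0 <- c(windows$center_pt[w], windows$center_at[w])
    kk <- c(windows$k_pt[w], windows$k_at[w])
    p <- c0
    traj <- matrix(NA_real_, n_steps, 2L)
    noise <- matrix(stats::rnorm(2L * n_steps, sd = sigma), n_steps, 2L)
    for (i in seq_len(n_steps)) {
      g <- .fes_point(surface, p[1], p[2])
      grad <- g[2:3] + kk * (p - c0)
      if (any(!is.finite(grad)) ||
          max(abs(grad)) * step_size / friction > diff(axr))
        stop("energy overflow during Langevin sampling; ",
             "use a smaller step_size")
      cand <- p - (step_size / friction) * grad + noise[i, ]
      if (cand[1] >= axr[1] && cand[1] <= axr[2] &&
          cand[2] >= ayr[1] && cand[2] <= ayr[2]) p <- cand
      traj[i, ] <- p
    }
    keep <- traj[(burn + 1L):n_steps, , drop = FALSE]
    res[[w]] <- tibble::tibble(window = w,
                               step = seq_len(nrow(keep)),
                               xi_pt = keep[, 1], xi_at = keep[, 2])
  }
  out <- dplyr::bind_rows(res)
  attr(out, "windows") <- windows
  attr(out, "burn_in") <- burn
  attr(out, "kT") <- kT
  out
}

#' Generate alchemical per-lambda samples with known free-energy difference
#'
#' Emulates an alchemical transformation (e.g. deprotonation of the general
#' acid N3 over a lambda schedule) by a chain of one-dimensional Gaussian
#' states: state k has reduced potential
#' `u_k(x) = (x - mu_k)^2 / (2 sigma^2) + a_k` with equally spaced means and
#' offsets `a_k` accumulating linearly to `ddg_true / kT`, so the analytic
#' end-to-end free-energy difference is exactly `ddg_true`. The `overlap`
#' parameter is sigma divided by the spacing of adjacent means; values well
#' below 1 give poor phase-space overlap.
#'
#' @param ddg_true Ground-truth end-to-end free-energy difference, kcal/mol.
#' @param n_windows Number of lambda windows (>= 2; default 25).
#' @param n_per_window Samples drawn from each window.
#' @param overlap Positive overlap parameter (default 1).
#' @param kT Thermal energy, kcal/mol (default 298.15 K value).
#' @param seed Integer seed (default NULL).
#' @return An `alchemical_dataset`: list with `u` (reduced energy matrix,
#'   n_windows x N_total: `u[k, n]` is sample n evaluated in state k),
#'   `n_k` (samples per state), `lambda` (schedule in [0,1]), `kT`,
#'   `ddg_true`, and `samples` (numeric vector, window-ordered).
#' @export
gen_alchemical_samples <- function(ddg_true, n_windows = 25L,
                                   n_per_window = 200L, overlap = 1,
                                   kT = 0.5924849, seed = NULL) {
  if (n_windows < 2L) stop("need at least 2 lambda windows")
  if (overlap <= 0)
    stop("overlap must be > 0: non-overlapping states cannot be estimated")
  if (!is.null(seed)) set.seed(seed)
  sigma <- 1
  spacing <- sigma / overlap
  mu <- (seq_len(n_windows) - 1L) * spacing
  a <- seq(0, ddg_true / kT, length.out = n_windows)
  x <- unlist(lapply(mu, function(m)
    stats::rnorm(n_per_window, mean = m, sd = sigma)))
  u <- outer(seq_len(n_windows), seq_along(x),
             function(k, n) (x[n] - mu[k])^2 / (2 * sigma^2) + a[k])
  structure(
    list(u = u, n_k = rep(n_per_window, n_windows),
         lambda = seq(0, 1, length.out = n_windows), kT = kT,
         ddg_true = ddg_true, samples = x),
    class = "alchemical_dataset"
  )
}

#' @export
print.alchemical_dataset <- function(x, ...) {
  cat(sprintf("<alchemical_dataset> %d lambda windows x %d samples, kT = %.4f kcal/mol\n",
              length(x$n_k), x$n_k[1], x$kT))
  invisible(x)
}
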