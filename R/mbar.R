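# Multistate Bennett acceptance ratio estimator, solved from its
# self-consistent equations. Internal energies are reduced (u = G/kT);
# conversion to kcal/mol happens only at module boundaries.

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# column-wise logsumexp of a matrix
.colLogSumExp <- function(M) {
  m <- apply(M, 2L, max)
  m + log(colSums(exp(sweep(M, 2L, m))))
}

.rowLogSumExp <- function(M) {
  m <- apply(M, 1L, max)
  m + log(rowSums(exp(sweep(M, 1L, m))))
}

#' Solve the MBAR self-consistent equations
#'
#' Estimates the dimensionless free energies `f_i` of K sampled states from
#' the reduced-energy matrix `u[i, n]` (every sample evaluated in every
#' state) by self-consistent iteration of
#' `f_i = -ln sum_n exp(-u_i(x_n)) / sum_k N_k exp(f_k - u_k(x_n))`,
#' followed by Newton polishing, with the gauge `f_1 = 0`. Asymptotic
#' uncertainties come from the standard MBAR covariance estimator. States
#' with poor phase-space overlap (best-partner overlap-matrix entry below
#' `overlap_threshold`) are flagged rather than failing silently.
#'
#' @param u Reduced-energy matrix, K states x N samples; `u[k, n]` is sample
#'   n evaluated in state k.
#' @param n_k Integer vector of samples contributed by each state
#'   (sum = N, all > 0).
#' @param tol Convergence tolerance on the maximum change in `f` (default
#'   1e-8).
#' @param max_iter Maximum self-consistent iterations (default 1e4).
#' @param overlap_threshold Threshold on the overlap diagnostic (worst
#'   best-partner entry of the overlap matrix; default 0.01).
#' @return An `mbar_result`: list with `f` (reduced free energies, `f[1] =
#'   0`), `se_f` (s.e. of `f_i - f_1`), `theta` (covariance matrix),
#'   `converged`, `n_iterations`, `overlap_matrix`, `overlap_min` (worst
#'   best-partner overlap across states), `low_overlap`, and the inputs
#'   `u`, `n_k`.
#' @export
mbar_solve <- function(u, n_k, tol = 1e-8, max_iter = 1e4,
                       overlap_threshold = 0.01) {
  u <- as.matrix(u)
  K <- nrow(u); N <- ncol(u)
  stopifnot(K >= 2L, length(n_k) == K, all(n_k > 0), sum(n_k) == N,
            all(is.finite(u)))
  lN <- log(n_k)
  f <- rep(0, K)
  converged <- FALSE
  it <- 0L
  resid <- Inf
  while (it < max_iter) {
    it <- it + 1L
    log_c <- .colLogSumExp(lN + f - u)       # per-sample mixture denominator
    f_new <- -.rowLogSumExp(sweep(-u, 2L, log_c))
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tol) { converged <- TRUE; break }
    # Newton polish once the SCF is in the basin of attraction
    if (resid < 1e-2 && it %% 5L == 0L) {
      log_c <- .colLogSumExp(lN + f - u)
      Wn <- exp(sweep(sweep(-u, 2L, log_c), 1L, f, `+`))  # K x N, W[k,n]
      g <- n_k * (rowSums(Wn) - 1)
      # Hessian H_kl = delta_kl N_k sum_n W_kn - N_k N_l sum_n W_kn W_ln
      H <- diag(n_k * rowSums(Wn), K) - (Wn * n_k) %*% t(Wn * n_k)
      step <- tryCatch(
        solve(H[-1, -1, drop = FALSE], -g[-1]),
        error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) {
        f_try <- f
        f_try[-1] <- f_try[-1] + step
        log_c2 <- .colLogSumExp(lN + f_try - u)
        f_chk <- -.rowLogSumExp(sweep(-u, 2L, log_c2))
        f_chk <- f_chk - f_chk[1]
        if (max(abs(f_chk - f_try)) < resid) f <- f_try
      }
    }
  }
  log_c <- .colLogSumExp(lN + f - u)
  W <- t(exp(sweep(sweep(-u, 2L, log_c), 1L, f, `+`)))  # N x K, W[n,k]
  # asymptotic covariance (SVD form of the standard MBAR estimator)
  sv <- svd(W)
  S <- sv$d
  Vm <- sv$v
  inner <- diag(K) - (S * t(Vm)) %*% (n_k * Vm) %*% diag(S, K)
  inner_inv <- tryCatch(solve(inner), error = function(e) MASS_ginv(inner))
  theta <- Vm %*% diag(S, K) %*% inner_inv %*% diag(S, K) %*% t(Vm)
  se_f <- sqrt(pmax(diag(theta) + theta[1, 1] - 2 * theta[1, ], 0))
  # each state must share samples with at least one other state: the
  # diagnostic is the worst, over states, of the best off-diagonal entry of
  # the MBAR overlap matrix (well-spaced chains sit near 0.2-0.3, states
  # ~5 sigma apart fall to ~0.01)
  overlap <- t(W) %*% W %*% diag(n_k, K)
  off <- overlap
  diag(off) <- 0
  overlap_min <- min(apply(off, 1L, max))
  low_overlap <- overlap_min < overlap_threshold
  if (low_overlap)
    warning("poor phase-space overlap between states (min best-partner ",
            "overlap ", signif(overlap_min, 3), "); uncertainties inflated")
  structure(
    list(f = f, se_f = se_f, theta = theta, converged = converged,
         n_iterations = it, residual = resid,
         overlap_matrix = overlap, overlap_min = overlap_min,
         low_overlap = low_overlap,
         u = u, n_k = n_k),
    class = "mbar_result"
  )
}

# Moore-Penrose pseudo-inverse via SVD (tiny helper; avoids a MASS import)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.mbar_result <- function(x, ...) {
  cat(sprintf("<mbar_result> %d states, %d samples, %s in %d iterations\n",
              length(x$f), ncol(x$u),
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  cat("  f =", paste(signif(x$f, 4), collapse = " "), "\n")
  if (x$low_overlap) cat("  WARNING: low overlap between states\n")
  invisible(x)
}

#' Tidy an MBAR result
#'
#' @param x An `mbar_result`.
#' @param ... Unused.
#' @return Tibble with `state`, `f`, `se_f`, `n_samples`.
#' @method tidy mbar_result
#' @export
tidy.mbar_result <- function(x, ...) {
  tibble::tibble(state = seq_along(x$f), f = x$f, se_f = x$se_f,
                 n_samples = x$n_k)
}

#' Bennett acceptance ratio for two states
#'
#' Solves the two-state BAR self-consistency condition by bisection
#' (`uniroot`) on the forward and reverse reduced works. Serves as the
#' independent two-state cross-check of [mbar_solve()], to which it is
#' mathematically identical at K = 2.
#'
#' @param w_forward Reduced works `u_2(x) - u_1(x)` for samples from state 1.
#' @param w_reverse Reduced works `u_1(x) - u_2(x)` for samples from state 2.
#' @param tol Root-finding tolerance (default 1e-10).
#' @return List with `df` (reduced free-energy difference `f_2 - f_1`) and
#'   the sample counts.
#' @export
bar_solve <- function(w_forward, w_reverse, tol = 1e-10) {
  nf <- length(w_forward); nr <- length(w_reverse)
  stopifnot(nf > 0, nr > 0)
  M <- log(nf / nr)
  fermi <- function(x) 1 / (1 + exp(x))
  gfun <- function(df) {
    sum(fermi(M + w_forward - df)) - sum(fermi(-M + w_reverse + df))
  }
  lo <- min(-w_reverse, w_forward) - 50
  hi <- max(-w_reverse, w_forward) + 50
  root <- stats::uniroot(gfun, c(lo, hi), tol = tol)
  list(df = root$root, n_forward = nf, n_reverse = nr)
}

#' Reduced-energy matrix for umbrella windows
#'
#' Builds the MBAR input from biased trajectories: `u[k, n]` is the
#' harmonic window bias of window k evaluated at sample n, divided by kT.
#' The unbiased surface energy is a per-sample constant across states and
#' cancels exactly in the MBAR equations, so the estimator never sees the
#' surface that generated the samples — the reconstructed PMF is a genuine
#' inference from the biased samples alone.
#'
#' @param trajectories Output of [gen_biased_trajectories()] (or any tibble
#'   with `window`, `xi_pt`, `xi_at` and the same attributes).
#' @param windows Window table; defaults to `attr(trajectories, "windows")`.
#' @param kT Thermal energy, kcal/mol; defaults to
#'   `attr(trajectories, "kT")`.
#' @return List with `u` (K x N), `n_k`, `kT`, and the sample coordinates.
#' @export
umbrella_energy_matrix <- function(trajectories,
                                   windows = attr(trajectories, "windows"),
                                   kT = attr(trajectories, "kT")) {
  stopifnot(is.data.frame(trajectories), !is.null(windows), !is.null(kT))
  ord <- order(trajectories$window)
  x <- trajectories$xi_pt[ord]; y <- trajectories$xi_at[ord]
  n_k <- as.integer(table(factor(trajectories$window,
                                 levels = seq_len(nrow(windows)))))
  K <- nrow(windows)
  u <- matrix(0, K, length(x))
  for (k in seq_len(K)) {
    u[k, ] <- (0.5 * windows$k_pt[k] * (x - windows$center_pt[k])^2 +
                 0.5 * windows$k_at[k] * (y - windows$center_at[k])^2) / kT
  }
  list(u = u, n_k = n_k, kT = kT, xi_pt = x, xi_at = y)
}

#' Two-dimensional PMF by MBAR reweighting
#'
#' Reconstructs the unbiased free-energy surface over 2D bins from umbrella
#' samples: each sample is weighted by the MBAR mixture weight
#' `1 / sum_k N_k exp(f_k - u_k(x_n))`, weights are accumulated per bin, and
#' `G = -kT ln(weight)` is shifted so the occupied minimum is zero. Bins
#' containing no samples are masked (NA).
#'
#' @param mbar An `mbar_result` fitted on the umbrella energy matrix.
#' @param em The matching [umbrella_energy_matrix()] (source of sample
#'   coordinates, biases and kT).
#' @param bins Length-2 integer vector of bin counts (default c(40, 40)).
#' @param max_empty_frac Error when more than this fraction of bins inside
#'   the sampled bounding box is empty (default 0.5), which indicates
#'   windows too narrow or too sparse.
#' @return An `fe_pmf`: list with bin-center axes `axis_pt`, `axis_at`,
#'   matrix `values` (kcal/mol, NA in unsampled bins), and `kT`.
#' @export
pmf_2d <- function(mbar, em, bins = c(40L, 40L), max_empty_frac = 0.5) {
  stopifnot(inherits(mbar, "mbar_result"))
  if (!mbar$converged) warning("MBAR is not converged; PMF may be biased")
  x <- em$xi_pt; y <- em$xi_at
  log_c <- .colLogSumExp(log(mbar$n_k) + mbar$f - mbar$u)
  log_w <- -log_c
  bx <- seq(min(x), max(x), length.out = bins[1] + 1L)
  by <- seq(min(y), max(y), length.out = bins[2] + 1L)
  ix <- pmin(findInterval(x, bx, rightmost.closed = TRUE), bins[1])
  iy <- pmin(findInterval(y, by, rightmost.closed = TRUE), bins[2])
  Fm <- matrix(NA_real_, bins[1], bins[2])
  idx <- (iy - 1L) * bins[1] + ix
  for (b in unique(idx)) {
    Fm[b] <- -.logsumexp(log_w[idx == b])
  }
  empty_frac <- mean(is.na(Fm))
  if (empty_frac > max_empty_frac)
    stop(sprintf("%.0f%% of PMF bins are empty: widen the umbrella windows ",
                 100 * empty_frac),
         "or sample longer")
  G <- em$kT * (Fm - min(Fm, na.rm = TRUE))
  structure(
    list(axis_pt = (bx[-1] + bx[-length(bx)]) / 2,
         axis_at = (by[-1] + by[-length(by)]) / 2,
         values = G, kT = em$kT),
    class = "fe_pmf"
  )
}

#' @export
print.fe_pmf <- function(x, ...) {
  cat(sprintf("<fe_pmf> %d x %d bins, %.0f%% occupied, G max %.3g kcal/mol\n",
              length(x$axis_pt), length(x$axis_at),
              100 * mean(!is.na(x$values)), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @method tidy fe_pmf
#' @export
tidy.fe_pmf <- function(x, ...) {
  out <- tibble::tibble(
    xi_pt = rep(x$axis_pt, times = length(x$axis_at)),
    xi_at = rep(x$axis_at, each = length(x$axis_pt)),
    G = as.vector(x$values)
  )
  out[!is.na(out$G), ]
}

#' End-to-end alchemical free-energy difference
#'
#' Runs [mbar_solve()] over the lambda schedule of an alchemical dataset and
#' converts the end-state reduced free-energy difference to kcal/mol at the
#' dataset temperature. Chaining the result through [delta_pka_from_ddg()]
#' and [ribozyme_pka()] yields the calculated pKa of the general acid in the
#' ribozyme environment.
#'
#' @param ds An `alchemical_dataset` from [gen_alchemical_samples()].
#' @param ... Passed to [mbar_solve()].
#' @return Tibble with `ddg` (kcal/mol), `se` (kcal/mol), `n_windows`,
#'   `converged`, `low_overlap`.
#' @export
alchemical_ddg <- function(ds, ...) {
  stopifnot(inherits(ds, "alchemical_dataset"))
  res <- mbar_solve(ds$u, ds$n_k, ...)
  K <- length(res$f)
  se_end <- sqrt(max(res$theta[K, K] + res$theta[1, 1] - 2 * res$theta[1, K], 0))
  tibble::tibble(ddg = (res$f[K] - res$f[1]) * ds$kT,
                 se = se_end * ds$kT,
                 n_windows = K,
                 converged = res$converged,
                 low_overlap = res$low_overlap)
}
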