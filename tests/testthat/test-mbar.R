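test_that("MBAR is exact for identical states and gauge invariant", {
  set.seed(1)
  x <- rnorm(400)
  u <- rbind(x^2 / 2, x^2 / 2)
  m <- mbar_solve(u, c(200, 200))
  expect_identical(m$f[2], 0)
  expect_true(m$converged)
  # adding a constant to one state's energies shifts only that f
  ds <- gen_alchemical_samples(1.5, 4, 150, seed = 2)
  m1 <- mbar_solve(ds$u, ds$n_k)
  u2 <- ds$u
  u2[3, ] <- u2[3, ] + 7.5
  m2 <- mbar_solve(u2, ds$n_k)
  expect_equal(m2$f[3] - 7.5, m1$f[3], tolerance = 1e-10)
  expect_equal(m2$f[c(2, 4)], m1$f[c(2, 4)], tolerance = 1e-10)
})

test_that("two-state MBAR agrees with BAR to solver precision", {
  ds <- gen_alchemical_samples(1.5, 2, 500, overlap = 1.5, seed = 3)
  m <- mbar_solve(ds$u, ds$n_k)
  n <- ds$n_k[1]
  w_f <- ds$u[2, seq_len(n)] - ds$u[1, seq_len(n)]
  w_r <- ds$u[1, n + seq_len(n)] - ds$u[2, n + seq_len(n)]
  b <- bar_solve(w_f, w_r)
  expect_equal(m$f[2], b$df, tolerance = 1e-6)
})

test_that("two-window chain matches exponential averaging within 3 s.e.", {
  ds <- gen_alchemical_samples(0.8, 2, 2000, overlap = 2, seed = 4)
  est <- alchemical_ddg(ds)
  n <- ds$n_k[1]
  w_f <- ds$u[2, seq_len(n)] - ds$u[1, seq_len(n)]
  fep <- -log(mean(exp(-w_f))) * ds$kT   # free-energy perturbation
  expect_lt(abs(est$ddg - fep), 3 * est$se)
})

test_that("25-window alchemical chain recovers the known shift", {
  ds0 <- gen_alchemical_samples(0, 25, 200, seed = 5)
  e0 <- alchemical_ddg(ds0)
  expect_lt(abs(e0$ddg), 3 * e0$se)
  ds <- gen_alchemical_samples(2.86, 25, 200, seed = 6)
  e <- alchemical_ddg(ds)
  expect_lt(abs(e$ddg - 2.86), 3 * e$se)
  expect_false(e$low_overlap)
  # reversing the lambda schedule negates the estimate exactly
  dsr <- ds
  dsr$u <- ds$u[25:1, ]
  dsr$n_k <- ds$n_k[25:1]
  er <- alchemical_ddg(dsr)
  expect_equal(er$ddg, -e$ddg, tolerance = 1e-10)
})

test_that("poor phase-space overlap is flagged, not silently accepted", {
  expect_warning(
    m <- mbar_solve(gen_alchemical_samples(0, 5, 100, overlap = 0.15,
                                           seed = 7)$u, rep(100, 5)),
    "overlap")
  expect_true(m$low_overlap)
})

test_that("PMF reconstruction recovers an analytic harmonic surface", {
  kx <- 3; ky <- 5; kT <- 0.5924849
  s <- quadratic_bowl(kx = kx, ky = ky, spacing = 0.05)
  wg <- expand.grid(center_pt = seq(-1, 1, length.out = 5),
                    center_at = seq(-1, 1, length.out = 5))
  wg$k_pt <- 20; wg$k_at <- 20
  tr <- gen_biased_trajectories(s, wg, kT = kT, n_steps = 3000,
                                step_size = 5e-3, seed = 7)
  em <- umbrella_energy_matrix(tr)
  m <- mbar_solve(em$u, em$n_k)
  expect_true(m$converged)
  pm <- pmf_2d(m, em, bins = c(30, 30))
  truth <- outer(pm$axis_pt, pm$axis_at,
                 function(x, y) 0.5 * (kx * x^2 + ky * y^2))
  occ <- !is.na(pm$values)
  expect_gt(mean(occ), 0.5)
  dev <- pm$values[occ] - truth[occ]
  dev <- dev - mean(dev)  # PMFs are defined up to an additive constant
  expect_lt(sqrt(mean(dev^2)), 0.3)
  # occupied minimum is shifted to zero
  expect_equal(min(pm$values, na.rm = TRUE), 0)
})

test_that("single unbiased window on a flat potential gives a flat PMF", {
  ax <- seq(-3, 3, by = 0.1)
  s <- fe_surface(ax, ax, matrix(0, length(ax), length(ax)))
  w <- data.frame(center_pt = 0, center_at = 0, k_pt = 1e-9, k_at = 1e-9)
  tr <- gen_biased_trajectories(s, w, kT = 0.6, n_steps = 20000,
                                step_size = 0.05, seed = 8)
  em <- umbrella_energy_matrix(tr)
  # MBAR needs >= 2 states; duplicate the free window
  em$u <- rbind(em$u, em$u)
  m <- mbar_solve(em$u, c(nrow(tr) - nrow(tr) %/% 2, nrow(tr) %/% 2))
  pm <- pmf_2d(m, em, bins = c(6, 6))
  rng <- range(pm$values, na.rm = TRUE)
  expect_lt(diff(rng), 0.5)  # flat within sampling noise
})

test_that("sparse sampling of separated windows raises the empty-bin error", {
  s <- quadratic_bowl(kx = 1, ky = 1, spacing = 0.05)
  w <- data.frame(center_pt = c(-1.5, 1.5), center_at = c(-1.5, 1.5),
                  k_pt = 200, k_at = 200)
  tr <- gen_biased_trajectories(s, w, kT = 0.1, n_steps = 500,
                                step_size = 1e-3, seed = 9)
  em <- umbrella_energy_matrix(tr)
  m <- suppressWarnings(mbar_solve(em$u, em$n_k))
  expect_error(pmf_2d(m, em, bins = c(40, 40)), "empty")
})

test_that("PMF error shrinks with sample size", {
  kT <- 0.5924849
  s <- quadratic_bowl(kx = 3, ky = 3, spacing = 0.05)
  wg <- expand.grid(center_pt = seq(-0.8, 0.8, length.out = 4),
                    center_at = seq(-0.8, 0.8, length.out = 4))
  wg$k_pt <- 15; wg$k_at <- 15
  rms_at <- function(n_steps) {
    tr <- gen_biased_trajectories(s, wg, kT = kT, n_steps = n_steps,
                                  step_size = 5e-3, seed = 10)
    em <- umbrella_energy_matrix(tr)
    m <- mbar_solve(em$u, em$n_k)
    pm <- pmf_2d(m, em, bins = c(20, 20))
    truth <- outer(pm$axis_pt, pm$axis_at,
                   function(x, y) 1.5 * (x^2 + y^2))
    occ <- !is.na(pm$values)
    dev <- pm$values[occ] - truth[occ]
    dev <- dev - mean(dev)
    sqrt(mean(dev^2))
  }
  r1 <- rms_at(400)
  r2 <- rms_at(1600)
  expect_lt(r2, r1)
})
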