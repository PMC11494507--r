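test_that("bicubic interpolation is exact on quadratic surfaces", {
  s <- quadratic_bowl(kx = 4, ky = 6)
  # grid nodes return stored values
  g <- fes_interpolate(s, cbind(s$axis_pt[7], s$axis_at[13]))
  expect_equal(g$G, s$values[7, 13], tolerance = 1e-12)
  # off-node points: value and analytic gradient to 1e-6
  set.seed(42)
  pts <- cbind(runif(50, -2.3, 2.3), runif(50, -2.3, 2.3))
  gi <- fes_interpolate(s, pts)
  expect_equal(gi$G, 0.5 * (4 * pts[, 1]^2 + 6 * pts[, 2]^2),
               tolerance = 1e-6)
  expect_equal(gi$dG_dpt, 4 * pts[, 1], tolerance = 1e-6)
  expect_equal(gi$dG_dat, 6 * pts[, 2], tolerance = 1e-6)
  # gradient vanishes at the symmetry center
  g0 <- fes_interpolate(s, c(0, 0))
  expect_equal(c(g0$dG_dpt, g0$dG_dat), c(0, 0), tolerance = 1e-12)
  expect_error(fes_interpolate(s, c(5, 0)), "outside")
})

test_that("grid file format round-trips exactly", {
  s <- gen_surface(two_well(-1, -1, -5, 0.6, 0.6, 1, 1, -4, 0.5, 0.8),
                   extent_pt = c(-2, 2), extent_at = c(-2, 2), spacing = 0.1)
  path <- withr::local_tempfile(fileext = ".dat")
  write_fes_grid(s, path)
  s2 <- read_fes_grid(path)
  expect_equal(s2$axis_pt, s$axis_pt, tolerance = 1e-12)
  expect_equal(s2$values, s$values, tolerance = 1e-11)
  # a second write reproduces the text byte for byte
  path2 <- withr::local_tempfile(fileext = ".dat")
  write_fes_grid(s2, path2)
  expect_identical(readLines(path), readLines(path2))
  expect_match(readLines(path)[3], "kcal/mol Angstrom")
})

test_that("gen_surface validates input and honors symmetry", {
  expect_error(gen_surface(two_well()), "empty")
  expect_warning(
    gen_surface(two_well(9, 9, -1, 0.5, 0.5, 0, 0, -1, 0.5, 0.5),
                extent_pt = c(-2, 2), extent_at = c(-2, 2), spacing = 0.1),
    "outside")
  # single bowl: minimum at its center with G = 0
  s <- gen_surface(two_well(0, 0, -3, 0.5, 0.5), extent_pt = c(-2, 2),
                   extent_at = c(-2, 2), spacing = 0.05)
  expect_equal(min(s$values), 0)
  idx <- which(s$values == 0, arr.ind = TRUE)
  expect_equal(c(s$axis_pt[idx[1]], s$axis_at[idx[2]]), c(0, 0))
  # point reflection: negating all centers reflects the surface
  comps <- two_well(-1, -0.5, -4, 0.5, 0.7, 0.8, 1.1, -2, 0.6, 0.4)
  s1 <- gen_surface(comps, extent_pt = c(-3, 3), extent_at = c(-3, 3),
                    spacing = 0.1)
  comps2 <- comps
  comps2$center_pt <- -comps2$center_pt
  comps2$center_at <- -comps2$center_at
  s2 <- gen_surface(comps2, extent_pt = c(-3, 3), extent_at = c(-3, 3),
                    spacing = 0.1, reactant = c(1, 0.5))
  expect_equal(s2$values, s1$values[rev(seq_along(s1$axis_pt)),
                                    rev(seq_along(s1$axis_at))],
               tolerance = 1e-10)
})

test_that("MTR1-like preset is calibrated to the requested barrier", {
  s <- mtr1_surface(barrier = 16.3)
  basins <- attr(s, "basins")
  mb <- minimax_barrier(s, basins$R, basins$P)
  expect_equal(mb$barrier, 16.3, tolerance = 0.05 / 16.3)  # grid resolution
  expect_lt(abs(mb$saddle[1, "xi_at"] - (-0.24)), 0.03)
  # a different requested barrier rescales the whole landscape
  s2 <- mtr1_surface(barrier = 30.3)
  mb2 <- minimax_barrier(s2, basins$R, basins$P)
  expect_equal(mb2$barrier, 30.3, tolerance = 0.1 / 30.3)
})

test_that("string on a quadratic bowl stays on the straight diameter", {
  s <- quadratic_bowl(kx = 2, ky = 2, spacing = 0.05)
  p <- string_mfep(s, c(-1.5, -1.5), c(1.5, 1.5), snap_endpoints = FALSE,
                   until_converged = TRUE, tol = 1e-8)
  # max perpendicular deviation from the diameter
  dev <- abs(p$images[, 1] - p$images[, 2]) / sqrt(2)
  expect_lt(max(dev), 1e-6)
  pr <- profile_along_path(s, p)
  expect_equal(sum(grepl("^TS", pr$states$label)), 0)
  expect_equal(min(pr$profile$G), 0, tolerance = 1e-8)
})

test_that("string barrier matches the minimax grid oracle on two-well surfaces", {
  for (cs in oracle_surfaces()) {
    mb <- minimax_barrier(cs$surface, cs$start, cs$end)
    p <- string_mfep(cs$surface, cs$start, cs$end, until_converged = TRUE)
    pr <- profile_along_path(cs$surface, p)
    expect_lt(abs(pr$rate_controlling_barrier - mb$barrier) / mb$barrier,
              0.01)
  }
})

test_that("equal-arc-length spacing holds on the converged string", {
  cs <- oracle_surfaces()$asymmetric
  p <- string_mfep(cs$surface, cs$start, cs$end, until_converged = TRUE)
  seg <- sqrt(rowSums(diff(p$images)^2))
  total <- sum(seg)
  expect_lt(max(abs(seg - mean(seg))) / total, 1e-6)
  expect_true(all(diff(p$arc_parameter) > 0))
})

test_that("profile of the reversed path mirrors the forward profile", {
  cs <- oracle_surfaces()$diagonal
  p <- string_mfep(cs$surface, cs$start, cs$end, until_converged = TRUE)
  pf <- profile_along_path(cs$surface, p)
  pr <- p
  pr$images <- p$images[rev(seq_len(p$n_images)), ]
  pb <- profile_along_path(cs$surface, pr)
  expect_equal(pb$profile$G, rev(pf$profile$G), tolerance = 1e-9)
  expect_equal(pb$rate_controlling_barrier, pf$rate_controlling_barrier,
               tolerance = 1e-9)
})

test_that("transition-state coordinates respect symmetry and translation", {
  # symmetric double well along xi_PT: TS at the symmetry coordinate
  comps <- two_well(-1, 0, -5, 0.5, 0.5, 1, 0, -5, 0.5, 0.5)
  s <- gen_surface(comps, extent_pt = c(-3, 3), extent_at = c(-2, 2),
                   spacing = 0.04)
  p <- string_mfep(s, c(-1, 0), c(1, 0), until_converged = TRUE)
  ts <- ts_coordinates(profile_along_path(s, p))
  expect_equal(nrow(ts), 1L)
  expect_equal(ts$xi_pt, 0, tolerance = 0.02)
  # shifting the surface by +delta in xi_AT shifts the TS by +delta
  delta <- 0.6
  comps2 <- comps
  comps2$center_at <- comps2$center_at + delta
  s2 <- gen_surface(comps2, extent_pt = c(-3, 3), extent_at = c(-2, 2),
                    spacing = 0.04, reactant = c(-1, delta))
  p2 <- string_mfep(s2, c(-1, delta), c(1, delta), until_converged = TRUE)
  ts2 <- ts_coordinates(profile_along_path(s2, p2))
  expect_equal(ts2$xi_at, ts$xi_at + delta, tolerance = 0.02)
})

test_that("preset reaction path visits R, I, P in order with TS2 rate-controlling", {
  s <- mtr1_surface(barrier = 16.3)
  basins <- attr(s, "basins")
  p <- string_mfep(s, basins$R, basins$P, until_converged = TRUE,
                   waypoints = rbind(basins$I))
  pr <- profile_along_path(s, p)
  expect_identical(pr$states$label, c("R", "TS1", "I", "TS2", "P"))
  expect_equal(pr$states$G[pr$states$label == "R"], 0)
  expect_equal(pr$rate_controlling_barrier, 16.3, tolerance = 0.005)
  ts <- ts_coordinates(pr)
  rate_ctrl <- ts[which.max(ts$G), ]
  # the rate-controlling saddle is the "early" alkyl-transfer TS
  expect_lt(abs(rate_ctrl$xi_at - (-0.24)), 0.025)
  expect_lt(ts$G[ts$label == "TS1"], ts$G[ts$label == "TS2"])
})

test_that("non-converged paths and missing transition states are flagged", {
  cs <- oracle_surfaces()$asymmetric
  p1 <- string_mfep(cs$surface, cs$start, cs$end, max_iter = 1L)
  expect_false(p1$converged)
  expect_warning(profile_along_path(cs$surface, p1), "not converged")
  # monotone bowl profile: no TS to report
  s <- quadratic_bowl(spacing = 0.05)
  pb <- string_mfep(s, c(-1, -1), c(1, 1), snap_endpoints = FALSE,
                    until_converged = TRUE)
  prb <- profile_along_path(s, pb)
  expect_message(ts_coordinates(prb), "no transition state")
})
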