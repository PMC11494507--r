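# Shared fixtures, all generated in code.

two_well <- function(...) {
  tibble::tribble(~center_pt, ~center_at, ~depth, ~width_pt, ~width_at, ...)
}

# Analytic two-well test surfaces with well-localized saddles, used for the
# string-vs-minimax oracle comparisons.
oracle_surfaces <- function(spacing = 0.04) {
  list(
    diagonal = list(
      surface = gen_surface(
        two_well(-1, -1, -5, 0.6, 0.6, 1, 1, -5, 0.6, 0.6),
        extent_pt = c(-3, 3), extent_at = c(-3, 3), spacing = spacing),
      start = c(-1, -1), end = c(1, 1)),
    asymmetric = list(
      surface = gen_surface(
        two_well(-1.2, -0.5, -6, 0.5, 0.7, 1.0, 0.8, -4, 0.8, 0.5),
        extent_pt = c(-3, 3), extent_at = c(-3, 3), spacing = spacing),
      start = c(-1.2, -0.5), end = c(1.0, 0.8)),
    bump = list(
      surface = gen_surface(
        two_well(-1.1, -0.9, -5, 0.55, 0.7, 1.2, 0.9, -4.5, 0.7, 0.55,
                 0.3, -0.1, 2.5, 0.45, 0.45),
        extent_pt = c(-3, 3), extent_at = c(-3, 3), spacing = spacing),
      start = c(-1.1, -0.9), end = c(1.2, 0.9))
  )
}

# Quadratic bowl stored on a grid: the interpolant reproduces it exactly.
quadratic_bowl <- function(kx = 2, ky = 3, spacing = 0.1, extent = 2.5) {
  ax <- seq(-extent, extent, by = spacing)
  fe_surface(ax, ax, outer(ax, ax, function(x, y) 0.5 * (kx * x^2 + ky * y^2)))
}

# Canonical biphasic sampling schedule: dense around the fast half-life
# (~1 min), extended far enough that the slow (0.01 /min) phase is observed.
biphasic_schedule <- function() {
  c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 7, 10, 15, 25, 40, 60, 90, 120, 160, 200,
    250, 300)
}

RT298 <- 1.98720425e-3 * 298.15
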