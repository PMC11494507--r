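#' Gridded two-dimensional free-energy surface
#'
#' Container for a free energy G(xi_PT, xi_AT) tabulated on a uniform grid.
#' The coordinates are the difference-of-distances reaction coordinates for
#' proton transfer (xi_PT) and alkyl transfer (xi_AT), in Angstrom; energies
#' are in kcal/mol. By convention the reactant-basin minimum is shifted to 0
#' by the generators (the constructor itself stores values as given).
#'
#' @param axis_pt,axis_at Strictly increasing, uniformly spaced grid vectors
#'   (Angstrom).
#' @param values Matrix of G values, `length(axis_pt)` rows by
#'   `length(axis_at)` columns, kcal/mol. All finite.
#' @return An `fe_surface` object.
#' @export
fe_surface <- function(axis_pt, axis_at, values) {
  stopifnot(is.numeric(axis_pt), is.numeric(axis_at), is.matrix(values))
  if (length(axis_pt) < 2L || length(axis_at) < 2L)
    stop("each axis needs at least 2 points")
  if (nrow(values) != length(axis_pt) || ncol(values) != length(axis_at))
    stop("values must be length(axis_pt) x length(axis_at)")
  if (!all(is.finite(values))) stop("surface values must be finite")
  check_uniform <- function(ax, nm) {
    d <- diff(ax)
    if (any(d <= 0)) stop(nm, " must be strictly increasing")
    if (max(abs(d - d[1])) > 1e-8 * abs(d[1])) stop(nm, " must be uniform")
  }
  check_uniform(axis_pt, "axis_pt")
  check_uniform(axis_at, "axis_at")
  s <- structure(
    list(axis_pt = as.numeric(axis_pt), axis_at = as.numeric(axis_at),
         values = values),
    class = "fe_surface"
  )
  s$padded <- .pad_grid(values)
  s
}

# Ghost layer by quadratic extrapolation so the Catmull-Rom stencil is
# defined in every cell (keeps exactness on quadratics up to the boundary).
.pad_grid <- function(v) {
  n <- nrow(v); m <- ncol(v)
  p <- matrix(0, n + 2L, m + 2L)
  p[2:(n + 1L), 2:(m + 1L)] <- v
  p[1L, ] <- 3 * p[2L, ] - 3 * p[3L, ] + p[4L, ]
  p[n + 2L, ] <- 3 * p[n + 1L, ] - 3 * p[n, ] + p[n - 1L, ]
  p[, 1L] <- 3 * p[, 2L] - 3 * p[, 3L] + p[, 4L]
  p[, m + 2L] <- 3 * p[, m + 1L] - 3 * p[, m] + p[, m - 1L]
  p
}

#' @export
print.fe_surface <- function(x, ...) {
  cat(sprintf(
    "<fe_surface> %d x %d grid, xi_PT [%g, %g] A, xi_AT [%g, %g] A, G range [%.3g, %.3g] kcal/mol\n",
    length(x$axis_pt), length(x$axis_at),
    min(x$axis_pt), max(x$axis_pt), min(x$axis_at), max(x$axis_at),
    min(x$values), max(x$values)))
  invisible(x)
}

#' Tidy a free-energy surface into a long tibble
#'
#' @param x An [fe_surface()].
#' @param ... Unused.
#' @return Tibble with columns `xi_pt`, `xi_at`, `G`.
#' @method tidy fe_surface
#' @export
tidy.fe_surface <- function(x, ...) {
  tibble::tibble(
    xi_pt = rep(x$axis_pt, times = length(x$axis_at)),
    xi_at = rep(x$axis_at, each = length(x$axis_pt)),
    G = as.vector(x$values)
  )
}

# Catmull-Rom basis weights and derivative weights at fractional position t.
.cr_w <- function(t) {
  cbind(0.5 * (-t^3 + 2 * t^2 - t),
        0.5 * (3 * t^3 - 5 * t^2 + 2),
        0.5 * (-3 * t^3 + 4 * t^2 + t),
        0.5 * (t^3 - t^2))
}
.cr_dw <- function(t) {
  cbind(0.5 * (-3 * t^2 + 4 * t - 1),
        0.5 * (9 * t^2 - 10 * t),
        0.5 * (-9 * t^2 + 8 * t + 1),
        0.5 * (3 * t^2 - 2 * t))
}

#' Interpolate a free-energy surface
#'
#' C1-continuous bicubic (Catmull-Rom tensor-product) interpolation with
#' analytic gradients. Exact for surfaces that are polynomials of total
#' degree <= 2 in each coordinate.
#'
#' @param surface An [fe_surface()].
#' @param points Numeric matrix (n x 2) or length-2 vector of
#'   (xi_PT, xi_AT) query points, all inside the grid hull.
#' @param gradient Return analytic gradients as well? Default TRUE.
#' @return Tibble with columns `xi_pt`, `xi_at`, `G` and, if requested,
#'   `dG_dpt`, `dG_dat` (kcal/mol/Angstrom).
#' @export
fes_interpolate <- function(surface, points, gradient = TRUE) {
  stopifnot(inherits(surface, "fe_surface"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L, byrow = TRUE)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L)
  ax <- surface$axis_pt; ay <- surface$axis_at
  hx <- ax[2] - ax[1]; hy <- ay[2] - ay[1]
  out_x <- points[, 1] < ax[1] - 1e-12 | points[, 1] > ax[length(ax)] + 1e-12
  out_y <- points[, 2] < ay[1] - 1e-12 | points[, 2] > ay[length(ay)] + 1e-12
  if (any(out_x | out_y)) {
    bad <- which(out_x | out_y)[1]
    stop(sprintf("point (%g, %g) lies outside the grid hull",
                 points[bad, 1], points[bad, 2]))
  }
  ix <- pmin(pmax(floor((points[, 1] - ax[1]) / hx), 0), length(ax) - 2L)
  iy <- pmin(pmax(floor((points[, 2] - ay[1]) / hy), 0), length(ay) - 2L)
  tx <- (points[, 1] - (ax[1] + ix * hx)) / hx
  ty <- (points[, 2] - (ay[1] + iy * hy)) / hy
  wx <- .cr_w(tx); wy <- .cr_w(ty)
  P <- surface$padded
  np <- nrow(P)
  # padded index of stencil corner: grid node ix (0-based) -> padded row ix+1
  G <- numeric(nrow(points))
  Gx <- Gy <- if (gradient) numeric(nrow(points)) else NULL
  dwx <- if (gradient) .cr_dw(tx) else NULL
  dwy <- if (gradient) .cr_dw(ty) else NULL
  for (a in 1:4) {
    rowi <- ix + a  # padded row index (1-based): (ix - 1) + a + 1
    # inner sum over b for all points at once
    sy <- syd <- 0
    for (b in 1:4) {
      coli <- iy + b
      f <- P[rowi + (coli - 1L) * np]
      sy <- sy + wy[, b] * f
      if (gradient) syd <- syd + dwy[, b] * f
    }
    G <- G + wx[, a] * sy
    if (gradient) {
      Gx <- Gx + dwx[, a] * sy
      Gy <- Gy + wx[, a] * syd
    }
  }
  res <- tibble::tibble(xi_pt = points[, 1], xi_at = points[, 2], G = G)
  if (gradient) {
    res$dG_dpt <- Gx / hx
    res$dG_dat <- Gy / hy
  }
  res
}

# Fast scalar interpolation for hot loops: returns c(G, dG_dpt, dG_dat)
# without tibble overhead. No hull check (caller clips).
.fes_point <- function(surface, x, y) {
  ax <- surface$axis_pt; ay <- surface$axis_at
  hx <- ax[2] - ax[1]; hy <- ay[2] - ay[1]
  ix <- min(max(floor((x - ax[1]) / hx), 0), length(ax) - 2L)
  iy <- min(max(floor((y - ay[1]) / hy), 0), length(ay) - 2L)
  tx <- (x - (ax[1] + ix * hx)) / hx
  ty <- (y - (ay[1] + iy * hy)) / hy
  wx <- .cr_w(tx); wy <- .cr_w(ty)
  dwx <- .cr_dw(tx); dwy <- .cr_dw(ty)
  F4 <- surface$padded[ix + (1:4), iy + (1:4), drop = FALSE]
  sy <- as.vector(F4 %*% t(wy))
  syd <- as.vector(F4 %*% t(dwy))
  c(G = sum(wx * sy), dG_dpt = sum(dwx * sy) / hx, dG_dat = sum(wx * syd) / hy)
}

#' Write / read the plain-text surface grid format
#'
#' Three header lines (`# axis_pt: start stop n`, `# axis_at: start stop n`,
#' `# units: kcal/mol Angstrom`) followed by the values in row-major order
#' (one row per xi_PT node, columns over xi_AT), printed at 12 significant
#' digits so a write/read cycle reproduces the text exactly.
#'
#' @param surface An [fe_surface()].
#' @param path File path.
#' @return `write_fes_grid` returns `path` invisibly; `read_fes_grid` an
#'   [fe_surface()].
#' @export
write_fes_grid <- function(surface, path) {
  stopifnot(inherits(surface, "fe_surface"))
  ax <- surface$axis_pt; ay <- surface$axis_at
  hdr <- c(
    sprintf("# axis_pt: %.12g %.12g %d", ax[1], ax[length(ax)], length(ax)),
    sprintf("# axis_at: %.12g %.12g %d", ay[1], ay[length(ay)], length(ay)),
    "# units: kcal/mol Angstrom"
  )
  rows <- apply(surface$values, 1L,
                function(r) paste(sprintf("%.12g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_fes_grid
#' @export
read_fes_grid <- function(path) {
  lines <- readLines(path)
  parse_axis <- function(line, key) {
    if (!startsWith(line, paste0("# ", key, ":")))
      stop("malformed grid header: expected '# ", key, ": start stop n'")
    f <- strsplit(sub(paste0("# ", key, ": *"), "", line), " +")[[1]]
    seq(as.numeric(f[1]), as.numeric(f[2]), length.out = as.integer(f[3]))
  }
  ax <- parse_axis(lines[1], "axis_pt")
  ay <- parse_axis(lines[2], "axis_at")
  vals <- do.call(rbind, lapply(lines[-(1:3)], function(l)
    as.numeric(strsplit(trimws(l), " +")[[1]])))
  fe_surface(ax, ay, vals)
}

# Steepest grid descent from the node nearest `point` to a local minimum.
# Returns list(index = c(i, j), value).
.grid_descend <- function(surface, point) {
  v <- surface$values
  n <- nrow(v); m <- ncol(v)
  i <- which.min(abs(surface$axis_pt - point[1]))
  j <- which.min(abs(surface$axis_at - point[2]))
  repeat {
    ii <- max(1L, i - 1L):min(n, i + 1L)
    jj <- max(1L, j - 1L):min(m, j + 1L)
    nb <- v[ii, jj, drop = FALSE]
    k <- arrayInd(which.min(nb), dim(nb))
    bi <- ii[k[1]]; bj <- jj[k[2]]
    if (v[bi, bj] >= v[i, j] - 0) {
      if (bi == i && bj == j) break
      if (v[bi, bj] >= v[i, j]) break
    }
    i <- bi; j <- bj
  }
  list(index = c(i, j), value = v[i, j],
       point = c(surface$axis_pt[i], surface$axis_at[j]))
}

# 8-connected flood fill restricted to `allowed` cells; returns reach mask.
.reach_mask <- function(allowed, start_idx) {
  n <- nrow(allowed); m <- ncol(allowed)
  reach <- matrix(FALSE, n, m)
  if (!allowed[start_idx[1], start_idx[2]]) return(reach)
  reach[start_idx[1], start_idx[2]] <- TRUE
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-n, ]
    grown[-n, ] <- grown[-n, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -m]
    grown[, -m] <- grown[, -m] | reach[, -1]
    grown[-1, -1] <- grown[-1, -1] | reach[-n, -m]
    grown[-n, -m] <- grown[-n, -m] | reach[-1, -1]
    grown[-1, -m] <- grown[-1, -m] | reach[-n, -1]
    grown[-n, -1] <- grown[-n, -1] | reach[-1, -m]
    grown <- grown & allowed
    if (identical(grown, reach)) return(reach)
    reach <- grown
  }
}

.connected <- function(allowed, start_idx, end_idx) {
  r <- .reach_mask(allowed, start_idx)
  r[end_idx[1], end_idx[2]]
}

# Dilate a logical mask by one 8-connected step.
.dilate8 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  g <- x
  g[-1, ] <- g[-1, ] | x[-n, ]
  g[-n, ] <- g[-n, ] | x[-1, ]
  g[, -1] <- g[, -1] | x[, -m]
  g[, -m] <- g[, -m] | x[, -1]
  g[-1, -1] <- g[-1, -1] | x[-n, -m]
  g[-n, -m] <- g[-n, -m] | x[-1, -1]
  g[-1, -m] <- g[-1, -m] | x[-n, -1]
  g[-n, -1] <- g[-n, -1] | x[-1, -m]
  g
}

#' Minimax barrier between two basins by exhaustive grid search
#'
#' Finds the lowest energy level at which the two basins become connected on
#' the 8-connected grid (binary search over grid levels with flood fill;
#' equivalent to a minimax Dijkstra over grid cells). This is the brute-force
#' oracle against which the string-method barrier is validated: the minimax
#' level is the energy of the rate-controlling saddle, and the barrier is
#' that level minus the starting-basin minimum.
#'
#' @param surface An [fe_surface()].
#' @param start,end Approximate (xi_PT, xi_AT) positions of the two basins;
#'   each is refined to its local grid minimum first.
#' @return List with `barrier` (kcal/mol above the start-basin minimum),
#'   `threshold` (absolute saddle level), `start_min`, `end_min` (refined
#'   basin minima as point/value lists), and `saddle` — a matrix of grid
#'   points at the bottleneck level.
#' @export
minimax_barrier <- function(surface, start, end) {
  stopifnot(inherits(surface, "fe_surface"))
  v <- surface$values
  s <- .grid_descend(surface, start)
  e <- .grid_descend(surface, end)
  levels <- sort(unique(as.vector(v)))
  lo <- 1L; hi <- length(levels)
  # invariant: connected at levels[hi], not connected at levels[lo] (unless
  # already connected at the lowest level containing both minima)
  if (.connected(v <= levels[lo], s$index, e$index)) {
    thr <- levels[lo]
  } else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (.connected(v <= levels[mid], s$index, e$index)) hi <- mid else lo <- mid
    }
    thr <- levels[hi]
  }
  # bottleneck cells: threshold-level cells adjacent to both strictly
  # sub-threshold components (the rate-controlling saddle region)
  below <- v < thr
  rs <- .reach_mask(below, s$index)
  re <- .reach_mask(below, e$index)
  bottleneck <- (v == thr) & .dilate8(rs) & .dilate8(re)
  if (!any(bottleneck)) bottleneck <- v == thr  # degenerate flat threshold
  sad_idx <- which(bottleneck, arr.ind = TRUE)
  saddle <- cbind(xi_pt = surface$axis_pt[sad_idx[, 1]],
                  xi_at = surface$axis_at[sad_idx[, 2]])
  list(barrier = thr - s$value, threshold = thr,
       start_min = s, end_min = e, saddle = saddle)
}
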