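# Maximum and mean interpolated energy along a spline refinement of the
# image polyline. The maximum is the step-control quantity (genuine descent
# never raises the ridge-crossing level); the mean is the stagnation
# quantity (it keeps improving while any part of the path still descends,
# even when the maximum is pinned at an endpoint).
.dense_path_stats <- function(surface, z, refine = 4L) {
  arc <- c(0, cumsum(sqrt(rowSums(diff(z)^2))))
  if (arc[length(arc)] == 0) {
    g <- .fes_point(surface, z[1, 1], z[1, 2])[1]
    return(c(max = g, mean = g))
  }
  sd_ <- seq(0, arc[length(arc)], length.out = refine * (nrow(z) - 1L) + 1L)
  x <- stats::spline(arc, z[, 1], xout = sd_, method = "natural", ties = "ordered")$y
  y <- stats::spline(arc, z[, 2], xout = sd_, method = "natural", ties = "ordered")$y
  x <- pmin(pmax(x, min(surface$axis_pt)), max(surface$axis_pt))
  y <- pmin(pmax(y, min(surface$axis_at)), max(surface$axis_at))
  g <- fes_interpolate(surface, cbind(x, y), gradient = FALSE)$G
  c(max = max(g), mean = mean(g))
}

# Equal-arc-length reparameterization (n x 2 matrix): cubic-spline
# interpolation of the image curve against chord arc length, resampled at
# uniform arc. Spline (rather than piecewise-linear) resampling avoids the
# systematic corner-cutting drift of linear interpolation on curved paths.
.reparam_equal_arc <- function(z, passes = 4L) {
  for (p in seq_len(passes)) {
    seg <- sqrt(rowSums(diff(z)^2))
    arc <- c(0, cumsum(seg))
    total <- arc[length(arc)]
    if (total == 0) return(z)
    if (max(abs(seg - mean(seg))) < 1e-8 * total) break
    s_new <- seq(0, total, length.out = nrow(z))
    z <- cbind(stats::spline(arc, z[, 1], xout = s_new, method = "natural",
                             ties = "ordered")$y,
               stats::spline(arc, z[, 2], xout = s_new, method = "natural",
                             ties = "ordered")$y)
  }
  z
}

# Descend from `point` to the nearest local minimum of the interpolated
# surface (simple gradient descent with backtracking).
.descend_to_minimum <- function(surface, point, max_iter = 500L) {
  ax <- range(surface$axis_pt); ay <- range(surface$axis_at)
  clip <- function(p) c(min(max(p[1], ax[1]), ax[2]), min(max(p[2], ay[1]), ay[2]))
  p <- clip(point)
  g0 <- .fes_point(surface, p[1], p[2])
  step <- 0.1
  for (i in seq_len(max_iter)) {
    g <- g0[2:3]
    gn <- sqrt(sum(g^2))
    if (gn < 1e-10) break
    moved <- FALSE
    for (h in 0:20) {
      cand <- clip(p - (step / 2^h) * g / max(gn, 1))
      gc <- .fes_point(surface, cand[1], cand[2])
      if (gc[1] < g0[1]) { p <- cand; g0 <- gc; moved <- TRUE; break }
    }
    if (!moved) break
  }
  list(point = p, value = unname(g0[1]))
}

#' Minimum free-energy path by the string method
#'
#' Relaxes a discretized path (a "string" of images) toward the minimum
#' free-energy path on a 2D surface: starting from the straight segment
#' between the two basins, each interior image moves downhill along the
#' component of the interpolated gradient perpendicular to the path tangent
#' (central-difference tangents), after which the images are redistributed
#' to equal arc length. Endpoints stay fixed at the basin minima. The
#' default discretization (32 images) and iteration count (30) mirror the
#' surface-accelerated string protocol used for MTR1; set
#' `until_converged = TRUE` to continue until the maximum image displacement
#' falls below `tol`.
#'
#' @param surface An [fe_surface()].
#' @param start,end Approximate (xi_PT, xi_AT) reactant and product
#'   positions, e.g. c(-1.5, -2.5) and c(1.5, 2.5).
#' @param n_images Number of images along the string (default 32).
#' @param max_iter Iteration budget (default 30).
#' @param step Initial trust radius for image moves, Angstrom (default 0.05);
#'   halved automatically when more than half the images would move uphill,
#'   with an error after 10 halvings.
#' @param tol Convergence threshold on the maximum image displacement per
#'   iteration, Angstrom (default 1e-4).
#' @param snap_endpoints Refine `start`/`end` to their local minima before
#'   iterating (default TRUE; the given positions are treated as approximate
#'   basin anchors).
#' @param waypoints Optional matrix of intermediate (xi_PT, xi_AT) anchors
#'   (e.g. a known metastable intermediate); the initial guess is then the
#'   piecewise-linear path through them, which avoids corner-cutting into a
#'   locally stable detour on strongly bent reaction paths. Default NULL
#'   (straight segment).
#' @param until_converged Continue past `max_iter` (up to 2000 iterations)
#'   until `tol` is met. Default FALSE.
#' @return A `path_string` object: list with `images` (n x 2 matrix),
#'   `arc_parameter` (normalized [0,1]), `converged`, `iterations_run`,
#'   `surface`.
#' @export
string_mfep <- function(surface, start, end, n_images = 32L, max_iter = 30L,
                        step = 0.05, tol = 1e-4, snap_endpoints = TRUE,
                        until_converged = FALSE, waypoints = NULL) {
  stopifnot(inherits(surface, "fe_surface"), n_images >= 3L)
  axr <- range(surface$axis_pt); ayr <- range(surface$axis_at)
  inside <- function(p) p[1] >= axr[1] && p[1] <= axr[2] &&
    p[2] >= ayr[1] && p[2] <= ayr[2]
  if (!inside(start) || !inside(end))
    stop("start and end must lie inside the grid")
  if (snap_endpoints) {
    start <- .descend_to_minimum(surface, start)$point
    end <- .descend_to_minimum(surface, end)$point
  }
  anchors <- rbind(start, if (!is.null(waypoints)) as.matrix(waypoints), end)
  seg_len <- sqrt(rowSums(diff(anchors)^2))
  arc_anchor <- c(0, cumsum(seg_len))
  s_init <- seq(0, arc_anchor[length(arc_anchor)], length.out = n_images)
  z <- cbind(stats::approx(arc_anchor, anchors[, 1], xout = s_init,
                           ties = "ordered")$y,
             stats::approx(arc_anchor, anchors[, 2], xout = s_init,
                           ties = "ordered")$y)
  # deterministic transverse bow of one grid spacing: breaks the symmetry
  # trap where the straight segment is an unstable stationary path (e.g. a
  # bump centered exactly on the line)
  chord <- c(end[1] - start[1], end[2] - start[2])
  nrm <- sqrt(sum(chord^2))
  if (nrm > 0 && is.null(waypoints)) {
    perp <- c(-chord[2], chord[1]) / nrm
    amp <- surface$axis_pt[2] - surface$axis_pt[1]
    svec <- seq(0, 1, length.out = n_images)
    z <- z + outer(amp * sin(pi * svec), perp)
  }
  z[, 1] <- pmin(pmax(z[, 1], axr[1]), axr[2])
  z[, 2] <- pmin(pmax(z[, 2], ayr[1]), ayr[2])
  z <- .reparam_equal_arc(z)
  clip2 <- function(m) {
    m[, 1] <- pmin(pmax(m[, 1], axr[1]), axr[2])
    m[, 2] <- pmin(pmax(m[, 2], ayr[1]), ayr[2])
    m
  }
  interior <- 2:(n_images - 1L)
  budget <- if (until_converged) max(max_iter, 2000L) else max_iter
  dt <- NULL
  converged <- FALSE
  iterations <- 0L
  best_max <- Inf
  best_mean <- Inf
  best_disp <- Inf
  stall <- 0L
  for (it in seq_len(budget)) {
    iterations <- it
    gi <- fes_interpolate(surface, z)
    grad <- cbind(gi$dG_dpt, gi$dG_dat)
    tang <- rbind(z[2, ] - z[1, ],
                  z[interior + 1L, ] - z[interior - 1L, ],
                  z[n_images, ] - z[n_images - 1L, ])
    tn <- sqrt(rowSums(tang^2)); tn[tn == 0] <- 1
    tang <- tang / tn
    gperp <- grad - tang * rowSums(grad * tang)
    if (is.null(dt)) {
      # scale by the full gradient, not just its perpendicular part, so a
      # path that starts on the MFEP (gperp ~ 0) gets a finite time step
      gmax <- max(sqrt(rowSums(grad^2)), 1e-8)
      dt0 <- step / gmax
      dt <- dt0
    }
    # step control on the dense (spline-refined) path maximum: any path
    # crossing the ridge tops out at or above the col height, so genuine
    # descent never raises this maximum, while the discrete image maximum
    # may creep up as images slide toward the saddle top
    st_old <- .dense_path_stats(surface, z)
    e_max_old <- st_old["max"]
    e_tol <- 1e-7 * max(1, abs(e_max_old))
    accepted <- FALSE
    best <- NULL
    st_new <- NULL
    for (h in 0:9) {
      znew <- z
      # simplified-string update: full-gradient descent then equal-arc
      # reparameterization (the explicit tangent projection is prone to a
      # kink instability; reparameterization removes the tangential motion)
      znew[interior, ] <- z[interior, ] - (dt / 2^h) * grad[interior, ]
      znew <- clip2(.reparam_equal_arc(clip2(znew)))
      st_new <- .dense_path_stats(surface, znew)
      e_max_new <- st_new["max"]
      if (is.null(best) || e_max_new < best$e) best <- list(z = znew, e = e_max_new)
      if (e_max_new <= e_max_old + e_tol) {
        if (h > 0) dt <- dt / 2^h
        else dt <- min(dt * 1.2, dt0)  # regrow after a clean step
        accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      if (best$e > e_max_old + 1e-3 * max(1, abs(e_max_old)))
        stop("string step too large: path maximum energy still increasing ",
             "after 10 halvings; retry with a smaller `step`")
      # residual increase is discretization noise: the string is stationary
      # at this resolution
      converged <- TRUE
      break
    }
    # convergence on the perpendicular displacement: tangential sliding from
    # the reparameterization does not move the path as a curve
    dz <- znew - z
    dperp <- dz - tang * rowSums(dz * tang)
    disp <- max(sqrt(rowSums(dperp^2)))
    z <- znew
    if (disp < tol) { converged <- TRUE; break }
    # stagnation: the discretized string can hover in a limit cycle whose
    # perpendicular displacement floor exceeds `tol` while the path, as a
    # curve, has stopped descending. A limit cycle shows neither improving
    # dense energies nor shrinking displacements; geometric convergence
    # keeps shrinking the displacement and is left to reach `tol`.
    improved <- FALSE
    if (st_new["max"] < best_max - 1e-8 * max(1, abs(st_new["max"]))) {
      best_max <- st_new["max"]
      improved <- TRUE
    }
    if (st_new["mean"] < best_mean - 1e-8 * max(1, abs(st_new["mean"]))) {
      best_mean <- st_new["mean"]
      improved <- TRUE
    }
    if (disp < (1 - 1e-3) * best_disp) {
      best_disp <- disp
      improved <- TRUE
    }
    if (improved) stall <- 0L else {
      stall <- stall + 1L
      if (stall >= 50L) { converged <- TRUE; break }
    }
  }
  seg <- sqrt(rowSums(diff(z)^2))
  arc <- c(0, cumsum(seg))
  structure(
    list(images = z, n_images = n_images,
         arc_parameter = arc / max(arc[length(arc)], .Machine$double.eps),
         converged = converged, iterations_run = iterations,
         surface = surface),
    class = "path_string"
  )
}

#' @export
print.path_string <- function(x, ...) {
  cat(sprintf("<path_string> %d images, %d iterations, %s\n",
              x$n_images, x$iterations_run,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Tidy a path string
#'
#' @param x A `path_string`.
#' @param ... Unused.
#' @return Tibble with `image`, `arc`, `xi_pt`, `xi_at`, `G`.
#' @method tidy path_string
#' @export
tidy.path_string <- function(x, ...) {
  g <- fes_interpolate(x$surface, x$images, gradient = FALSE)
  tibble::tibble(image = seq_len(x$n_images), arc = x$arc_parameter,
                 xi_pt = x$images[, 1], xi_at = x$images[, 2], G = g$G)
}

# Local extrema of a numeric series. Consecutive values within `tol` are
# collapsed into plateau runs; a run is an extremum if both neighbouring runs
# lie above (minimum) or below (maximum) it, endpoints counting as one-sided.
# The reported index is the leftmost point of the run (plateau tie-break).
.local_extrema <- function(g, tol = 1e-9) {
  plateau <- cumsum(c(TRUE, abs(diff(g)) > tol))
  run_start <- which(!duplicated(plateau))
  val <- g[run_start]
  R <- length(val)
  if (R == 1L) return(list(minima = 1L, maxima = integer(0)))
  lower_left <- c(TRUE, val[-R] > val[-1])    # run r below run r-1
  lower_right <- c(val[-R] < val[-1], TRUE)   # run r below run r+1
  is_min <- lower_left & lower_right
  higher_left <- c(TRUE, val[-R] < val[-1])
  higher_right <- c(val[-R] > val[-1], TRUE)
  is_max <- higher_left & higher_right
  list(minima = run_start[is_min], maxima = run_start[is_max])
}

#' Free-energy profile along a path
#'
#' Interpolates the surface along a (spline-refined) path, shifts the energy
#' so the first basin minimum is zero, and labels the stationary states:
#' minima R, I, ... , P and maxima TS1, TS2, ... in arc order. The
#' rate-controlling barrier is the profile maximum relative to R.
#'
#' @param surface An [fe_surface()].
#' @param path A `path_string` from [string_mfep()].
#' @param n_refine Dense evaluation points per image interval along the arc
#'   (cubic-spline refinement of the image polyline; default 8).
#' @return A `reaction_profile` object: list with `profile` (tibble: `arc`,
#'   `xi_pt`, `xi_at`, `G`), `states` (tibble: `label`, `arc`, `xi_pt`,
#'   `xi_at`, `G`), `rate_controlling_barrier` (kcal/mol), `converged`.
#' @export
profile_along_path <- function(surface, path, n_refine = 8L) {
  stopifnot(inherits(surface, "fe_surface"), inherits(path, "path_string"))
  if (!path$converged)
    warning("path is not converged; profile may be unreliable")
  s <- path$arc_parameter
  n_dense <- n_refine * (path$n_images - 1L) + 1L
  sd_ <- seq(0, 1, length.out = n_dense)
  x <- stats::spline(s, path$images[, 1], xout = sd_, method = "natural")$y
  y <- stats::spline(s, path$images[, 2], xout = sd_, method = "natural")$y
  # keep the refined path inside the hull
  x <- pmin(pmax(x, min(surface$axis_pt)), max(surface$axis_pt))
  y <- pmin(pmax(y, min(surface$axis_at)), max(surface$axis_at))
  g <- fes_interpolate(surface, cbind(x, y), gradient = FALSE)$G
  ex <- .local_extrema(g)
  if (length(ex$minima) == 0) ex$minima <- which.min(g)
  ref <- g[ex$minima[1]]
  g <- g - ref
  mins <- ex$minima
  # a saddle is interior to the path: endpoint maxima are not labeled TS
  maxs <- setdiff(ex$maxima, c(1L, length(g)))
  min_labels <- if (length(mins) == 1L) "R" else
    c("R", if (length(mins) > 2L) paste0("I", seq_len(length(mins) - 2L)), "P")
  if (length(mins) == 3L) min_labels <- c("R", "I", "P")
  ts_labels <- if (length(maxs)) paste0("TS", seq_along(maxs)) else character(0)
  idx <- c(mins, maxs)
  lab <- c(min_labels, ts_labels)
  ord <- order(idx)
  states <- tibble::tibble(label = lab[ord], arc = sd_[idx[ord]],
                           xi_pt = x[idx[ord]], xi_at = y[idx[ord]],
                           G = g[idx[ord]])
  structure(
    list(profile = tibble::tibble(arc = sd_, xi_pt = x, xi_at = y, G = g),
         states = states,
         rate_controlling_barrier = max(g),
         converged = path$converged),
    class = "reaction_profile"
  )
}

#' @export
print.reaction_profile <- function(x, ...) {
  cat(sprintf("<reaction_profile> barrier %.3f kcal/mol; states: %s\n",
              x$rate_controlling_barrier,
              paste(x$states$label, collapse = " -> ")))
  invisible(x)
}

#' Transition-state coordinates along a reaction profile
#'
#' Coordinates of each labeled transition state, refined by a parabolic fit
#' of G against arc length through the three profile points bracketing the
#' maximum (sub-grid resolution). Under the sign convention of the alkyl
#' transfer coordinate, a negative xi_AT at the rate-controlling TS marks an
#' "early" transition state with nucleophilic attack less advanced than
#' leaving-group departure.
#'
#' @param profile A `reaction_profile` from [profile_along_path()].
#' @return Tibble with `label`, `arc`, `xi_pt`, `xi_at`, `G` per transition
#'   state (zero rows, with a message, if no TS was found).
#' @export
ts_coordinates <- function(profile) {
  stopifnot(inherits(profile, "reaction_profile"))
  st <- profile$states[grepl("^TS", profile$states$label), , drop = FALSE]
  if (nrow(st) == 0L) {
    message("no transition state found along the profile")
    return(tibble::tibble(label = character(0), arc = numeric(0),
                          xi_pt = numeric(0), xi_at = numeric(0),
                          G = numeric(0)))
  }
  pr <- profile$profile
  refine <- function(arc0) {
    i <- which.min(abs(pr$arc - arc0))
    if (i <= 1L || i >= nrow(pr)) return(pr[i, ])
    a <- pr$arc[(i - 1):(i + 1)]; gg <- pr$G[(i - 1):(i + 1)]
    denom <- (gg[1] - 2 * gg[2] + gg[3])
    ds <- if (abs(denom) < 1e-14) 0 else
      0.5 * (gg[1] - gg[3]) / denom * (a[2] - a[1])
    ds <- max(min(ds, a[3] - a[2]), a[1] - a[2])
    s_star <- a[2] + ds
    tibble::tibble(
      arc = s_star,
      xi_pt = stats::spline(pr$arc, pr$xi_pt, xout = s_star)$y,
      xi_at = stats::spline(pr$arc, pr$xi_at, xout = s_star)$y,
      G = stats::spline(pr$arc, pr$G, xout = s_star)$y
    )
  }
  out <- dplyr::bind_rows(lapply(st$arc, refine))
  dplyr::bind_cols(tibble::tibble(label = st$label), out)
}
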