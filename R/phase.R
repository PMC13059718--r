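## Phase-plane analysis: attractor assignment, basins of attraction over a
## grid of initial (r, n) states, and nullclines.

stable_attractors <- function(params, search_box = NULL) {
  fp <- find_fixed_points(params, search_box)
  fp[fp$classification == "stable", , drop = FALSE]
}

## scaled distance used to decide that a trajectory has settled on an attractor
attractor_distance <- function(n, r, attractors, r_scale, K) {
  vapply(seq_len(nrow(attractors)), function(i) {
    sqrt(((r - attractors$r[i]) / r_scale)^2 + ((n - attractors$n[i]) / K)^2)
  }, numeric(1))
}

#' Which attractor does an initial state evolve to?
#'
#' Integrates the model from `init` over `horizon` hours and matches the
#' final state against the stable fixed points in scaled coordinates
#' (`r / r_scale`, `n / K`). Returns the index of the matched attractor (row
#' of the `attractors` table), or `NA` (unresolved) if the final state is not
#' within `tol` of any stable fixed point.
#'
#' @param init Initial [model_state()].
#' @param params A [model_params()] object.
#' @param horizon Integration horizon in hours.
#' @param tol Match tolerance in scaled coordinates.
#' @param attractors Optional pre-computed stable fixed-point table (as
#'   returned by [find_fixed_points()], stable rows only); computed if `NULL`.
#' @param r_scale ROS scale used for the match; defaults to the basin-grid
#'   convention `4 * r0` (at least the extinction-line ROS level).
#' @return Integer attractor index or `NA_integer_`, with the attractor table
#'   in attribute `"attractors"`.
#' @export
attractor_of <- function(init, params, horizon = 2000, tol = 0.02,
                         attractors = NULL, r_scale = NULL) {
  stopifnot(inherits(params, "ferrodyn_params"))
  init <- as_state(init)
  if (is.null(attractors)) attractors <- stable_attractors(params)
  if (!nrow(attractors))
    fd_stop_numeric("no stable attractor found for these parameters")
  if (is.null(r_scale))
    r_scale <- max(4 * params$r0,
                   1.2 * params$a * params$alpha / (params$b - params$c))
  tr <- simulate_model(params, init, times = c(0, horizon))
  fin <- tr[nrow(tr), ]
  d <- attractor_distance(fin$n, fin$r, attractors, r_scale, params$K)
  idx <- if (min(d) < tol) which.min(d) else NA_integer_
  structure(idx, attractors = attractors)
}

## classic RK4 on a batch of states; cheap per step so a fixed step is used.
## dt = 0.25 h is far below the fastest model timescale (~10 h).
batch_rk4 <- function(n, r, params, horizon, dt) {
  f <- function(n, r) rhs_raw(n, r, params)
  steps <- ceiling(horizon / dt)
  for (i in seq_len(steps)) {
    k1 <- f(n, r)
    k2 <- f(n + dt / 2 * k1$dn, r + dt / 2 * k1$dr)
    k3 <- f(n + dt / 2 * k2$dn, r + dt / 2 * k2$dr)
    k4 <- f(n + dt * k3$dn, r + dt * k3$dr)
    n <- n + dt / 6 * (k1$dn + 2 * k2$dn + 2 * k3$dn + k4$dn)
    r <- r + dt / 6 * (k1$dr + 2 * k2$dr + 2 * k3$dr + k4$dr)
    n <- pmax(n, 0); r <- pmax(r, 0)
  }
  list(n = n, r = r)
}

#' Basins of attraction over a grid of initial states
#'
#' Every grid node (an initial condition `(r, n)`) is integrated forward and
#' labelled with the index of the stable fixed point it converges to,
#' mirroring the shaded basin maps used to read off cell fate from seeding
#' density and initial lipid ROS. Nodes not settled within the horizon are
#' labelled unresolved (`NA`), never silently assigned.
#'
#' The whole grid is integrated simultaneously with a fixed-step RK4 batch
#' integrator (step `dt`); [attractor_of()] with its adaptive solver is the
#' reference the labels are checked against in the test-suite.
#'
#' @param params A [model_params()] object.
#' @param r_axis,n_axis Strictly increasing grid axes. Defaults: 60 points
#'   over `r` in `[0, 4 r0]` and `n` in `[1e-3, 1.1 K]`.
#' @param horizon Integration horizon in hours.
#' @param tol Attractor match tolerance in scaled `(r/r_max, n/K)` coordinates.
#' @param dt RK4 step (hours).
#' @return A `ferrodyn_basins` object: list with `r_axis`, `n_axis`, `labels`
#'   (integer matrix, rows = r, cols = n, `NA` = unresolved), `attractors`
#'   (stable fixed-point table), and `unresolved_fraction`.
#' @export
compute_basins <- function(params, r_axis = NULL, n_axis = NULL,
                           horizon = 2000, tol = 0.02, dt = 0.25) {
  stopifnot(inherits(params, "ferrodyn_params"))
  r_ext <- params$a * params$alpha / (params$b - params$c)
  r_max <- max(4 * params$r0, 1.2 * r_ext)
  if (is.null(r_axis)) r_axis <- seq(0, r_max, length.out = 60)
  if (is.null(n_axis)) n_axis <- seq(1e-3, 1.1 * params$K, length.out = 60)
  if (any(diff(r_axis) <= 0) || any(diff(n_axis) <= 0))
    fd_stop_invalid("grid axes must be strictly increasing")
  attractors <- stable_attractors(
    params, c(r_max = max(r_axis, r_ext) * 1.2, n_max = max(n_axis) * 1.2))
  if (!nrow(attractors))
    fd_stop_numeric("no stable attractor found for these parameters")

  g <- expand.grid(r = r_axis, n = n_axis)
  fin <- batch_rk4(g$n, g$r, params, horizon, dt)
  r_scale <- max(r_axis)
  dists <- vapply(seq_len(nrow(attractors)), function(i) {
    sqrt(((fin$r - attractors$r[i]) / r_scale)^2 +
           ((fin$n - attractors$n[i]) / params$K)^2)
  }, numeric(length(fin$n)))
  dists <- matrix(dists, ncol = nrow(attractors))
  best <- max.col(-dists, ties.method = "first")
  best[dists[cbind(seq_along(best), best)] >= tol] <- NA_integer_
  labels <- matrix(best, nrow = length(r_axis), ncol = length(n_axis))
  structure(list(r_axis = r_axis, n_axis = n_axis, labels = labels,
                 attractors = attractors,
                 unresolved_fraction = mean(is.na(labels)),
                 params = params),
            class = "ferrodyn_basins")
}

#' @export
print.ferrodyn_basins <- function(x, ...) {
  cat(sprintf("Basin grid %d x %d (r x n), %d attractor(s), %.1f%% unresolved\n",
              length(x$r_axis), length(x$n_axis), nrow(x$attractors),
              100 * x$unresolved_fraction))
  print(x$attractors[, c("n", "r", "classification")])
  invisible(x)
}

#' Fraction of the grid draining to one attractor
#'
#' Fractions over all attractors plus the unresolved fraction partition the
#' grid, so they sum to one.
#'
#' @param basins A `ferrodyn_basins` object.
#' @param index Attractor index (row in `basins$attractors`).
#' @return Fraction in `[0, 1]`.
#' @export
basin_area_fraction <- function(basins, index) {
  stopifnot(inherits(basins, "ferrodyn_basins"))
  if (!index %in% seq_len(nrow(basins$attractors)))
    fd_stop_invalid("attractor index out of range")
  mean(!is.na(basins$labels) & basins$labels == index)
}

#' Index of the sensitive (low-n) / resistant (high-n) attractor
#'
#' @param attractors A fixed-point table (rows of [find_fixed_points()]).
#' @return Row index into `attractors`.
#' @export
sensitive_index <- function(attractors) which.min(attractors$n)

#' @rdname sensitive_index
#' @export
resistant_index <- function(attractors) which.max(attractors$n)

#' Nullclines of the feedback system
#'
#' The `r`-nullcline of the model is the line
#' `n = K (1 - (b - c) r / (a alpha))`; the `n`-nullclines are the `n = 0`
#' axis and the curve `n = K (1 - (beta/alpha) sigma(r))` (clipped at zero).
#'
#' @param params A [model_params()] object.
#' @param r_axis ROS grid over which curves are evaluated; defaults to 200
#'   points over `[0, 4 r0]` (at least the extinction-line level).
#' @return List of data.frames (`r`, `n`), named `dn_curve`, `dn_axis`,
#'   `dr_curve`.
#' @export
nullclines <- function(params, r_axis = NULL) {
  stopifnot(inherits(params, "ferrodyn_params"))
  r_ext <- params$a * params$alpha / (params$b - params$c)
  if (is.null(r_axis))
    r_axis <- seq(0, max(4 * params$r0, 1.2 * r_ext), length.out = 200)
  dn_curve <- data.frame(
    r = r_axis,
    n = pmax(0, params$K * (1 - (params$beta / params$alpha) *
                              death_switch(r_axis, params))))
  dr_curve <- data.frame(
    r = r_axis,
    n = params$K * (1 - (params$b - params$c) * r_axis /
                      (params$a * params$alpha)))
  dr_curve <- dr_curve[dr_curve$n >= 0, , drop = FALSE]
  list(dn_curve = dn_curve,
       dn_axis = data.frame(r = r_axis, n = 0),
       dr_curve = dr_curve)
}

#' Plot a basin-of-attraction map
#'
#' Base-graphics rendering of a [compute_basins()] grid using the standard
#' colour convention (sensitive basin orange/red, insensitive blue).
#'
#' @param x A `ferrodyn_basins` object.
#' @param col_sensitive,col_resistant,col_unresolved Fill colours.
#' @param ... Passed to [graphics::image()].
#' @export
plot.ferrodyn_basins <- function(x, col_sensitive = "#F2A26B",
                                 col_resistant = "#7FA8D9",
                                 col_unresolved = "grey85", ...) {
  att <- x$attractors
  z <- x$labels
  cols <- rep(col_unresolved, nrow(att) + 1L)
  cols[1L + sensitive_index(att)] <- col_sensitive
  cols[1L + resistant_index(att)] <- col_resistant
  z[is.na(z)] <- 0L
  image(x$r_axis, x$n_axis, z, col = cols[sort(unique(as.vector(z))) + 1L],
        xlab = "lipid ROS per cell (r)", ylab = "confluence fraction (n)", ...)
  points(att$r, att$n, pch = 21, bg = "white", cex = 1.4)
  invisible(x)
}
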