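## Core ODE system: logistic growth gated by a lipid-ROS death switch,
## ROS production proportional to the division rate, first-order clearance,
## and linear Fenton autocatalysis.

#' Per-capita ferroptotic death switch
#'
#' Fraction of the maximal death rate engaged at lipid ROS level `r`. The
#' default is a Hill function \eqn{\sigma(r) = r^h/(r_0^h + r^h)}, which is 0
#' at `r = 0`, 1/2 at the threshold `r0`, and saturates at 1. With
#' `switch_form = "step"` the idealised hard threshold `1(r > r0)` is used
#' instead (with value 1/2 exactly at the threshold).
#'
#' @param r Lipid ROS level(s), >= 0. Vectorised.
#' @param params A [model_params()] object.
#' @return Death multiplier(s) in `[0, 1]`.
#' @export
#' @examples
#' death_switch(model_params()$r0, model_params())  # 0.5 at threshold
death_switch <- function(r, params) {
  if (!is.numeric(r) || any(!is.finite(r)))
    fd_stop_invalid("lipid ROS level r must be finite")
  if (any(r < 0))
    fd_stop_invalid("lipid ROS level r must be >= 0")
  if (params$switch_form == "step") {
    out <- as.numeric(r > params$r0)
    out[r == params$r0] <- 0.5
    return(out)
  }
  rh <- r^params$h
  rh / (params$r0^params$h + rh)
}

## derivative of the Hill switch; 0 almost everywhere for the step form
death_switch_deriv <- function(r, params) {
  if (params$switch_form == "step") return(rep(0, length(r)))
  h <- params$h
  r0h <- params$r0^h
  h * r0h * r^(h - 1) / (r0h + r^h)^2
}

#' Right-hand side of the feedback ODE system
#'
#' \deqn{dn/dt = \alpha n (1 - n/K) - \beta n \sigma(r)}
#' \deqn{dr/dt = a \alpha (1 - n/K) - b r + c r}
#'
#' ROS production is tied to the per-capita division rate `alpha (1 - n/K)`:
#' crowded, slowly dividing populations generate little new lipid ROS, which
#' is what couples population density to ferroptosis sensitivity.
#'
#' @param state A [model_state()] (or length-2 numeric `c(n, r)`).
#' @param params A [model_params()] object.
#' @return Named numeric `c(dn, dr)`.
#' @export
model_rhs <- function(state, params) {
  s <- as_state(state)
  n <- s[["n"]]; r <- s[["r"]]
  dn <- params$alpha * n * (1 - n / params$K) -
    params$beta * n * death_switch(r, params)
  dr <- params$a * params$alpha * (1 - n / params$K) -
    params$b * r + params$c * r
  out <- c(dn = dn, dr = dr)
  if (any(!is.finite(out))) fd_stop_numeric("non-finite derivative")
  out
}

## unchecked internal version used inside the integrator
rhs_raw <- function(n, r, params) {
  sig <- if (params$switch_form == "step") {
    out <- as.numeric(r > params$r0); out[r == params$r0] <- 0.5; out
  } else {
    rh <- pmax(r, 0)^params$h
    rh / (params$r0^params$h + rh)
  }
  list(
    dn = params$alpha * n * (1 - n / params$K) - params$beta * n * sig,
    dr = params$a * params$alpha * (1 - n / params$K) -
      (params$b - params$c) * r,
    death = params$beta * n * sig
  )
}

#' Analytic Jacobian of the feedback system
#'
#' @inheritParams model_rhs
#' @return A 2x2 matrix with rows (dn, dr) and columns (n, r).
#' @export
model_jacobian <- function(state, params) {
  s <- as_state(state)
  n <- s[["n"]]; r <- s[["r"]]
  J <- matrix(0, 2, 2, dimnames = list(c("dn", "dr"), c("n", "r")))
  J[1, 1] <- params$alpha * (1 - 2 * n / params$K) -
    params$beta * death_switch(r, params)
  J[1, 2] <- -params$beta * n * death_switch_deriv(r, params)
  J[2, 1] <- -params$a * params$alpha / params$K
  J[2, 2] <- -(params$b - params$c)
  J
}

#' Integrate the feedback model
#'
#' Solves the ODE system with a stiff-capable adaptive integrator
#' ([deSolve::ode()], method `lsoda`) at relative/absolute tolerances
#' 1e-8/1e-10. A cumulative dead-cell area \eqn{D(t) = \int_0^t \beta n
#' \sigma(r)\,ds} is integrated alongside the state (the dead-cell dye marks
#' cells once and the count accrues). States are clipped at zero after
#' integration; a clip exceeding 1e-6 is reported as a warning.
#'
#' @param params A [model_params()] object.
#' @param init Initial [model_state()].
#' @param times Strictly increasing output times in hours, `times[1] >= 0`.
#' @param rtol,atol Solver tolerances.
#' @return A `ferrodyn_trajectory`: data.frame with columns `time_h`, `n`,
#'   `r`, `dead`, and the parameters in attribute `"params"`.
#' @export
simulate_model <- function(params, init, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "ferrodyn_params"))
  init <- as_state(init)
  if (!is.numeric(times) || length(times) < 2L || any(!is.finite(times)))
    fd_stop_invalid("times must be finite numerics of length >= 2")
  if (times[1] < 0 || any(diff(times) <= 0))
    fd_stop_invalid("times must be strictly increasing with times[1] >= 0")

  deriv <- function(t, y, parms) {
    d <- rhs_raw(y[1L], y[2L], parms)
    list(c(d$dn, d$dr, d$death))
  }
  sol <- try(ode(y = c(n = init[["n"]], r = init[["r"]], dead = 0),
                 times = times, func = deriv, parms = params,
                 method = "lsoda", rtol = rtol, atol = atol),
             silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(times) ||
      any(!is.finite(sol[, c("n", "r")])))
    fd_stop_numeric(paste0("ODE integration failed: ",
                           if (inherits(sol, "try-error")) attr(sol, "condition")$message
                           else "incomplete or non-finite solution"))
  out <- as.data.frame(unclass(sol))
  names(out)[1L] <- "time_h"
  clip <- min(0, min(out$n), min(out$r))
  if (clip < -1e-6)
    warning(sprintf("integrated state clipped at zero by %.3g", -clip))
  out$n <- pmax(out$n, 0)
  out$r <- pmax(out$r, 0)
  out$dead <- pmax(out$dead, 0)
  structure(out, params = params, class = c("ferrodyn_trajectory", "data.frame"))
}

#' Enumerate fixed points of the feedback system
#'
#' Multi-start Newton iteration on the 2-variable root problem, seeded from a
#' regular grid over the search box plus the `n = 0` and `r = 0` axes and the
#' closed-form boundary candidates `(n, r) = (0, 0)`, `(K, 0)`, and the
#' extinction-line point `(0, a*alpha/(b - c))`. Converged roots are
#' de-duplicated (pairwise distance > 1e-5) and classified from the
#' eigenvalues of the analytic Jacobian: all real parts below -1e-9 is
#' `stable`, all above 1e-9 `unstable`, mixed signs `saddle`, and anything
#' inside the zero band is reported as `unclassified` rather than guessed.
#'
#' @param params A [model_params()] object.
#' @param search_box Named numeric `c(r_max, n_max)` bounding the search.
#'   Defaults to `c(r_max = 4 * r0_or_ros_range, n_max = 1.1 * K)` where the
#'   ROS range is at least the extinction-line level.
#' @param grid_n Starts per axis for the multi-start grid.
#' @param tol Residual tolerance: returned points satisfy `|rhs| < tol`.
#' @return A data.frame with columns `n`, `r`, `eig1`, `eig2` (complex), and
#'   `classification`.
#' @export
find_fixed_points <- function(params, search_box = NULL, grid_n = 20L,
                              tol = 1e-8) {
  stopifnot(inherits(params, "ferrodyn_params"))
  r_ext <- params$a * params$alpha / (params$b - params$c)
  if (is.null(search_box))
    search_box <- c(r_max = max(4 * params$r0, 1.2 * r_ext),
                    n_max = 1.1 * params$K)
  r_max <- search_box[["r_max"]]; n_max <- search_box[["n_max"]]
  if (r_max <= 0 || n_max <= 0) fd_stop_invalid("search box must be positive")

  f <- function(x) unname(c(
    params$alpha * x[1] * (1 - x[1] / params$K) -
      params$beta * x[1] * death_switch(max(x[2], 0), params),
    params$a * params$alpha * (1 - x[1] / params$K) -
      (params$b - params$c) * x[2]))

  newton <- function(x0) {
    x <- x0
    for (i in 1:80) {
      fx <- f(x)
      if (any(!is.finite(fx))) return(NULL)
      if (sqrt(sum(fx^2)) < 1e-13) break
      J <- model_jacobian(model_state(max(x[1], 0), max(x[2], 0)), params)
      step <- tryCatch(solve(J, fx), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      ## damped update, keep iterates near the physical region
      lam <- 1
      repeat {
        xn <- x - lam * step
        if (all(is.finite(xn)) && xn[1] > -0.1 * n_max && xn[2] > -0.1 * r_max &&
            xn[1] < 2 * n_max && xn[2] < 2 * r_max) break
        lam <- lam / 2
        if (lam < 1e-4) return(NULL)
      }
      x <- xn
    }
    if (sqrt(sum(f(x)^2)) >= tol) return(NULL)
    x
  }

  gr <- seq(0, r_max, length.out = grid_n)
  gn <- seq(0, n_max, length.out = grid_n)
  starts <- rbind(as.matrix(expand.grid(n = gn, r = gr)),
                  cbind(n = gn, r = 0), cbind(n = 0, r = gr),
                  c(0, 0), c(params$K, 0), c(0, r_ext))
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    x <- newton(as.numeric(starts[i, ]))
    if (is.null(x)) next
    x[abs(x) < 1e-10] <- 0
    if (x[1] < -1e-9 || x[2] < -1e-9) next
    if (x[1] > 1.5 * n_max || x[2] > 1.5 * r_max) next
    dup <- any(vapply(roots, function(y) sqrt(sum((y - x)^2)) <= 1e-5, logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <- x
  }
  if (!length(roots))
    return(data.frame(n = numeric(0), r = numeric(0),
                      eig1 = complex(0), eig2 = complex(0),
                      classification = character(0)))
  res <- do.call(rbind, lapply(roots, function(x) {
    ev <- eigen(model_jacobian(model_state(max(x[1], 0), max(x[2], 0)), params),
                only.values = TRUE)$values
    ev <- as.complex(ev)
    re <- Re(ev)
    cls <- if (any(abs(re) <= 1e-9)) "unclassified"
    else if (all(re < 0)) "stable"
    else if (all(re > 0)) "unstable"
    else "saddle"
    data.frame(n = x[1], r = x[2], eig1 = ev[1], eig2 = ev[2],
               classification = cls)
  }))
  res <- res[order(res$n, res$r), , drop = FALSE]
  rownames(res) <- NULL
  res
}
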