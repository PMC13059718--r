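## Weighted least-squares estimation of model parameters from observed
## time courses, with optional condition-specific parameters (e.g. a lower
## lipid-ROS death threshold under GPX4 inhibition) shared-fit jointly.

fit_param_names <- function() {
  c("alpha", "K", "beta", "a", "b", "c", "r0", "h", "ros_scale", "ros_baseline")
}

## ros_baseline may be zero, so it is fitted on the natural scale; all other
## parameters are strictly positive rates/levels and are fitted on log scale.
log_scale_params <- function() setdiff(fit_param_names(), "ros_baseline")

default_fit_bounds <- function() {
  list(alpha = c(1e-4, 1), K = c(0.2, 2), beta = c(1e-4, 1),
       a = c(1e-3, 10), b = c(1e-4, 1), c = c(1e-6, 0.5),
       r0 = c(0.05, 10), h = c(1, 12),
       ros_scale = c(1e-3, 100), ros_baseline = c(0, 10))
}

#' Specification of a weighted least-squares fit
#'
#' @param free Character vector of free parameters, a subset of
#'   `c("alpha","K","beta","a","b","c","r0","h","ros_scale","ros_baseline")`.
#'   Fitting `a` and `ros_scale` simultaneously is refused: under the affine
#'   observation map they are confounded (only their product is identified),
#'   so one must be fixed.
#' @param condition_specific Subset of `free` estimated separately per
#'   condition (e.g. `"r0"` for a control/GPX4-inhibition contrast); the
#'   remaining free parameters are shared across conditions.
#' @param fixed Named list overriding the package defaults for parameters
#'   that are not free.
#' @param bounds Named list of `c(lower, upper)` per parameter; defaults
#'   cover the plausible physiological ranges.
#' @param weights Weighting scheme: `"inv_var"` (default, per-observable
#'   inverse pooled replicate variance; residuals are scaled by the pooled
#'   replicate SD, floored at its 10th percentile so exact replicates do not
#'   produce infinite weights) or a named numeric vector of per-observable
#'   weights applied directly to the residuals.
#' @param multistart Number of jittered optimisation starts.
#' @param seed Integer seed controlling the start jitter (recorded in the
#'   result).
#' @param jitter_sd Log-scale SD of the multiplicative start jitter.
#' @return An object of class `ferrodyn_fit_spec`.
#' @export
fit_spec <- function(free = c("alpha", "K", "beta", "r0"),
                     condition_specific = character(),
                     fixed = list(), bounds = list(),
                     weights = "inv_var",
                     multistart = 16L, seed = 1L, jitter_sd = 0.3) {
  bad <- setdiff(free, fit_param_names())
  if (length(bad))
    fd_stop_invalid(paste0("unknown free parameter(s): ", paste(bad, collapse = ", ")))
  if (all(c("a", "ros_scale") %in% free))
    fd_stop_invalid(paste0(
      "'a' and 'ros_scale' cannot both be free: the affine observation map ",
      "only identifies their product; fix one of them"))
  if (!all(condition_specific %in% free))
    fd_stop_invalid("condition_specific must be a subset of free")
  b <- modifyList(default_fit_bounds(), bounds)
  for (p in free) {
    bp <- b[[p]]
    if (!is.numeric(bp) || length(bp) != 2L || any(!is.finite(bp)) || bp[1] >= bp[2])
      fd_stop_invalid(sprintf("bounds for '%s' must be finite and ordered", p))
  }
  if (multistart < 1L) fd_stop_invalid("multistart must be >= 1")
  structure(list(free = free, condition_specific = condition_specific,
                 fixed = fixed, bounds = b, weights = weights,
                 multistart = as.integer(multistart), seed = as.integer(seed),
                 jitter_sd = jitter_sd),
            class = "ferrodyn_fit_spec")
}

#' Per-record weights for a dataset
#'
#' The default scheme weights each observable by the inverse of its pooled
#' replicate variance: at each (condition, time) the across-replicate
#' variance is computed, pooled (averaged) over time, and floored at the 10th
#' percentile of the positive per-time variances so that exact replicates
#' (e.g. noiseless synthetic data) do not yield infinite weights; residuals
#' are then divided by the pooled SD. With a single replicate the overall
#' variance of the observable's values is used as a scale proxy.
#'
#' @param dataset A [timecourse_dataset()].
#' @param scheme `"inv_var"` or a named numeric vector of per-observable
#'   weights.
#' @return Numeric weight per record of `dataset`.
#' @export
make_weights <- function(dataset, scheme = "inv_var") {
  if (is.numeric(scheme)) {
    if (is.null(names(scheme)) || !all(unique(dataset$observable) %in% names(scheme)))
      fd_stop_invalid("numeric weights must be named by observable")
    return(unname(scheme[dataset$observable]))
  }
  if (!identical(scheme, "inv_var"))
    fd_stop_invalid(sprintf("unknown weight scheme '%s'", scheme))
  w_obs <- vapply(unique(dataset$observable), function(o) {
    sub <- dataset[dataset$observable == o, ]
    vt <- tapply(sub$value, interaction(sub$condition, sub$time_h, drop = TRUE),
                 function(v) if (length(v) > 1L) var(v) else NA_real_)
    vt <- vt[!is.na(vt)]
    pos <- vt[vt > 0]
    pooled <- if (length(pos)) {
      floor_v <- quantile(pos, 0.1, names = FALSE)
      mean(pmax(vt, floor_v))
    } else if (length(vt)) {
      v <- var(sub$value)            # all replicate variances zero
      if (v > 0) v else 1
    } else {
      v <- var(sub$value)            # single replicate
      if (is.finite(v) && v > 0) v else 1
    }
    1 / sqrt(pooled)
  }, numeric(1))
  unname(w_obs[dataset$observable])
}

## decode a transformed parameter vector into per-condition parameter sets
decode_theta <- function(theta, spec, conditions, base) {
  shared <- setdiff(spec$free, spec$condition_specific)
  vals <- list()
  i <- 1L
  for (p in shared) {
    vals[[p]] <- if (p %in% log_scale_params()) exp(theta[i]) else theta[i]
    i <- i + 1L
  }
  per_cond <- list()
  for (cond in conditions) {
    pc <- base
    pc[names(vals)] <- vals
    for (p in spec$condition_specific) {
      v <- if (p %in% log_scale_params()) exp(theta[i]) else theta[i]
      pc[[p]] <- v
      i <- i + 1L
    }
    per_cond[[cond]] <- pc
  }
  per_cond
}

theta_names <- function(spec, conditions) {
  shared <- setdiff(spec$free, spec$condition_specific)
  if (!length(spec$condition_specific)) return(shared)
  c(shared, unlist(lapply(conditions, function(cond)
    paste(spec$condition_specific, cond, sep = "."))))
}

build_param_obs <- function(pc) {
  params <- model_params(alpha = pc$alpha, K = pc$K, beta = pc$beta,
                         a = pc$a, b = pc$b, c = pc$c, r0 = pc$r0, h = pc$h,
                         switch_form = pc$switch_form %||% "hill")
  obs <- observation_model(ros_scale = pc$ros_scale,
                           ros_baseline = pc$ros_baseline)
  list(params = params, obs = obs)
}

## initial state per condition, from the first observed time point:
## n0 from mean confluence/100, r0 via the observation map, D0 = 0.
infer_init_state <- function(sub, obs) {
  t0 <- min(sub$time_h)
  first <- sub[sub$time_h == t0, ]
  n0 <- mean(first$value[first$observable == "confluence_pct"]) / 100
  ratio0 <- mean(first$value[first$observable == "lipid_ros_ratio"])
  r0 <- if (is.finite(ratio0))
    max(0, (ratio0 - obs$ros_baseline) / obs$ros_scale) else 0
  if (!is.finite(n0))
    fd_stop_invalid("cannot infer initial confluence from the dataset")
  model_state(max(n0, 1e-6), r0)
}

#' Weighted residual vector for a candidate parameter set
#'
#' One entry per dataset record: `weight * (observed - predicted)`. Initial
#' states per condition are taken from `init_states` when given, otherwise
#' inferred from the first observed time point via [infer_init_state] rules
#' (confluence/100 and the inverse observation map).
#'
#' @param params A [model_params()] object, or a named list of them (one per
#'   condition).
#' @param obs An [observation_model()], or a named list per condition.
#' @param dataset A [timecourse_dataset()].
#' @param weights Per-record numeric weights, a named per-observable vector,
#'   or a scheme name for [make_weights()].
#' @param init_states Optional named list of [model_state()] per condition.
#' @return Numeric residual vector, length `nrow(dataset)`.
#' @export
wls_residuals <- function(params, obs, dataset, weights = "inv_var",
                          init_states = NULL) {
  conditions <- unique(dataset$condition)
  if (inherits(params, "ferrodyn_params"))
    params <- setNames(rep(list(params), length(conditions)), conditions)
  if (inherits(obs, "ferrodyn_obs"))
    obs <- setNames(rep(list(obs), length(conditions)), conditions)
  w <- if (is.numeric(weights) && length(weights) == nrow(dataset) &&
           is.null(names(weights))) weights
       else make_weights(dataset, weights)
  res <- numeric(nrow(dataset))
  for (cond in conditions) {
    sel <- dataset$condition == cond
    sub <- dataset[sel, ]
    init <- if (!is.null(init_states)) as_state(init_states[[cond]])
            else infer_init_state(sub, obs[[cond]])
    times <- sort(unique(sub$time_h))
    pred <- predict_observables(params[[cond]], obs[[cond]], init, times)
    for (o in unique(sub$observable)) {
      osel <- sel & dataset$observable == o
      pv <- pred[[o]][match(dataset$time_h[osel], pred$time_h)]
      res[osel] <- dataset$value[osel] - pv
    }
  }
  if (any(!is.finite(res))) fd_stop_numeric("non-finite residuals")
  w * res
}

#' Fit the feedback model to observed time courses
#'
#' Bounded weighted least squares (Levenberg-Marquardt via
#' [minpack.lm::nls.lm()]) on a log-scale internal parameterisation, from
#' `multistart` jittered starts centred on the package defaults (overridden
#' by `fixed` and `start`). Parameters listed in `spec$condition_specific`
#' get one estimate per condition; all other free parameters are shared
#' across conditions (a joint fit).
#'
#' @param dataset A [timecourse_dataset()] covering every condition.
#' @param spec A [fit_spec()].
#' @param init_states Optional named list of [model_state()] per condition;
#'   by default inferred from the first observed time point.
#' @param start Optional named list overriding the start centre.
#' @return A `ferrodyn_fit`: list with `estimates` (named vector, natural
#'   scale), `per_condition` (list of `params`/`obs` per condition), `rss`,
#'   `residual_norms` (per observable), `convergence`, `multistart`
#'   (per-start table), `dispersion` (max relative spread of estimates among
#'   starts within 1% of the best RSS), and `seed`.
#' @export
fit_timecourses <- function(dataset, spec = fit_spec(), init_states = NULL,
                            start = list()) {
  stopifnot(inherits(dataset, "ferrodyn_dataset"),
            inherits(spec, "ferrodyn_fit_spec"))
  conditions <- unique(dataset$condition)
  base <- modifyList(c(unclass(model_params()),
                       unclass(observation_model())), spec$fixed)
  centre <- modifyList(base, start)
  w <- make_weights(dataset, spec$weights)

  nm <- theta_names(spec, conditions)
  bound_of <- function(name) {
    p <- sub("\\..*$", "", name)
    spec$bounds[[p]]
  }
  to_internal <- function(name, v) {
    p <- sub("\\..*$", "", name)
    if (p %in% log_scale_params()) log(v) else v
  }
  lower <- vapply(nm, function(x) to_internal(x, bound_of(x)[1]), numeric(1))
  upper <- vapply(nm, function(x) to_internal(x, bound_of(x)[2]), numeric(1))
  centre_theta <- vapply(nm, function(x) {
    p <- sub("\\..*$", "", x)
    to_internal(x, min(max(centre[[p]], bound_of(x)[1]), bound_of(x)[2]))
  }, numeric(1))

  objective <- function(theta) {
    per_cond <- decode_theta(theta, spec, conditions, base)
    bad <- any(vapply(per_cond, function(pc) pc$b <= pc$c, logical(1)))
    if (bad) return(rep(1e6, nrow(dataset)))   # infeasible: net ROS clearance <= 0
    po <- lapply(per_cond, build_param_obs)
    tryCatch(
      wls_residuals(lapply(po, `[[`, "params"), lapply(po, `[[`, "obs"),
                    dataset, weights = w, init_states = init_states),
      ferrodyn_error = function(e) rep(1e6, nrow(dataset)))
  }

  set.seed(spec$seed)
  jitters <- matrix(rnorm(spec$multistart * length(nm), 0, spec$jitter_sd),
                    nrow = spec$multistart)
  jitters[1L, ] <- 0   # first start is the unjittered centre
  runs <- vector("list", spec$multistart)
  for (k in seq_len(spec$multistart)) {
    th0 <- pmin(pmax(centre_theta + jitters[k, ], lower), upper)
    runs[[k]] <- tryCatch(
      nls.lm(par = th0, lower = lower, upper = upper, fn = objective,
             control = nls.lm.control(maxiter = 200)),
      error = function(e) e)
  }
  ok <- vapply(runs, function(x) inherits(x, "nls.lm"), logical(1))
  if (!any(ok)) {
    msgs <- vapply(runs, function(x) conditionMessage(x), character(1))
    fd_stop_numeric(paste0("all optimisation starts failed:\n",
                           paste(unique(msgs), collapse = "\n")))
  }
  rss <- vapply(runs, function(x)
    if (inherits(x, "nls.lm")) x$deviance else NA_real_, numeric(1))
  best_k <- which.min(rss)
  best <- runs[[best_k]]
  theta_hat <- setNames(best$par, nm)

  est <- vapply(nm, function(x) {
    p <- sub("\\..*$", "", x)
    if (p %in% log_scale_params()) exp(theta_hat[[x]]) else theta_hat[[x]]
  }, numeric(1))
  per_cond <- lapply(decode_theta(best$par, spec, conditions, base),
                     build_param_obs)

  resid_best <- wls_residuals(lapply(per_cond, `[[`, "params"),
                              lapply(per_cond, `[[`, "obs"),
                              dataset, weights = w, init_states = init_states)
  norms <- vapply(unique(dataset$observable), function(o)
    sqrt(sum(resid_best[dataset$observable == o]^2)), numeric(1))

  near <- which(ok & rss <= min(rss, na.rm = TRUE) * 1.01)
  disp <- if (length(near) > 1L) {
    mats <- vapply(near, function(k) {
      vapply(nm, function(x) {
        p <- sub("\\..*$", "", x)
        v <- runs[[k]]$par[match(x, nm)]
        if (p %in% log_scale_params()) exp(v) else v
      }, numeric(1))
    }, numeric(length(nm)))
    mats <- matrix(mats, nrow = length(nm))
    max((apply(mats, 1, max) - apply(mats, 1, min)) /
          pmax(abs(est), 1e-12))
  } else 0

  structure(list(
    estimates = est,
    per_condition = per_cond,
    rss = sum(resid_best^2),
    residual_norms = norms,
    convergence = best$info %in% 1:4,
    multistart = data.frame(start = seq_len(spec$multistart), rss = rss,
                            converged = ok),
    dispersion = disp,
    seed = spec$seed,
    spec = spec,
    conditions = conditions),
    class = "ferrodyn_fit")
}

#' @export
print.ferrodyn_fit <- function(x, ...) {
  cat(sprintf("Weighted least-squares fit: RSS %.6g, %s, %d start(s), seed %d\n",
              x$rss, if (x$convergence) "converged" else "NOT converged",
              nrow(x$multistart), x$seed))
  print(round(x$estimates, 6))
  invisible(x)
}
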