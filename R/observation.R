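## Observation model: maps model state onto the measured live-cell imaging
## channels (confluence %, oxidized/reduced reporter ratio, dead counts per
## confluence).

#' Observation model linking lipid ROS to the reporter ratio
#'
#' The ratiometric lipid-peroxidation reporter is assumed affine in the
#' model's per-cell ROS variable: `ratio = ros_baseline + ros_scale * r`.
#' `ros_baseline` is the oxidized/reduced ratio of an unstressed cell.
#'
#' @param ros_scale Ratio units per ROS unit (> 0).
#' @param ros_baseline Ratio at `r = 0` (>= 0).
#' @return An object of class `ferrodyn_obs`.
#' @export
observation_model <- function(ros_scale = 0.5, ros_baseline = 0.1) {
  if (!is.numeric(ros_scale) || length(ros_scale) != 1L || !is.finite(ros_scale) ||
      ros_scale <= 0)
    fd_stop_invalid("ros_scale must be a single positive number")
  if (!is.numeric(ros_baseline) || length(ros_baseline) != 1L ||
      !is.finite(ros_baseline) || ros_baseline < 0)
    fd_stop_invalid("ros_baseline must be a single non-negative number")
  structure(list(ros_scale = ros_scale, ros_baseline = ros_baseline),
            class = "ferrodyn_obs")
}

#' Names of the observables produced by the model
#' @export
observable_names <- function() {
  c("confluence_pct", "lipid_ros_ratio", "dead_per_confluence")
}

#' Predict the measured time courses from model parameters
#'
#' Runs [simulate_model()] and maps the trajectory onto the observables:
#' `confluence_pct = 100 n(t)`, `lipid_ros_ratio = ros_baseline +
#' ros_scale * r(t)`, and `dead_per_confluence = D(t) / n(t)` where `D` is
#' the cumulative dead area integrated alongside the state (the dead-cell
#' dye marks a cell once and the count accrues).
#'
#' @param params A [model_params()] object.
#' @param obs An [observation_model()].
#' @param init Initial [model_state()].
#' @param times Output times (hours), strictly increasing.
#' @return Data.frame with columns `time_h`, `confluence_pct`,
#'   `lipid_ros_ratio`, `dead_per_confluence`.
#' @export
predict_observables <- function(params, obs, init, times) {
  stopifnot(inherits(obs, "ferrodyn_obs"))
  tr <- simulate_model(params, init, times)
  data.frame(
    time_h = tr$time_h,
    confluence_pct = 100 * tr$n,
    lipid_ros_ratio = obs$ros_baseline + obs$ros_scale * tr$r,
    dead_per_confluence = ifelse(tr$n > 1e-12, tr$dead / tr$n, NA_real_))
}
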