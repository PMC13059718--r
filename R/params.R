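#' Model parameters for the growth/lipid-ROS feedback system
#'
#' Constructs and validates the full parameter vector of the feedback ODEs.
#' All rates are per hour; `n` is measured as a fraction of full confluence
#' and `r` in arbitrary ROS units set by the reporter calibration.
#'
#' The defaults are the package's canonical parameter set. They are chosen so
#' that the model is bistable (a ferroptosis-resistant state at full
#' confluence and zero lipid ROS, and a ferroptosis-sensitive state at low
#' confluence and high lipid ROS near (n = 0.21, r = 1.98)) and so that the
#' standard experimental phenotypes are reproduced: untreated populations
#' grow to confluence from all seeding densities, while GPX4 inhibition
#' (threshold lowered to 0.4 of control) kills populations seeded at low and
#' medium but not high density.
#'
#' @param alpha Basal per-capita division rate (1/h).
#' @param K Carrying capacity (confluence fraction).
#' @param beta Maximal per-capita ferroptotic death rate (1/h).
#' @param a Lipid ROS generated per cell division (ROS units).
#' @param b Lipid ROS clearance rate per molecule (1/h).
#' @param c Fenton autocatalysis rate (1/h). Must satisfy `b > c` so that net
#'   clearance stays positive and ROS remains bounded.
#' @param r0 Lipid ROS death threshold (ROS units); the Hill switch is at
#'   half-maximum there.
#' @param h Death-switch steepness (dimensionless, >= 1).
#' @param switch_form Either `"hill"` (smooth switch, default) or `"step"`
#'   (hard threshold indicator), kept for fidelity checks against the
#'   idealised threshold picture.
#' @return An object of class `ferrodyn_params` (a named list).
#' @export
#' @examples
#' p <- model_params()
#' p$r0
model_params <- function(alpha = 0.05, K = 1.0, beta = 0.045,
                         a = 0.5, b = 0.03, c = 0.02,
                         r0 = 1.2, h = 4,
                         switch_form = c("hill", "step")) {
  switch_form <- match.arg(switch_form)
  p <- list(alpha = alpha, K = K, beta = beta, a = a, b = b, c = c,
            r0 = r0, h = h, switch_form = switch_form)
  validate_model_params(p)
  structure(p, class = "ferrodyn_params")
}

validate_model_params <- function(p) {
  num <- c("alpha", "K", "beta", "a", "b", "c", "r0", "h")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      fd_stop_invalid(sprintf("parameter '%s' must be a single finite number", f))
    if (v < 0)
      fd_stop_invalid(sprintf("parameter '%s' must be >= 0", f))
  }
  if (p$K <= 0) fd_stop_invalid("carrying capacity K must be > 0")
  if (p$b <= p$c)
    fd_stop_invalid("clearance must exceed autocatalysis (b > c) for bounded ROS")
  if (p$h < 1) fd_stop_invalid("death-switch steepness h must be >= 1")
  invisible(p)
}

#' @export
print.ferrodyn_params <- function(x, ...) {
  cat("Feedback-model parameters (", x$switch_form, " death switch):\n", sep = "")
  v <- unlist(x[c("alpha", "K", "beta", "a", "b", "c", "r0", "h")])
  print(v)
  invisible(x)
}

#' Modify a subset of model parameters
#'
#' @param params A `ferrodyn_params` object.
#' @param ... Named fields to replace, e.g. `r0 = 0.5`.
#' @return A validated `ferrodyn_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "ferrodyn_params"))
  p <- modifyList(unclass(params), list(...))
  do.call(model_params, p)
}

#' Model state: confluence fraction and per-cell lipid ROS
#'
#' @param n Population size as a fraction of full confluence (>= 0).
#' @param r Average lipid ROS per live cell (ROS units, >= 0).
#' @return An object of class `ferrodyn_state` (named numeric of length 2).
#' @export
model_state <- function(n, r) {
  if (!is.numeric(n) || !is.numeric(r) || length(n) != 1L || length(r) != 1L ||
      !is.finite(n) || !is.finite(r))
    fd_stop_invalid("state components n and r must be single finite numbers")
  if (n < 0 || r < 0)
    fd_stop_invalid("state components n and r must be non-negative")
  structure(c(n = n, r = r), class = "ferrodyn_state")
}

as_state <- function(x) {
  if (inherits(x, "ferrodyn_state")) return(x)
  if (is.numeric(x) && length(x) == 2L) {
    nm <- names(x)
    if (!is.null(nm) && all(c("n", "r") %in% nm)) return(model_state(x[["n"]], x[["r"]]))
    return(model_state(x[[1L]], x[[2L]]))
  }
  fd_stop_invalid("cannot interpret input as a model state (need n and r)")
}

## serialization --------------------------------------------------------------

#' Read/write model parameters as flat JSON or YAML
#'
#' The on-disk representation is a flat mapping with exactly the field names
#' of [model_params()].
#'
#' @param params A `ferrodyn_params` object.
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `read_params` returns a `ferrodyn_params`; `write_params` the path,
#'   invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "ferrodyn_params"))
  ext <- tolower(file_ext(path))
  obj <- unclass(params)
  if (ext == "json") {
    atomic_write(path, function(tmp)
      write_json(obj, tmp, auto_unbox = TRUE, digits = NA))
  } else if (ext %in% c("yaml", "yml")) {
    atomic_write(path, function(tmp) write_yaml(obj, tmp))
  } else {
    fd_stop_schema(sprintf("unsupported parameter file extension '%s'", ext))
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  ext <- tolower(file_ext(path))
  obj <- if (ext == "json") read_json(path, simplifyVector = TRUE)
         else if (ext %in% c("yaml", "yml")) read_yaml(path)
         else fd_stop_schema(sprintf("unsupported parameter file extension '%s'", ext))
  known <- c("alpha", "K", "beta", "a", "b", "c", "r0", "h", "switch_form")
  bad <- setdiff(names(obj), known)
  if (length(bad))
    fd_stop_schema(paste0("unknown parameter field(s): ", paste(bad, collapse = ", ")))
  do.call(model_params, obj)
}
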