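## Ground-truth-known synthetic datasets emulating the standard experimental
## designs: three seeding densities, vehicle vs GPX4 inhibition, glucose vs
## galactose, restricted growth space, dose-per-confluence variants, 2-hour
## live-cell imaging sampling, replicate noise, and (optionally) rendered
## microscopy-like image frames.

#' Define a synthetic experimental scenario
#'
#' Treatments are represented as multipliers on the canonical parameters:
#' GPX4 inhibition lowers the lipid-ROS death threshold (`r0_multiplier < 1`,
#' default 0.4), a galactose-forced OXPHOS switch raises ROS production per
#' division (`a_multiplier > 1`, default 1.8), and restricted growth space
#' rescales the initial confluence (`space_factor = 2` for the same cells in
#' half the area).
#'
#' @param name Condition identifier.
#' @param seeding Seeding label (`"LD"`, `"MD"`, `"HD"`, or free-form).
#' @param n0 Initial confluence fraction in (0, 1) *before* the space factor
#'   is applied.
#' @param r_init Initial per-cell lipid ROS (default 0).
#' @param r0_multiplier,a_multiplier Treatment multipliers (> 0).
#' @param space_factor Initial-confluence rescaling for growth-space variants.
#' @param interval_h Sampling interval (hours; default 2, the imaging cadence).
#' @param duration_h Experiment duration (hours; default 72).
#' @param replicates Number of replicate wells (>= 1).
#' @param noise List with `confluence` (log-normal sigma of the multiplicative
#'   confluence noise), `ratio` (SD of the additive, zero-truncated Gaussian
#'   reporter-ratio noise), and `dead_count_scale` (expected dead counts per
#'   unit cumulative dead area; dead counts are Poisson).
#' @param seed Integer RNG seed.
#' @return An object of class `ferrodyn_scenario`.
#' @export
scenario <- function(name, seeding = "LD", n0 = 0.10, r_init = 0,
                     r0_multiplier = 1, a_multiplier = 1, space_factor = 1,
                     interval_h = 2, duration_h = 72, replicates = 3,
                     noise = list(confluence = 0.05, ratio = 0.05,
                                  dead_count_scale = 500),
                     seed = 1L) {
  if (n0 <= 0 || n0 >= 1) fd_stop_invalid("initial fraction n0 must be in (0, 1)")
  if (interval_h <= 0) fd_stop_invalid("sampling interval must be > 0")
  if (duration_h < interval_h) fd_stop_invalid("duration must cover >= 1 interval")
  if (replicates < 1) fd_stop_invalid("replicates must be >= 1")
  if (r0_multiplier <= 0 || a_multiplier <= 0 || space_factor <= 0)
    fd_stop_invalid("treatment multipliers must be > 0")
  noise <- modifyList(list(confluence = 0.05, ratio = 0.05,
                           dead_count_scale = 500), noise)
  if (noise$confluence < 0 || noise$ratio < 0 || noise$dead_count_scale <= 0)
    fd_stop_invalid("invalid noise parameters")
  structure(list(name = name, seeding = seeding, n0 = n0, r_init = r_init,
                 r0_multiplier = r0_multiplier, a_multiplier = a_multiplier,
                 space_factor = space_factor, interval_h = interval_h,
                 duration_h = duration_h, replicates = as.integer(replicates),
                 noise = noise, seed = as.integer(seed)),
            class = "ferrodyn_scenario")
}

#' Initial confluence fractions for the three seeding densities
#'
#' The plated cell counts translate to area fractions only approximately;
#' these values are the package's calibration of low, medium, and high
#' seeding density.
#'
#' @return Named numeric `c(LD = 0.10, MD = 0.22, HD = 0.48)`.
#' @export
seeding_fractions <- function() c(LD = 0.10, MD = 0.22, HD = 0.48)

#' Map an RSL3 dose per percent confluence to a threshold multiplier
#'
#' Graded GPX4 inhibition: the lipid-ROS death threshold is reduced by
#' `exp(-0.8 * dose)` for a dose in ng per percent confluence. The anchors
#' reproduce the reported dose-transfer phenotypes: at the high-density dose
#' (0.79 ng/%) low-density populations die while high-density ones survive,
#' and at the low-density dose (1.8 ng/%) death is the only long-term fate.
#'
#' @param dose_ng_per_pct Dose in ng per percent confluence (>= 0).
#' @return Threshold multiplier in (0, 1].
#' @export
dose_to_r0_multiplier <- function(dose_ng_per_pct) {
  if (any(dose_ng_per_pct < 0)) fd_stop_invalid("dose must be >= 0")
  exp(-0.8 * dose_ng_per_pct)
}

#' Preset scenarios covering the standard experimental designs
#'
#' All combinations of seeding density (LD/MD/HD), treatment (DMSO/RSL3),
#' sugar (glucose/galactose), and growth space (unrestricted/restricted),
#' named `"<seeding>_<treatment>_<sugar>[_restricted]"` (the glucose,
#' unrestricted defaults are omitted from the name), plus the
#' dose-per-confluence transfer variants `"LD_HDdose"`, `"HD_HDdose"`,
#' `"LD_LDdose"`, `"HD_LDdose"`.
#'
#' @param replicates,seed Passed to every [scenario()].
#' @return Named list of `ferrodyn_scenario` objects.
#' @export
preset_scenarios <- function(replicates = 3, seed = 1L) {
  fr <- seeding_fractions()
  out <- list()
  for (sd_lab in names(fr)) {
    for (trt in c("DMSO", "RSL3")) {
      for (sugar in c("glucose", "galactose")) {
        for (space in c("unrestricted", "restricted")) {
          nm <- paste0(sd_lab, "_", trt,
                       if (sugar == "galactose") "_galactose" else "",
                       if (space == "restricted") "_restricted" else "")
          out[[nm]] <- scenario(
            name = nm, seeding = sd_lab, n0 = fr[[sd_lab]],
            r0_multiplier = if (trt == "RSL3") 0.4 else 1,
            a_multiplier = if (sugar == "galactose") 1.8 else 1,
            space_factor = if (space == "restricted") 2 else 1,
            replicates = replicates, seed = seed)
        }
      }
    }
  }
  doses <- c(HDdose = 0.79, LDdose = 1.8)
  for (sd_lab in c("LD", "HD")) {
    for (dn in names(doses)) {
      nm <- paste0(sd_lab, "_", dn)
      out[[nm]] <- scenario(
        name = nm, seeding = sd_lab, n0 = fr[[sd_lab]],
        r0_multiplier = dose_to_r0_multiplier(doses[[dn]]),
        replicates = replicates, seed = seed)
    }
  }
  out
}

## apply scenario treatment multipliers to a parameter set
scenario_params <- function(scn, params = model_params()) {
  update_params(params,
                r0 = params$r0 * scn$r0_multiplier,
                a = params$a * scn$a_multiplier)
}

scenario_init <- function(scn, params) {
  model_state(min(scn$n0 * scn$space_factor, 0.999 * params$K), scn$r_init)
}

#' Generate a synthetic dataset for one or more scenarios
#'
#' For each scenario the true trajectory is integrated at the sampling times
#' `0, interval, 2*interval, ...`, converted to noiseless observables via
#' [predict_observables()], and then perturbed per replicate with the stated
#' noise model: multiplicative log-normal noise on confluence, additive
#' zero-truncated Gaussian noise on the reporter ratio, and Poisson dead
#' counts (`counts ~ Pois(dead_count_scale * D(t))`, normalised by the noisy
#' confluence). All randomness is drawn from the scenario seed(s), so
#' regeneration is deterministic.
#'
#' @param scenarios A [scenario()] or a list of them (condition id = name).
#' @param params Baseline [model_params()] the treatment multipliers act on.
#' @param obs An [observation_model()].
#' @return A `ferrodyn_synthetic`: list with `dataset` (noisy
#'   [timecourse_dataset()]), `noiseless` (exact observables per condition),
#'   `trajectories`, `true_params` (per condition), `obs`, `scenarios`.
#' @export
generate_dataset <- function(scenarios, params = model_params(),
                             obs = observation_model()) {
  if (inherits(scenarios, "ferrodyn_scenario")) scenarios <- list(scenarios)
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios))))
    names(scenarios) <- vapply(scenarios, `[[`, character(1), "name")
  rows <- list(); noiseless <- list(); trajs <- list(); true_p <- list()
  for (nm in names(scenarios)) {
    scn <- scenarios[[nm]]
    p <- scenario_params(scn, params)
    init <- scenario_init(scn, p)
    times <- seq(0, scn$duration_h, by = scn$interval_h)
    tr <- simulate_model(p, init, times)
    clean <- predict_observables(p, obs, init, times)
    trajs[[nm]] <- tr; noiseless[[nm]] <- clean; true_p[[nm]] <- p
    set.seed(scn$seed + match(nm, names(scenarios)) - 1L)
    for (rep_k in seq_len(scn$replicates)) {
      conf <- clean$confluence_pct *
        exp(rnorm(length(times), 0, scn$noise$confluence))
      conf <- pmin(conf, 100)
      ratio <- pmax(0, clean$lipid_ros_ratio +
                      rnorm(length(times), 0, scn$noise$ratio))
      if (scn$noise$confluence == 0 && scn$noise$ratio == 0) {
        dead <- clean$dead_per_confluence
      } else {
        counts <- rpois(length(times), scn$noise$dead_count_scale * tr$dead)
        dead <- (counts / scn$noise$dead_count_scale) / (conf / 100)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        condition = nm, replicate = rep_k,
        time_h = rep(times, 3L),
        observable = rep(observable_names(), each = length(times)),
        value = c(conf, ratio, dead))
    }
  }
  ds <- timecourse_dataset(
    do.call(rbind, rows),
    metadata = list(seeding = vapply(scenarios, `[[`, character(1), "seeding")))
  structure(list(dataset = ds, noiseless = noiseless, trajectories = trajs,
                 true_params = true_p, obs = obs, scenarios = scenarios),
            class = "ferrodyn_synthetic")
}

#' @export
print.ferrodyn_synthetic <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d condition(s), %d records\n",
              length(x$scenarios), nrow(x$dataset)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## image rendering

#' Render a microscopy-like frame for a model state
#'
#' Ellipse-shaped cells are placed with limited overlap until the live area
#' fraction matches `n` and the dead area fraction matches `dead_area`. Live
#' cells carry reduced-reporter intensity 1 and oxidized intensity equal to
#' the observation map of `r`; dead cells carry dead-marker intensity and an
#' elevated oxidized signal (their exclusion therefore matters for the live
#' ratio). A ground-truth label image (0 background, 1 live, 2 dead) is
#' attached.
#'
#' @param n Live area fraction requested.
#' @param r Per-cell lipid ROS encoded in the reporter channels.
#' @param dead_area Dead area fraction requested.
#' @param obs An [observation_model()].
#' @param dim Image edge length in pixels.
#' @param radius_px Range of cell semi-axes in pixels.
#' @param noise_sd Multiplicative intensity noise SD.
#' @param max_fill Packing limit; requesting `n + dead_area` beyond it errors.
#' @param seed RNG seed.
#' @param time_h Acquisition time recorded in the frame.
#' @return A [channel_frame()] with attributes `labels` (truth image) and
#'   `truth` (list of ground-truth fractions and ratio).
#' @export
render_frame <- function(n, r, dead_area = 0, obs = observation_model(),
                         dim = 512, radius_px = c(6, 10), noise_sd = 0.02,
                         max_fill = 0.8, seed = 1L, time_h = NA_real_) {
  if (n < 0 || dead_area < 0) fd_stop_invalid("area fractions must be >= 0")
  if (n + dead_area > max_fill)
    fd_stop_invalid(sprintf(
      "requested area fraction %.2f exceeds the packing limit %.2f",
      n + dead_area, max_fill))
  set.seed(seed)
  labels <- matrix(0L, dim, dim)
  npix <- dim * dim
  paint <- function(labels, target_frac, value) {
    target <- round(target_frac * npix)
    placed <- sum(labels == value)
    tries <- 0L
    while (placed < target && tries < 20000L) {
      tries <- tries + 1L
      cx <- runif(1, 1, dim); cy <- runif(1, 1, dim)
      ax <- runif(1, radius_px[1], radius_px[2])
      ay <- runif(1, radius_px[1], radius_px[2])
      th <- runif(1, 0, pi)
      x0 <- max(1L, floor(cx - max(ax, ay))); x1 <- min(dim, ceiling(cx + max(ax, ay)))
      y0 <- max(1L, floor(cy - max(ax, ay))); y1 <- min(dim, ceiling(cy + max(ax, ay)))
      xs <- x0:x1; ys <- y0:y1
      dx <- outer(xs - cx, rep(1, length(ys)))
      dy <- outer(rep(1, length(xs)), ys - cy)
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      inside <- (u / ax)^2 + (v / ay)^2 <= 1
      patch <- labels[xs, ys]
      overlap <- mean(patch[inside] != 0L)
      if (is.nan(overlap) || overlap > 0.3) next
      sel <- inside & patch == 0L
      add <- min(sum(sel), target - placed)
      if (add < sum(sel)) {
        ## trim the last cell so the painted fraction lands on the target
        idx <- which(sel)[seq_len(add)]
        sel[] <- FALSE; sel[idx] <- TRUE
      }
      patch[sel] <- value
      labels[xs, ys] <- patch
      placed <- placed + add
    }
    if (placed < target)
      fd_stop_numeric("could not reach the requested area fraction")
    labels
  }
  if (n > 0) labels <- paint(labels, n, 1L)
  if (dead_area > 0) labels <- paint(labels, dead_area, 2L)

  live <- labels == 1L; dead <- labels == 2L
  noisy <- function(base) base * exp(matrix(rnorm(npix, 0, noise_sd), dim, dim))
  ratio_live <- obs$ros_baseline + obs$ros_scale * r
  ox <- matrix(0, dim, dim); red <- matrix(0, dim, dim); dd <- matrix(0, dim, dim)
  red[live] <- 1; ox[live] <- ratio_live
  red[dead] <- 1; ox[dead] <- 2 * ratio_live + 0.5   # oxidised halo on dead cells
  dd[dead] <- 1
  ox <- noisy(ox); red <- noisy(red); dd <- noisy(dd)
  frame <- channel_frame(coverage = live | dead, dead = dd, ox = ox, red = red,
                         time_h = time_h)
  attr(frame, "labels") <- labels
  attr(frame, "truth") <- list(
    live_confluence = mean(live), dead_area_fraction = mean(dead),
    live_lipid_ros = ratio_live)
  frame
}

#' Render frames along a synthetic trajectory
#'
#' @param synthetic A `ferrodyn_synthetic` from [generate_dataset()].
#' @param condition Condition name (default: first).
#' @param times Subset of trajectory times to render (default: 5 evenly
#'   spaced frames).
#' @param ... Passed to [render_frame()] (image spec).
#' @return List of frames (with ground-truth attributes), one per time.
#' @export
render_frames <- function(synthetic, condition = NULL, times = NULL, ...) {
  stopifnot(inherits(synthetic, "ferrodyn_synthetic"))
  condition <- condition %||% names(synthetic$trajectories)[1]
  tr <- synthetic$trajectories[[condition]]
  if (is.null(tr)) fd_stop_invalid(sprintf("unknown condition '%s'", condition))
  if (is.null(times))
    times <- tr$time_h[unique(round(seq(1, nrow(tr), length.out = 5)))]
  scn <- synthetic$scenarios[[condition]]
  lapply(times, function(t0) {
    row <- tr[which.min(abs(tr$time_h - t0)), ]
    render_frame(n = row$n, r = row$r, dead_area = min(row$dead, 0.3),
                 obs = synthetic$obs,
                 seed = scn$seed + round(100 * t0), time_h = row$time_h, ...)
  })
}
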