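## Signal transforms from raw imaging/counting channels to model
## observables, and dead-cell mask exclusion on image frames.

#' Oxidized-to-reduced reporter ratio
#'
#' @param ox_signal,red_signal Non-negative signal(s); vectorised.
#' @return `ox_signal / red_signal`.
#' @export
#' @examples
#' oxred_ratio(2, 4)  # 0.5
oxred_ratio <- function(ox_signal, red_signal) {
  if (any(!is.finite(ox_signal)) || any(!is.finite(red_signal)) ||
      any(ox_signal < 0) || any(red_signal < 0))
    fd_stop_invalid("reporter signals must be finite and >= 0")
  if (any(red_signal == 0))
    fd_stop_invalid("reduced signal is zero: oxidized/reduced ratio undefined")
  ox_signal / red_signal
}

#' Dead-cell counts normalised to confluence
#'
#' Accounts for different starting densities by expressing dead counts per
#' percent confluence.
#'
#' @param dead_count,confluence_pct Non-negative; vectorised.
#' @return `dead_count / confluence_pct`.
#' @export
dead_to_confluence <- function(dead_count, confluence_pct) {
  if (any(!is.finite(dead_count)) || any(!is.finite(confluence_pct)) ||
      any(dead_count < 0) || any(confluence_pct < 0))
    fd_stop_invalid("inputs must be finite and >= 0")
  if (any(confluence_pct == 0))
    fd_stop_invalid("confluence is zero: normalised death undefined")
  dead_count / confluence_pct
}

#' Population doublings between seeding and counting
#'
#' `log2(cells counted) - log2(cells seeded)`; negative when the population
#' shrank.
#'
#' @param cells_seeded,cells_counted Positive counts; vectorised.
#' @return Number of doublings.
#' @export
population_doublings <- function(cells_seeded, cells_counted) {
  if (any(!is.finite(cells_seeded)) || any(!is.finite(cells_counted)) ||
      any(cells_seeded <= 0) || any(cells_counted <= 0))
    fd_stop_invalid("cell counts must be finite and > 0")
  log2(cells_counted) - log2(cells_seeded)
}

#' Normalise fluorescence intensities to a per-replicate reference
#'
#' Mirrors the flow-cytometry convention of expressing mean fluorescence
#' intensity relative to a reference group within each replicate (so the
#' reference entry maps to 1 in every replicate).
#'
#' @param values Numeric intensities.
#' @param group Group label per value (e.g. density x time).
#' @param replicate Replicate label per value.
#' @param reference The group used as the denominator.
#' @return `values` divided by their replicate's reference value.
#' @export
mfi_normalize <- function(values, group, replicate, reference) {
  if (length(values) != length(group) || length(values) != length(replicate))
    fd_stop_invalid("values, group, and replicate must have equal length")
  out <- numeric(length(values))
  for (rep_id in unique(replicate)) {
    sel <- replicate == rep_id
    ref <- values[sel & group == reference]
    if (length(ref) != 1L || !is.finite(ref) || ref <= 0)
      fd_stop_invalid(sprintf(
        "replicate '%s' needs exactly one positive reference value", rep_id))
    out[sel] <- values[sel] / ref
  }
  out
}

## ---------------------------------------------------------------------------
## image frames and dead-cell exclusion

#' Multi-channel image frame
#'
#' @param coverage Logical matrix: pixels covered by cells.
#' @param dead Dead-cell marker intensity image (>= 0).
#' @param ox,red Oxidized and reduced reporter intensity images (>= 0).
#' @param pixel_size_um Optional pixel edge length in micrometres.
#' @param time_h Optional acquisition time (hours).
#' @return An object of class `ferrodyn_frame`.
#' @export
channel_frame <- function(coverage, dead, ox, red, pixel_size_um = NA_real_,
                          time_h = NA_real_) {
  coverage <- coverage > 0
  dims <- dim(coverage)
  for (ch in list(dead = dead, ox = ox, red = red)) {
    if (!identical(dim(ch), dims))
      fd_stop_invalid("all channels must share the same dimensions")
  }
  if (any(dead < 0) || any(ox < 0) || any(red < 0))
    fd_stop_invalid("channel intensities must be >= 0")
  structure(list(coverage = coverage, dead = dead, ox = ox, red = red,
                 pixel_size_um = pixel_size_um, time_h = time_h),
            class = "ferrodyn_frame")
}

## structuring element: discrete disk, pixels with dx^2 + dy^2 <= radius^2
disk_kernel <- function(radius) {
  ix <- seq(-radius, radius)
  outer(ix, ix, function(x, y) as.numeric(x^2 + y^2 <= radius^2))
}

#' Dead-cell mask from the dead-marker channel
#'
#' Thresholds the dead-marker channel and morphologically dilates the result
#' by a discrete disk, so that the halo of reporter signal around a dead
#' cell is excluded along with the cell itself. The dilated mask is always a
#' superset of the plain threshold mask.
#'
#' @param frame A [channel_frame()].
#' @param threshold Intensity threshold, or `"otsu"` for an automatic
#'   Otsu threshold on the dead channel.
#' @param dilation_radius Dilation radius in pixels (>= 0; 0 disables
#'   dilation).
#' @return Logical matrix.
#' @export
dead_mask <- function(frame, threshold = "otsu", dilation_radius = 3) {
  stopifnot(inherits(frame, "ferrodyn_frame"))
  if (dilation_radius < 0) fd_stop_invalid("dilation radius must be >= 0")
  dead <- frame$dead
  if (identical(threshold, "otsu")) {
    mx <- max(dead)
    if (mx == 0) return(matrix(FALSE, nrow(dead), ncol(dead)))
    threshold <- EBImage::otsu(EBImage::Image(dead / mx), range = c(0, 1)) * mx
  }
  m <- dead > threshold
  if (!any(m) || dilation_radius == 0) return(m)
  storage.mode(m) <- "integer"
  out <- EBImage::dilate(EBImage::Image(m), disk_kernel(dilation_radius))
  matrix(EBImage::imageData(out) > 0, nrow(dead), ncol(dead))
}

#' Live-cell measurements with dead-cell exclusion
#'
#' The live mask is `coverage AND NOT dead_mask`; live confluence is the
#' live-pixel fraction of the whole image; the live lipid-ROS ratio is the
#' oxidized channel sum divided by the reduced channel sum within the live
#' mask (sum-then-divide, robust to zero-intensity pixels); cellular lipid
#' ROS divides that ratio by the live confluence, averaging the signal over
#' the live population. Dead pixels contribute nothing to live statistics.
#'
#' @inheritParams dead_mask
#' @return A `ferrodyn_live_measurement`: list with `live_confluence`,
#'   `live_lipid_ros`, `cellular_lipid_ros`, `dead_area_fraction`, and a
#'   logical `undefined` flag (set when the live mask is empty, in which
#'   case the ratio fields are `NA`).
#' @export
live_cell_measurement <- function(frame, threshold = "otsu",
                                  dilation_radius = 3) {
  stopifnot(inherits(frame, "ferrodyn_frame"))
  dm <- dead_mask(frame, threshold, dilation_radius)
  live <- frame$coverage & !dm
  live_confluence <- mean(live)
  dead_area_fraction <- mean(frame$coverage & dm)
  if (!any(live)) {
    out <- list(live_confluence = 0, live_lipid_ros = NA_real_,
                cellular_lipid_ros = NA_real_,
                dead_area_fraction = dead_area_fraction, undefined = TRUE)
    return(structure(out, class = "ferrodyn_live_measurement"))
  }
  red_sum <- sum(frame$red[live])
  ratio <- if (red_sum > 0) sum(frame$ox[live]) / red_sum else NA_real_
  structure(list(
    live_confluence = live_confluence,
    live_lipid_ros = ratio,
    cellular_lipid_ros = if (is.na(ratio)) NA_real_ else ratio / live_confluence,
    dead_area_fraction = dead_area_fraction,
    undefined = is.na(ratio)),
    class = "ferrodyn_live_measurement")
}

#' @export
print.ferrodyn_live_measurement <- function(x, ...) {
  cat(sprintf(paste0("live confluence %.3f | live ox/red %.3f | ",
                     "cellular lipid ROS %.3f | dead area %.3f%s\n"),
              x$live_confluence, x$live_lipid_ros, x$cellular_lipid_ros,
              x$dead_area_fraction,
              if (x$undefined) " [ratios undefined]" else ""))
  invisible(x)
}
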