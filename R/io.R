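## Format readers/writers. CSV dialect: comma-separated, UTF-8, "." decimal,
## mandatory header, floats at 10 significant digits (bit-stable diffs).

atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", file_ext(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) fd_stop_numeric(sprintf("cannot write '%s'", path))
  invisible(path)
}

fmt10 <- function(x) {
  if (is.numeric(x)) formatC(x, digits = 10, format = "g") else x
}

write_csv10 <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt10), stringsAsFactors = FALSE)
  atomic_write(path, function(tmp)
    write.csv(out, tmp, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8"))
}

#' Read/write a trajectory as CSV
#'
#' Columns `time_h`, `n`, `r` (plus `dead` when present).
#'
#' @param trajectory A `ferrodyn_trajectory` from [simulate_model()].
#' @param path CSV file path.
#' @return The path / a data.frame.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  write_csv10(as.data.frame(trajectory), path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  need <- c("time_h", "n", "r")
  miss <- setdiff(need, names(df))
  if (length(miss))
    fd_stop_schema(paste0("trajectory CSV missing column(s): ",
                          paste(miss, collapse = ", ")))
  df
}

#' Read/write a tidy time-course dataset as CSV
#'
#' Columns `condition`, `replicate`, `time_h`, `observable`, `value`.
#'
#' @param dataset A [timecourse_dataset()].
#' @param path CSV file path.
#' @export
write_dataset_csv <- function(dataset, path) {
  write_csv10(as.data.frame(dataset), path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- tryCatch(read.csv(path, fileEncoding = "UTF-8"),
                 error = function(e) fd_stop_schema(paste0(
                   "cannot parse CSV '", path, "': ", conditionMessage(e))))
  timecourse_dataset(df)
}

#' Write a basin grid as CSV plus a JSON attractor table
#'
#' The CSV holds one row per grid node (`r`, `n`, `label`; unresolved nodes
#' have an empty label); the JSON sidecar (same path with extension
#' `.attractors.json`) lists the attractors with their classification.
#'
#' @param basins A `ferrodyn_basins` from [compute_basins()].
#' @param path CSV file path.
#' @export
write_basins_csv <- function(basins, path) {
  stopifnot(inherits(basins, "ferrodyn_basins"))
  g <- expand.grid(r = basins$r_axis, n = basins$n_axis)
  g$label <- as.vector(basins$labels)
  write_csv10(g, path)
  att <- basins$attractors
  sidecar <- sub("\\.csv$", ".attractors.json", path)
  atomic_write(sidecar, function(tmp)
    write_json(list(
      attractors = data.frame(index = seq_len(nrow(att)), n = att$n, r = att$r,
                              classification = att$classification),
      unresolved_fraction = basins$unresolved_fraction),
      tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' @rdname write_basins_csv
#' @export
read_basins_csv <- function(path) {
  g <- read.csv(path, fileEncoding = "UTF-8")
  need <- c("r", "n", "label")
  if (length(setdiff(need, names(g))))
    fd_stop_schema("basin CSV must have columns r, n, label")
  g
}

#' Write/read multi-channel image frames as TIFF with a JSON sidecar
#'
#' Channel order in the stack: coverage, dead, oxidized, reduced. The JSON
#' sidecar (`<path>.json`) records times and pixel size.
#'
#' @param frames List of [channel_frame()] objects.
#' @param path TIFF file path.
#' @export
write_frames_tiff <- function(frames, path) {
  pages <- unlist(lapply(frames, function(f) {
    mx <- max(1, max(f$dead), max(f$ox), max(f$red))
    list(matrix(as.numeric(f$coverage), nrow(f$coverage)),
         f$dead / mx, f$ox / mx, f$red / mx)
  }), recursive = FALSE)
  atomic_write(path, function(tmp)
    tiff::writeTIFF(pages, tmp, bits.per.sample = 32L))
  scales <- vapply(frames, function(f)
    max(1, max(f$dead), max(f$ox), max(f$red)), numeric(1))
  atomic_write(paste0(path, ".json"), function(tmp)
    write_json(list(
      n_frames = length(frames),
      channels = c("coverage", "dead", "ox", "red"),
      intensity_scale = scales,
      time_h = vapply(frames, function(f) f$time_h, numeric(1)),
      pixel_size_um = vapply(frames, function(f) f$pixel_size_um, numeric(1))),
      tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' @rdname write_frames_tiff
#' @export
read_frames_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (length(pages) != 4L * meta$n_frames)
    fd_stop_schema("TIFF page count does not match the sidecar metadata")
  lapply(seq_len(meta$n_frames), function(i) {
    off <- 4L * (i - 1L)
    sc <- meta$intensity_scale[i]
    channel_frame(coverage = pages[[off + 1L]] > 0.5,
                  dead = pages[[off + 2L]] * sc,
                  ox = pages[[off + 3L]] * sc,
                  red = pages[[off + 4L]] * sc,
                  pixel_size_um = meta$pixel_size_um[i],
                  time_h = meta$time_h[i])
  })
}
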