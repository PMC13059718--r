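## Tidy time-course container shared by the fitting and synthetic-data
## modules. Long format: one row per (condition, replicate, time, observable).

#' Validate a tidy time-course dataset
#'
#' @param df Data.frame with columns `condition`, `replicate`, `time_h`,
#'   `observable`, `value`. Observables must be among [observable_names()],
#'   times non-negative, `confluence_pct` within `[0, 100]`,
#'   `lipid_ros_ratio` non-negative, and every (condition, replicate,
#'   observable) series must have at least two distinct times.
#' @param metadata Optional named list (seeding label, treatment tags, ...).
#' @return The validated data.frame with class `ferrodyn_dataset`.
#' @export
timecourse_dataset <- function(df, metadata = list()) {
  need <- c("condition", "replicate", "time_h", "observable", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    fd_stop_schema(paste0("dataset is missing column(s): ",
                          paste(miss, collapse = ", ")))
  if (!is.numeric(df$time_h) || any(!is.finite(df$time_h)) || any(df$time_h < 0))
    fd_stop_schema("time_h must be finite and non-negative")
  bad <- setdiff(unique(df$observable), observable_names())
  if (length(bad))
    fd_stop_schema(paste0("unknown observable(s): ", paste(bad, collapse = ", ")))
  if (!is.numeric(df$value) || any(!is.finite(df$value)))
    fd_stop_schema("value must be finite numeric")
  conf <- df$value[df$observable == "confluence_pct"]
  if (length(conf) && (any(conf < 0) || any(conf > 100)))
    fd_stop_schema("confluence_pct must lie in [0, 100]")
  ratio <- df$value[df$observable == "lipid_ros_ratio"]
  if (length(ratio) && any(ratio < 0))
    fd_stop_schema("lipid_ros_ratio must be >= 0")
  ntimes <- tapply(df$time_h,
                   interaction(df$condition, df$replicate, df$observable,
                               drop = TRUE),
                   function(t) length(unique(t)))
  if (any(ntimes < 2L))
    fd_stop_schema("every fitted series needs >= 2 distinct times")
  structure(as.data.frame(df), metadata = metadata,
            class = c("ferrodyn_dataset", "data.frame"))
}

#' @export
print.ferrodyn_dataset <- function(x, ...) {
  cat(sprintf("Time-course dataset: %d records, %d condition(s), %d replicate(s)\n",
              nrow(x), length(unique(x$condition)),
              length(unique(x$replicate))))
  NextMethod()
}
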