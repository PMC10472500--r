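# Plain-text serialization of recordings. The on-disk layout mirrors a
# grouped container: a directory holding `meta.json` (configuration,
# including the master seed), `trials.csv` (columnar trial table), and
# `data.csv` (float64 samples in long-by-trial/channel layout). Text formats
# keep datasets diffable and dependency-free.

#' Write a recording to a directory
#'
#' Creates (or reuses) `path` and writes three files: `meta.json` with the
#' provenance/config list (including the seed) plus array dimensions,
#' `trials.csv` with the trial table, and `data.csv` with one row per
#' (trial, channel) and one column per time sample.
#'
#' @param rec an [lfp_recording()] object.
#' @param path directory to write into.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "lfp_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(rec$data)
  meta <- list(
    time_step_ms = rec$time_step_ms,
    channel_positions_mm = rec$channel_positions_mm,
    dims = list(n_trials = d[1], n_channels = d[2], n_time = d[3]),
    provenance = rec$provenance
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(rec$trials, file.path(path, "trials.csv"))
  flat <- matrix(aperm(rec$data, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
  idx <- expand.grid(channel = seq_len(d[2]), trial = seq_len(d[1]))[, 2:1]
  df <- cbind(idx, as.data.frame(flat))
  names(df) <- c("trial", "channel", paste0("t", seq_len(d[3])))
  readr::write_csv(tibble::as_tibble(df), file.path(path, "data.csv"))
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path directory containing `meta.json`, `trials.csv`, `data.csv`.
#' @return an [lfp_recording()] object.
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  trials <- readr::read_csv(file.path(path, "trials.csv"), show_col_types = FALSE)
  df <- readr::read_csv(file.path(path, "data.csv"), show_col_types = FALSE)
  d <- unlist(meta$dims)
  if (nrow(df) != d[["n_trials"]] * d[["n_channels"]]) {
    stop("data.csv row count does not match recorded dimensions", call. = FALSE)
  }
  ord <- order(df$trial, df$channel)
  flat <- as.matrix(df[ord, -(1:2)])
  data <- aperm(array(t(flat), dim = c(d[["n_time"]], d[["n_channels"]],
                                       d[["n_trials"]])), c(3, 2, 1))
  lfp_recording(
    data = data,
    time_step_ms = meta$time_step_ms,
    channel_positions_mm = meta$channel_positions_mm,
    trials = trials,
    provenance = meta$provenance
  )
}
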