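#' Write a recording bundle
#'
#' Serializes a `recording_session` (and, optionally, its ground truth)
#' as a directory: `meta.json` with the acquisition metadata and channel
#' table, `signals.csv` with one row per channel (mV), and `truth.json`
#' when a `synthetic_recording` is given.
#'
#' @param x a `recording_session` or `synthetic_recording`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording_bundle <- function(x, dir) {
  truth <- NULL
  if (inherits(x, "synthetic_recording")) {
    truth <- list(onsets_ms = x$truth_onsets, amplitudes_mv = x$truth_amplitudes,
                  mechanism = unclass(x$truth_mechanism))
    x <- x$session
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(fs_hz = x$fs, band_hz = x$band, qrs_onsets_ms = x$qrs_onsets_ms,
               beat_types = x$beat_types, pacing_onsets_ms = x$pacing_onsets_ms,
               spacing_mm = x$grid$spacing_mm, layers = x$grid$layers,
               channel_table = data.frame(channel = x$channel_map$site,
                                          needle = x$channel_map$needle,
                                          layer = x$channel_map$layer,
                                          x_mm = x$grid$sites$x, y_mm = x$grid$sites$y),
               needle_xy_mm = x$grid$needle_xy)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(x$signals, file.path(dir, "signals.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a recording bundle
#'
#' Inverse of [write_recording_bundle()]; reconstructs the
#' `recording_session` (grid geometry included) from `meta.json` and
#' `signals.csv`.
#'
#' @param dir bundle directory.
#' @return a `recording_session`; if `truth.json` exists it is attached
#'   as attribute `"truth"`.
#' @export
read_recording_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  signals <- as.matrix(utils::read.csv(file.path(dir, "signals.csv"), header = FALSE))
  dimnames(signals) <- NULL
  grid <- make_grid(n_needles = nrow(meta$needle_xy_mm), spacing_mm = meta$spacing_mm,
                    layers = meta$layers, positions = meta$needle_xy_mm)
  session <- structure(list(signals = signals, fs = meta$fs_hz, band = meta$band_hz,
                            grid = grid,
                            channel_map = data.frame(site = meta$channel_table$channel,
                                                     needle = meta$channel_table$needle,
                                                     layer = meta$channel_table$layer),
                            qrs_onsets_ms = meta$qrs_onsets_ms,
                            beat_types = meta$beat_types,
                            pacing_onsets_ms = meta$pacing_onsets_ms,
                            duration_ms = ncol(signals) * 1000 / meta$fs_hz),
                       class = "recording_session")
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf))
    attr(session, "truth") <- jsonlite::read_json(tf, simplifyVector = TRUE)
  session
}

#' Write detected events to CSV
#'
#' @param events events data.frame from [detect_session()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events[, c("beat", "channel", "needle", "layer", "time_ms",
                              "mode", "good", "amplitude_mv", "missing")],
                   path, row.names = FALSE)
  invisible(path)
}
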