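#' Local electrogram interval around the dominant deflection
#'
#' Finds the activation complex of one beat: the anchor is the max
#' |dV/dt| within a window 30 ms before to 80 ms after the surface QRS
#' onset; the interval end proceeds forward from the anchor to the first
#' sample inside the isoelectric band (|v| below 3x the baseline noise
#' SD, estimated from the diastolic segment preceding the window); the
#' start proceeds backward to the first sample where the local |slope|
#' falls below `slope_factor` times the tracing's mean |slope|.
#'
#' @param x sample vector (mV) for the channel.
#' @param fs sampling rate (Hz).
#' @param qrs_onset_ms surface QRS onset (ms from record start).
#' @param slope_factor backward-stop fraction of the mean absolute slope.
#' @param window_ms search window around QRS onset (ms).
#' @return list of class `local_interval`: `start_ms`, `end_ms`,
#'   `anchor_ms`, `anchor_dvdt` (mV/ms), `v_pp_mv` (max positive minus
#'   max negative voltage inside the interval).
#' @export
local_interval <- function(x, fs, qrs_onset_ms, slope_factor = 0.1,
                           window_ms = c(-30, 80)) {
  i0 <- ms_to_idx(qrs_onset_ms + window_ms[1], fs)
  i1 <- ms_to_idx(qrs_onset_ms + window_ms[2], fs)
  if (i0 < 1L || i1 > length(x)) stop("search window outside the recorded span")
  dv <- dvdt(x, fs)
  j <- argmax_absdvdt(dv, i0, i1)
  # isoelectric band from the diastolic segment before the window
  base <- x[max(1L, i0 - ms_to_idx(50, fs)):max(1L, i0 - 1L)]
  iso <- 3 * max(stats::sd(base), 1e-6)
  if (max(abs(x[i0:i1])) < 5 * max(stats::sd(base), 1e-6))
    stop("no-deflection: tracing is flat within the search window")
  # forward to the isoelectric line: past the whole deflection, i.e. to the
  # first sample where the signal stays inside the band for the next 5 ms
  look <- ms_to_idx(5, fs)
  e <- j
  while (e < length(x) && max(abs(x[e:min(e + look, length(x))])) > iso) e <- e + 1L
  # backward until the local slope drops below slope_factor * mean |slope|
  mean_slope <- mean(abs(dv))
  s <- j
  while (s > 1L && abs(dv[s]) >= slope_factor * mean_slope) s <- s - 1L
  seg <- x[s:e]
  structure(list(start_ms = idx_to_ms(s, fs), end_ms = idx_to_ms(e, fs),
                 anchor_ms = idx_to_ms(j, fs), anchor_dvdt = dv[j],
                 v_pp_mv = max(seg, 0) - min(seg, 0)),
            class = "local_interval")
}

#' Measure the maximal total voltage of one site
#'
#' Convenience wrapper: [local_interval()] then the peak-to-peak voltage
#' and maximum slope inside it, the two quantities the ischemia criterion
#' compares across occlusion.
#'
#' @inheritParams local_interval
#' @return list with `v_pp_mv`, `max_dvdt`, `interval`.
#' @export
measure_local_voltage <- function(x, fs, qrs_onset_ms, slope_factor = 0.1,
                                  window_ms = c(-30, 80)) {
  iv <- local_interval(x, fs, qrs_onset_ms, slope_factor, window_ms)
  list(v_pp_mv = iv$v_pp_mv, max_dvdt = abs(iv$anchor_dvdt), interval = iv)
}

#' Classify a site as ischemic from pre/post-occlusion voltages
#'
#' A site is ischemic when its maximal total voltage drops by at least
#' 45% from before to after coronary occlusion. When the drop is
#' borderline (within `borderline_band`, default 40-45%), ischemia is
#' confirmed by an additional 45% or greater decrease in the maximum
#' slope (`borderline-confirmed`, which counts as ischemic). Otherwise
#' the site is non-ischemic.
#'
#' @param v_pre_mv,v_post_mv peak-to-peak voltages before/after occlusion.
#' @param dvdt_pre,dvdt_post optional maximum slopes for the borderline
#'   confirmation path.
#' @param drop_threshold voltage-drop fraction for outright ischemia.
#' @param borderline_band drop interval `[lo, hi)` that triggers the
#'   dV/dt confirmation.
#' @param dvdt_threshold slope-drop fraction confirming borderline sites.
#' @return list of class `ischemia_call`: `v_pre_mv`, `v_post_mv`,
#'   `drop_frac`, `dvdt_drop_frac` (or `NA`), `status` in
#'   `c("ischemic", "borderline-confirmed", "non-ischemic")`,
#'   `is_ischemic` (TRUE for both ischemic statuses).
#' @export
classify_ischemia <- function(v_pre_mv, v_post_mv, dvdt_pre = NULL, dvdt_post = NULL,
                              drop_threshold = 0.45, borderline_band = c(0.40, 0.45),
                              dvdt_threshold = 0.45) {
  if (v_pre_mv < 0 || v_post_mv < 0) stop("voltages must be nonnegative")
  if (v_pre_mv == 0) stop("undefined-site: zero pre-occlusion voltage")
  drop <- 1 - v_post_mv / v_pre_mv
  dvdt_drop <- if (!is.null(dvdt_pre) && !is.null(dvdt_post) && dvdt_pre > 0)
    1 - dvdt_post / dvdt_pre else NA_real_
  eps <- 1e-12  # "at least 45%" must hold at exactly 45% despite rounding
  status <- if (drop >= drop_threshold - eps) {
    "ischemic"
  } else if (drop >= borderline_band[1] - eps && drop < borderline_band[2] - eps &&
             is.finite(dvdt_drop) && dvdt_drop >= dvdt_threshold - eps) {
    "borderline-confirmed"
  } else "non-ischemic"
  structure(list(v_pre_mv = v_pre_mv, v_post_mv = v_post_mv, drop_frac = drop,
                 dvdt_drop_frac = dvdt_drop, status = status,
                 is_ischemic = status != "non-ischemic"),
            class = "ischemia_call")
}
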