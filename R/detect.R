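#' Detection configuration
#'
#' Parameters of the max-dV/dt onset detector, defaulting to the
#' acquisition-matched values: 50-sample boxcar smoothing, 120 ms
#' good-channel onset spacing, 60% amplitude clause, +/-20 ms good-channel
#' peak window, (-40, +80) ms intracardiac and (+15, +150) ms pacing
#' class windows, +/-8 ms raw refinement around the smoothed maximum, and
#' the 65 ms refractory rule with its 80 ms recalculation window.
#'
#' @param smooth_window_samples boxcar length (samples).
#' @param good_spacing_ms max onset-to-onset gap for a good channel (ms).
#' @param good_amp_frac amplitude clause: every per-beat peak must exceed
#'   this fraction of the channel's average per-beat maximum.
#' @param good_peak_window_ms half-window around the peak amplitude used
#'   for good channels and their neighbors (ms).
#' @param intracardiac_window_ms class window relative to the reference
#'   for non-paced beats (ms).
#' @param pacing_window_ms class window relative to the pacing onset (ms).
#' @param refine_ms raw-signal refinement half-window (ms).
#' @param refractory_ms minimum gap between consecutive events on one
#'   channel (ms).
#' @param recalc_window_ms length of the recalculation window starting
#'   `refractory_ms` after the previous event (ms).
#' @param min_amplitude_mv peak amplitude below which a channel-beat is
#'   flagged missing rather than detected.
#' @param min_slope_mv_per_ms slope below which a recalculation window is
#'   considered empty of deflections.
#' @return object of class `detection_config`.
#' @export
detect_config <- function(smooth_window_samples = 50L, good_spacing_ms = 120,
                          good_amp_frac = 0.60, good_peak_window_ms = 20,
                          intracardiac_window_ms = c(-40, 80),
                          pacing_window_ms = c(15, 150), refine_ms = 8,
                          refractory_ms = 65, recalc_window_ms = 80,
                          min_amplitude_mv = 0.1, min_slope_mv_per_ms = 0.1) {
  cfg <- list(smooth_window_samples = as.integer(smooth_window_samples),
              good_spacing_ms = good_spacing_ms, good_amp_frac = good_amp_frac,
              good_peak_window_ms = good_peak_window_ms,
              intracardiac_window_ms = intracardiac_window_ms,
              pacing_window_ms = pacing_window_ms, refine_ms = refine_ms,
              refractory_ms = refractory_ms, recalc_window_ms = recalc_window_ms,
              min_amplitude_mv = min_amplitude_mv,
              min_slope_mv_per_ms = min_slope_mv_per_ms)
  if (any(unlist(cfg[c("smooth_window_samples", "good_spacing_ms", "good_amp_frac",
                       "good_peak_window_ms", "refine_ms", "refractory_ms",
                       "recalc_window_ms")]) <= 0))
    stop("configuration values must be positive")
  structure(cfg, class = "detection_config")
}

#' Centered moving-average smoothing
#'
#' Boxcar smoothing with 'same' alignment; edge windows shrink to the
#' available samples. `window = 1` is the identity.
#'
#' @param x sample vector.
#' @param window averaging window length (samples).
#' @return smoothed vector, same length as `x`.
#' @export
smooth_signal <- function(x, window = 50L) {
  n <- length(x)
  if (!n) stop("empty input")
  window <- as.integer(window)
  if (window < 1L || window > n) stop("window must be in [1, length(x)]")
  if (window == 1L) return(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - (ceiling(window / 2) - 1L))
  hi <- pmin(n, i + floor(window / 2))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Flag good channels
#'
#' A channel is "good" when every gap between its consecutive onsets is
#' at most `good_spacing_ms` and every per-beat peak amplitude exceeds
#' `good_amp_frac` times the channel's average per-beat maximum.
#' Single-beat channels are evaluated on the amplitude clause alone.
#'
#' @param events_per_beat data.frame with columns `channel`, `onset_ms`
#'   (absolute), `amplitude_mv` (per-beat peak).
#' @param config a [detect_config()].
#' @return named logical vector, one flag per channel.
#' @export
flag_good_channels <- function(events_per_beat, config = detect_config()) {
  stopifnot(all(c("channel", "onset_ms", "amplitude_mv") %in% names(events_per_beat)))
  by_ch <- split(events_per_beat, events_per_beat$channel)
  vapply(by_ch, function(d) {
    ok <- is.finite(d$onset_ms)
    if (!any(ok)) return(FALSE)
    t_ <- sort(d$onset_ms[ok]); a <- d$amplitude_mv[ok]
    gap_ok <- length(t_) < 2L || all(diff(t_) <= config$good_spacing_ms)
    amp_ok <- all(a > config$good_amp_frac * mean(a))
    gap_ok && amp_ok
  }, logical(1))
}

# class window (absolute ms) for one channel-beat
beat_window <- function(session, beat, config, reference_ms = NULL) {
  type <- session$beat_types[beat]
  if (type == "paced") {
    p <- session$pacing_onsets_ms[beat]
    c(p + config$pacing_window_ms[1], p + config$pacing_window_ms[2])
  } else {
    ref <- if (is.null(reference_ms)) session$qrs_onsets_ms[beat] else reference_ms
    c(ref + config$intracardiac_window_ms[1], ref + config$intracardiac_window_ms[2])
  }
}

ms_to_idx <- function(ms, fs) as.integer(round(ms * fs / 1000)) + 1L
idx_to_ms <- function(idx, fs) (idx - 1L) * 1000 / fs

# preliminary per-beat raw detection used to establish good channels:
# raw max |dV/dt| and peak amplitude within the QRS-referenced class window
prelim_events <- function(session, config) {
  fs <- session$fs
  nch <- nrow(session$signals)
  out <- vector("list", length(session$qrs_onsets_ms))
  for (b in seq_along(session$qrs_onsets_ms)) {
    win <- beat_window(session, b, config)
    i0 <- ms_to_idx(win[1], fs); i1 <- ms_to_idx(win[2], fs)
    i0c <- max(1L, i0); i1c <- min(ncol(session$signals), i1)
    rows <- lapply(seq_len(nch), function(ch) {
      if (i0c > i1c) return(data.frame(channel = ch, beat = b, onset_ms = NA_real_,
                                       amplitude_mv = 0))
      seg <- session$signals[ch, i0c:i1c]
      dv <- dvdt(session$signals[ch, ], fs)
      j <- argmax_absdvdt(dv, i0c, i1c)
      data.frame(channel = ch, beat = b, onset_ms = idx_to_ms(j, fs),
                 amplitude_mv = max(abs(seg)))
    })
    out[[b]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Detect all activation onsets for one beat
#'
#' Implements the template-based max-dV/dt scheme. Good channels and
#' their neighbors (same or grid-adjacent needle) are detected as the raw
#' max |dV/dt| within `good_peak_window_ms` of the channel's peak
#' amplitude (mode `raw_dvdt`). All other channels are detected as the
#' max |dV/dt| of the boxcar-smoothed signal within the class window —
#' (-40, +80) ms around the reference for intracardiac beats (the median
#' good-channel onset on the needle when available, else the surface QRS
#' onset) or +15 to +150 ms after the pacing onset for paced beats — then
#' refined to the raw max |dV/dt| within `refine_ms` of the smoothed
#' maximum (mode `smoothed_refined`). VF beats are always detected raw.
#'
#' @param session a `recording_session`.
#' @param beat beat (QRS trigger) index.
#' @param config a [detect_config()].
#' @param good optional precomputed logical good-channel vector;
#'   recomputed from the whole session when omitted.
#' @return data.frame with one row per channel: `channel`, `needle`,
#'   `layer`, `beat`, `time_ms` (relative to the beat's QRS onset),
#'   `abs_ms`, `mode`, `good`, `amplitude_mv`, `missing`.
#' @export
detect_all_onsets <- function(session, beat, config = detect_config(), good = NULL) {
  fs <- session$fs
  nch <- nrow(session$signals)
  nsamp <- ncol(session$signals)
  cmap <- session$channel_map
  is_vf <- session$beat_types[beat] == "vf"
  if (is.null(good)) {
    prelim <- prelim_events(session, config)
    good <- flag_good_channels(prelim, config)
    good <- unname(good[order(as.integer(names(good)))])
  }
  adjn <- needle_adjacency(session$grid)
  good_needles <- unique(cmap$needle[good])
  neighbor <- cmap$needle %in% good_needles |
    vapply(cmap$needle, function(nd) any(adjn[nd, good_needles]), logical(1))
  use_template <- (good | neighbor) & !is_vf

  qrs <- session$qrs_onsets_ms[beat]
  res <- data.frame(channel = seq_len(nch), needle = cmap$needle, layer = cmap$layer,
                    beat = beat, time_ms = NA_real_, abs_ms = NA_real_,
                    mode = NA_character_, good = good, amplitude_mv = NA_real_,
                    missing = FALSE, stringsAsFactors = FALSE)

  detect_one <- function(ch, win, mode) {
    i0 <- max(1L, ms_to_idx(win[1], fs)); i1 <- min(nsamp, ms_to_idx(win[2], fs))
    if (i0 > i1) return(NULL)
    x <- session$signals[ch, ]
    seg <- x[i0:i1]
    amp <- max(abs(seg))
    if (amp < config$min_amplitude_mv) return(list(missing = TRUE, amplitude = amp))
    if (mode == "raw") {
      if (use_template[ch] && !is_vf) {
        pk <- i0 + which.max(abs(seg)) - 1L
        h <- as.integer(round(config$good_peak_window_ms * fs / 1000))
        j <- argmax_absdvdt(dvdt(x, fs), max(i0, pk - h), min(i1, pk + h))
      } else {
        j <- argmax_absdvdt(dvdt(x, fs), i0, i1)
      }
      list(idx = j, amplitude = amp, mode = "raw_dvdt")
    } else {
      sm <- smooth_signal(x, config$smooth_window_samples)
      js <- argmax_absdvdt(dvdt(sm, fs), i0, i1)
      h <- as.integer(round(config$refine_ms * fs / 1000))
      # refinement stays inside the class window (window containment)
      j <- argmax_absdvdt(dvdt(x, fs), max(i0, js - h), min(i1, js + h))
      list(idx = j, amplitude = amp, mode = "smoothed_refined")
    }
  }

  fill <- function(ch, r) {
    if (is.null(r)) { res$missing[ch] <<- TRUE; return(invisible()) }
    res$amplitude_mv[ch] <<- r$amplitude
    if (isTRUE(r$missing)) { res$missing[ch] <<- TRUE; return(invisible()) }
    res$abs_ms[ch] <<- idx_to_ms(r$idx, fs)
    res$time_ms[ch] <<- res$abs_ms[ch] - qrs
    res$mode[ch] <<- r$mode
  }

  # pass 1: template channels (good + neighbors) and all VF channels, raw
  for (ch in which(use_template | is_vf)) {
    win <- beat_window(session, beat, config)
    fill(ch, detect_one(ch, win, "raw"))
  }
  # per-needle reference from good-channel detections of this beat
  ref_by_needle <- tapply(res$abs_ms[good & !res$missing],
                          cmap$needle[good & !res$missing],
                          stats::median)
  # pass 2: remaining channels, smoothed then refined
  for (ch in which(!(use_template | is_vf))) {
    nd <- as.character(cmap$needle[ch])
    ref <- if (!is.null(ref_by_needle) && nd %in% names(ref_by_needle))
      ref_by_needle[[nd]] else NULL
    win <- beat_window(session, beat, config, reference_ms = ref)
    fill(ch, detect_one(ch, win, "smoothed"))
  }
  res
}

# needle-level adjacency (in-plane distance <= factor * spacing)
needle_adjacency <- function(grid) {
  d <- as.matrix(stats::dist(grid$needle_xy))
  adj <- d <= grid$adjacency_factor * grid$spacing_mm
  diag(adj) <- FALSE
  adj
}

#' Enforce the per-channel refractory rule
#'
#' Scans each channel's events in time order and requires consecutive
#' events to be at least `refractory_ms` apart. A violating event is
#' re-detected as the raw max |dV/dt| within the recalculation window
#' (`refractory_ms` to `refractory_ms + recalc_window_ms` after the
#' previous event); if that window holds no deflection (max slope below
#' `min_slope_mv_per_ms`), the event is dropped with reason
#' `"refractory_no_deflection"` recorded in the `note` column. Running
#' the correction twice equals running it once.
#'
#' @param events data.frame as returned by [detect_all_onsets()] (rows
#'   from several beats), with absolute times in `abs_ms`.
#' @param session the `recording_session` the events came from.
#' @param config a [detect_config()].
#' @return events data.frame with corrected `abs_ms`/`time_ms`, dropped
#'   rows removed, and a `note` attribute listing dropped events.
#' @export
enforce_refractory <- function(events, session, config = detect_config()) {
  fs <- session$fs
  keep <- rep(TRUE, nrow(events))
  dropped <- character(0)
  for (ch in unique(events$channel)) {
    idx <- which(events$channel == ch & !events$missing & is.finite(events$abs_ms))
    idx <- idx[order(events$abs_ms[idx])]
    if (length(idx) < 2L) next
    last <- events$abs_ms[idx[1L]]
    x <- session$signals[ch, ]
    for (i in idx[-1L]) {
      t_i <- events$abs_ms[i]
      if (t_i - last < config$refractory_ms) {
        w0 <- last + config$refractory_ms
        w1 <- w0 + config$recalc_window_ms
        j <- relocate_in_window(x, fs, w0, w1, events$amplitude_mv[i], config)
        if (is.na(j)) {
          keep[i] <- FALSE
          dropped <- c(dropped, sprintf("channel %s at %.1f ms: refractory_no_deflection", ch, t_i))
          next
        }
        events$abs_ms[i] <- idx_to_ms(j, fs)
        events$time_ms[i] <- events$abs_ms[i] -
          session$qrs_onsets_ms[events$beat[i]]
      }
      last <- events$abs_ms[i]
    }
  }
  out <- events[keep, , drop = FALSE]
  attr(out, "note") <- dropped
  out
}

#' Detect and refractory-correct all beats of a session
#'
#' Convenience wrapper: preliminary pass, good-channel flags, per-beat
#' [detect_all_onsets()], then [enforce_refractory()] across the record.
#'
#' @inheritParams detect_all_onsets
#' @return combined events data.frame.
#' @export
detect_session <- function(session, config = detect_config()) {
  prelim <- prelim_events(session, config)
  good <- flag_good_channels(prelim, config)
  good <- unname(good[order(as.integer(names(good)))])
  ev <- do.call(rbind, lapply(seq_along(session$qrs_onsets_ms), function(b)
    detect_all_onsets(session, b, config, good = good)))
  enforce_refractory(ev, session, config)
}
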