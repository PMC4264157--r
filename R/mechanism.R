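#' Layer-specific tachycardia refractory periods
#'
#' Assumed refractory periods during tachycardia: shorter in epicardium
#' (80 ms) than endocardium (100 ms). Cycle lengths below the layer value
#' mark candidate refractory block when considering reentry. The midwall
#' value is the mean of the two (not separately specified).
#'
#' @param epi_ms,endo_ms,mid_ms refractory periods (ms).
#' @return named list of class `layer_refractory_config`.
#' @export
layer_refractory_config <- function(epi_ms = 80, endo_ms = 100,
                                    mid_ms = (epi_ms + endo_ms) / 2) {
  if (any(c(epi_ms, endo_ms, mid_ms) <= 0)) stop("refractory periods must be positive")
  structure(list(epi_ms = epi_ms, endo_ms = endo_ms, mid_ms = mid_ms),
            class = "layer_refractory_config")
}

#' Classify one tachycardia complex as focal or reentrant
#'
#' Applies the operational definitions to two consecutive activation
#' maps. Reentry: the site recording the earliest activity of the
#' current complex is immediately (grid-)adjacent to the site of the
#' latest activation of the previous complex, supported by diastolic
#' bridging (short diastolic gap between the two) and/or conduction-block
#' evidence (a site with >75% voltage reduction followed by increased
#' voltage on the next activation). Focal: the earliest site is
#' surrounded by adjacent sites that all activate after it with
#' progressive spread away from the origin, and none of them shows late
#' activity returning toward it beyond 50% of the cycle length. The
#' adjacency (reentry) criterion takes precedence when both could hold.
#'
#' @param maps list of two or more consecutive [activation_map()]s; the
#'   last two are compared.
#' @param grid the `electrode_grid`.
#' @param cycle_length_ms tachycardia cycle length (ms).
#' @param amplitudes optional site x complex matrix of deflection
#'   amplitudes (mV) aligned with the supplied maps, used for block
#'   evidence.
#' @param refractory a [layer_refractory_config()].
#' @param bridge_frac_max diastolic gap (as a fraction of cycle length)
#'   at or below which bridging is considered present.
#' @return object of class `mechanism_call`: list with `kind`
#'   (`"focal"`, `"reentry"` or `"indeterminate"`), `layer`,
#'   `purkinje_origin` (NA until assessed), and `evidence` (earliest
#'   site/time, latest prior site/time, adjacency flag, diastolic gap,
#'   bridge flag, block sites, refractory-block candidate flag).
#' @export
classify_beat_mechanism <- function(maps, grid, cycle_length_ms, amplitudes = NULL,
                                    refractory = layer_refractory_config(),
                                    bridge_frac_max = 0.5) {
  if (length(maps) < 2L) stop("need >= 2 consecutive activation maps")
  if (cycle_length_ms <= 0) stop("cycle length must be positive")
  prev <- maps[[length(maps) - 1L]]
  cur <- maps[[length(maps)]]
  if (nrow(cur) < 4L) {
    return(mechanism_call("indeterminate", NA_character_, list(
      reason = "insufficient mapped sites")))
  }
  i_early <- which.min(cur$time_ms)
  early_site <- cur$site[i_early]
  early_layer <- cur$layer[i_early]
  i_late <- which.max(prev$time_ms)
  late_site <- prev$site[i_late]
  adj <- grid$adjacency
  is_adjacent <- early_site == late_site || adj[early_site, late_site]

  early_abs <- cur$time_ms[i_early] + attr(cur, "qrs_onset_ms")
  late_abs <- prev$time_ms[i_late] + attr(prev, "qrs_onset_ms")
  gap <- early_abs - late_abs
  bridge <- is.finite(gap) && gap >= 0 && gap <= bridge_frac_max * cycle_length_ms

  block_sites <- integer(0)
  if (!is.null(amplitudes) && ncol(amplitudes) >= 2L) {
    kc <- min(ncol(amplitudes), length(maps))
    kp <- kc - 1L
    typical <- apply(amplitudes, 1, stats::median)
    block_sites <- which(amplitudes[, kp] < 0.25 * typical &
                         amplitudes[, kc] > amplitudes[, kp])
  }
  ref_ms <- switch(early_layer, epi = refractory$epi_ms, endo = refractory$endo_ms,
                   refractory$mid_ms)
  refractory_block_candidate <- cycle_length_ms < ref_ms

  # focal surround criterion on the current complex
  nb <- cur$site != early_site & (adj[early_site, cur$site] | cur$needle == cur$needle[i_early])
  nb_dt <- cur$time_ms[nb] - cur$time_ms[i_early]
  focal_ok <- FALSE
  if (sum(nb) >= 2L) {
    all_after <- all(nb_dt > 0)
    no_late_return <- all(nb_dt < 0.5 * cycle_length_ms)
    # progressive spread: over all mapped sites, time increases with distance
    d_xy <- if (is.null(cur$x_mm)) NA else
      sqrt((cur$x_mm - cur$x_mm[i_early])^2 + (cur$y_mm - cur$y_mm[i_early])^2)
    if (all(is.na(d_xy))) {
      progressive <- TRUE
    } else {
      progressive <- stats::cor(d_xy, cur$time_ms, method = "spearman") > 0
    }
    focal_ok <- all_after && no_late_return && progressive
  }

  evidence <- list(earliest_site = early_site, earliest_time_ms = cur$time_ms[i_early],
                   latest_prior_site = late_site, latest_prior_time_ms = prev$time_ms[i_late],
                   adjacency = is_adjacent, diastolic_gap_ms = gap, bridge = bridge,
                   block_sites = block_sites,
                   refractory_block_candidate = refractory_block_candidate)
  reentry_ok <- is_adjacent && (bridge || length(block_sites) > 0L)
  kind <- if (reentry_ok) "reentry" else if (focal_ok) "focal" else "indeterminate"
  mechanism_call(kind, early_layer, evidence)
}

mechanism_call <- function(kind, layer, evidence) {
  structure(list(kind = kind, layer = layer, purkinje_origin = NA, evidence = evidence),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("<mechanism_call> ", x$kind,
      if (!is.na(x$layer)) paste0(" (", x$layer, ")"),
      if (isTRUE(x$purkinje_origin)) " [Purkinje]", "\n", sep = "")
  invisible(x)
}

# high-frequency residual used to isolate brief low-amplitude spikes from
# the much wider muscle deflection
highfreq_residual <- function(x, fs, cutoff_ms = 5) {
  x - smooth_signal(x, max(3L, as.integer(round(cutoff_ms * fs / 1000))))
}

# does channel ch carry a Purkinje-like prepotential before onset_abs_ms?
has_prepotential <- function(x, fs, onset_abs_ms, lead_range_ms = c(1, 11),
                             amp_range_mv = c(0.25, 1.0), max_width_ms = 2.5) {
  hf <- highfreq_residual(x, fs)
  i0 <- ms_to_idx(onset_abs_ms - lead_range_ms[2], fs)
  i1 <- ms_to_idx(onset_abs_ms - lead_range_ms[1], fs)
  i0 <- max(1L, i0); i1 <- min(length(x), i1)
  if (i0 >= i1) return(FALSE)
  seg <- hf[i0:i1]
  n <- length(seg)
  if (n < 3L) return(FALSE)
  # scan local maxima: the muscle deflection's leading edge can leak into
  # the window with a large peak, so the global max is not enough
  pks <- which(seg[2:(n - 1L)] >= seg[1:(n - 2L)] & seg[2:(n - 1L)] > seg[3:n]) + 1L
  for (pk in pks) {
    amp <- seg[pk]
    if (amp < amp_range_mv[1] || amp > amp_range_mv[2]) next
    above <- seg >= amp / 2
    l <- pk; while (l > 1L && above[l - 1L]) l <- l - 1L
    r <- pk; while (r < n && above[r + 1L]) r <- r + 1L
    if ((r - l + 1L) * 1000 / fs <= max_width_ms) return(TRUE)
  }
  FALSE
}

#' Detect a Purkinje origin for a focal endocardial tachycardia
#'
#' True only when a high-frequency, low-amplitude spike (about 0.5 mV,
#' 1-2 ms) precedes the endocardial muscle deflection by 1-11 ms on at
#' least `min_channels` endocardial channels, on the tachycardia focus
#' beat AND on atrial-paced reference beats recorded both before and
#' after coronary occlusion.
#'
#' @param vt,pre,post lists with elements `session` (a
#'   `recording_session`) and `events` (the detected events of the beat
#'   to assess, with `abs_ms` and `layer`). `pre`/`post` are the
#'   atrial-paced references; pass `NULL` if unavailable
#'   (indeterminate).
#' @param min_channels minimum endocardial channels showing the spike.
#' @param lead_range_ms allowed spike lead relative to muscle onset.
#' @param amp_range_mv allowed spike amplitude band.
#' @return `TRUE`, `FALSE`, or `NA` (indeterminate: missing references).
#' @export
detect_purkinje_origin <- function(vt, pre, post, min_channels = 2L,
                                   lead_range_ms = c(1, 11),
                                   amp_range_mv = c(0.25, 1.0)) {
  if (is.null(pre) || is.null(post)) return(NA)
  count_spikes <- function(rec) {
    ev <- rec$events
    ev <- ev[ev$layer == "endo" & !ev$missing & is.finite(ev$abs_ms), , drop = FALSE]
    sum(vapply(seq_len(nrow(ev)), function(i)
      has_prepotential(rec$session$signals[ev$channel[i], ], rec$session$fs,
                       ev$abs_ms[i], lead_range_ms, amp_range_mv), logical(1)))
  }
  all(vapply(list(vt, pre, post), count_spikes, numeric(1)) >= min_channels)
}

#' Classify an induced episode
#'
#' Total episode typing: VF when the surface QRS is continuously
#' changing and arterial pressure collapses (mechanism then read from
#' the first 8-40 complexes); otherwise sustained VT when the episode
#' lasts at least 10 s or required pace termination or a shock;
#' otherwise non-sustained VT when it self-terminated after at least 3
#' complexes in under 10 s; otherwise not an episode.
#'
#' @param complex_times_ms onset times of the episode's complexes (ms).
#' @param terminated_by `"spontaneous"`, `"pacing"`, `"shock"` or
#'   `"none"` (ongoing).
#' @param qrs_variability continuously changing surface QRS?
#' @param pressure_collapse no effective arterial pressure?
#' @return object of class `episode_call`: `type` (`"VF"`,
#'   `"sustained_VT"`, `"nonsustained_VT"`, `"not_an_episode"`),
#'   `duration_s`, `n_complexes`, `terminated_by`, `analyzed_prefix`
#'   (complex index range for mechanism analysis; VF limits it to the
#'   first 8-40).
#' @export
classify_episode <- function(complex_times_ms,
                             terminated_by = c("spontaneous", "pacing", "shock", "none"),
                             qrs_variability = FALSE, pressure_collapse = FALSE) {
  terminated_by <- match.arg(terminated_by)
  if (!length(complex_times_ms)) stop("need >= 1 complex")
  n <- length(complex_times_ms)
  duration_s <- (max(complex_times_ms) - min(complex_times_ms)) / 1000
  if (qrs_variability && pressure_collapse) {
    type <- "VF"
    prefix <- c(1L, min(n, 40L))
  } else if (duration_s >= 10 || terminated_by %in% c("pacing", "shock")) {
    type <- "sustained_VT"
    prefix <- c(1L, n)
  } else if (n >= 3L && duration_s < 10) {
    type <- "nonsustained_VT"
    prefix <- c(1L, n)
  } else {
    type <- "not_an_episode"
    prefix <- c(NA_integer_, NA_integer_)
  }
  structure(list(type = type, duration_s = duration_s, n_complexes = n,
                 terminated_by = terminated_by, analyzed_prefix = prefix),
            class = "episode_call")
}

#' Classify a whole simulated or recorded episode end to end
#'
#' Pipeline helper: detect onsets on every beat, sequence them, build
#' per-complex activation maps, and classify each complex after the
#' first, returning the per-complex calls and the episode-level
#' mechanism set (the union of calls, as multi-mechanism episodes are
#' reported).
#'
#' @param session a `recording_session`.
#' @param config a [detect_config()].
#' @param cycle_length_ms cycle length; estimated from the QRS onsets
#'   when omitted.
#' @return list with `calls` (per-complex `mechanism_call`s), `maps`,
#'   `kinds` (character vector), `majority` (most frequent kind/layer).
#' @export
classify_session <- function(session, config = detect_config(), cycle_length_ms = NULL) {
  if (is.null(cycle_length_ms))
    cycle_length_ms <- stats::median(diff(session$qrs_onsets_ms))
  ev <- detect_session(session, config)
  grid <- session$grid
  maps <- lapply(seq_along(session$qrs_onsets_ms), function(b) {
    eb <- ev[ev$beat == b, , drop = FALSE]
    eb <- sequence_onsets(eb, session, b, k = 0L, config = config)
    m <- activation_map(eb, session, b)
    m$x_mm <- grid$sites$x[m$site]
    m$y_mm <- grid$sites$y[m$site]
    m
  })
  amps <- do.call(cbind, lapply(seq_along(maps), function(b) {
    a <- rep(NA_real_, nrow(grid$sites))
    eb <- ev[ev$beat == b, ]
    a[eb$channel] <- eb$amplitude_mv
    a
  }))
  calls <- lapply(2:length(maps), function(k)
    classify_beat_mechanism(maps[seq_len(k)], grid, cycle_length_ms,
                            amplitudes = amps))
  kinds <- vapply(calls, `[[`, "", "kind")
  layers <- vapply(calls, `[[`, "", "layer")
  det <- kinds != "indeterminate"
  majority <- if (any(det)) {
    kl <- paste(kinds[det], layers[det])
    strsplit(names(sort(table(kl), decreasing = TRUE))[1], " ")[[1]]
  } else c("indeterminate", NA_character_)
  list(calls = calls, maps = maps, kinds = kinds,
       majority = list(kind = majority[1], layer = majority[2]))
}
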