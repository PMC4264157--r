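#' Layer-pair adjacency margin
#'
#' Margin (ms) within which two layers of one needle are considered
#' consistent at onset index `k` (0-based): +/-20 ms for neighboring
#' layers (endo-mid, mid-epi) and +/-30 ms for endo-epi, growing by 2 and
#' 3 ms respectively for each following onset.
#'
#' @param pair `"endo-mid"`, `"mid-epi"` or `"endo-epi"`.
#' @param k 0-based onset index.
#' @return margin in ms.
#' @export
adjacency_margin <- function(pair, k = 0L) {
  if (k < 0) stop("onset index must be >= 0")
  if (pair %in% c("endo-mid", "mid-epi")) 20 + 2 * k
  else if (pair == "endo-epi") 30 + 3 * k
  else stop("unknown layer pair: ", pair)
}

#' Build the layer-adjacency assessment for each needle
#'
#' For every needle with at least two recorded layers, flags whether each
#' layer pair's onset times fall within the margin for onset index `k`.
#' Missing layers yield `NA` flags.
#'
#' @param events data.frame with columns `needle`, `layer`, `time_ms`
#'   (one onset per needle-layer, e.g. one complex of a map).
#' @param k 0-based onset index controlling margin growth.
#' @return data.frame with one row per needle: `needle`, `endo_mid`,
#'   `mid_epi`, `endo_epi` (logical), and the margins used.
#' @export
build_adjacency <- function(events, k = 0L) {
  pairs <- list(endo_mid = c("endo", "mid"), mid_epi = c("mid", "epi"),
                endo_epi = c("endo", "epi"))
  margins <- c(endo_mid = adjacency_margin("endo-mid", k),
               mid_epi = adjacency_margin("mid-epi", k),
               endo_epi = adjacency_margin("endo-epi", k))
  rows <- lapply(split(events, events$needle), function(d) {
    t_of <- function(layer) {
      v <- d$time_ms[d$layer == layer]
      if (length(v) == 1L && is.finite(v)) v else NA_real_
    }
    fl <- vapply(names(pairs), function(p) {
      dtv <- abs(t_of(pairs[[p]][1]) - t_of(pairs[[p]][2]))
      if (is.na(dtv)) NA else dtv <= margins[[p]]
    }, logical(1))
    data.frame(needle = d$needle[1L], endo_mid = fl[["endo_mid"]],
               mid_epi = fl[["mid_epi"]], endo_epi = fl[["endo_epi"]],
               margin_neighbor_ms = margins[["endo_mid"]],
               margin_endo_epi_ms = margins[["endo_epi"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sequence onsets: relocate single-layer outliers
#'
#' A layer whose onset lies outside the margin of BOTH other layers of
#' its needle is re-detected at the raw max |dV/dt| within the trend
#' window spanned by the two in-margin layers' times padded by the pair
#' margin. Events on VF or paced beats pass through unchanged, as do
#' needles with fewer than three detected layers. When the trend window
#' holds no deflection the event is kept and flagged `outlier`.
#'
#' @param events data.frame as from [detect_all_onsets()] for one beat
#'   (columns `channel`, `needle`, `layer`, `time_ms`, `abs_ms`).
#' @param session the `recording_session`.
#' @param beat beat index (used for beat type and QRS reference).
#' @param k 0-based onset index for the margins.
#' @param config a [detect_config()] (for the deflection threshold).
#' @return events with adjusted times and a logical `outlier` column.
#' @export
sequence_onsets <- function(events, session, beat, k = 0L, config = detect_config()) {
  events$outlier <- FALSE
  if (session$beat_types[beat] %in% c("vf", "paced")) return(events)
  fs <- session$fs
  qrs <- session$qrs_onsets_ms[beat]
  pair_margin <- function(l1, l2) {
    if ("endo" %in% c(l1, l2) && "epi" %in% c(l1, l2)) adjacency_margin("endo-epi", k)
    else adjacency_margin("endo-mid", k)
  }
  for (nd in unique(events$needle)) {
    rows <- which(events$needle == nd & is.finite(events$time_ms))
    if (length(rows) != 3L) next
    t_ <- events$time_ms[rows]
    ly <- events$layer[rows]
    for (i in 1:3) {
      others <- setdiff(1:3, i)
      out_of <- vapply(others, function(o2)
        abs(t_[i] - t_[o2]) > pair_margin(ly[i], ly[o2]), logical(1))
      if (all(out_of)) {
        pad <- max(vapply(others, function(o2) pair_margin(ly[i], ly[o2]), numeric(1)))
        w0 <- min(t_[others]) - pad + qrs
        w1 <- max(t_[others]) + pad + qrs
        ch <- events$channel[rows[i]]
        x <- session$signals[ch, ]
        j <- relocate_in_window(x, fs, w0, w1, events$amplitude_mv[rows[i]], config)
        if (is.na(j)) {
          events$outlier[rows[i]] <- TRUE
        } else {
          events$abs_ms[rows[i]] <- idx_to_ms(j, fs)
          events$time_ms[rows[i]] <- events$abs_ms[rows[i]] - qrs
        }
        break  # at most one of three layers can be outside both margins
      }
    }
  }
  events
}

# Re-detect an onset inside [w0, w1] ms: smoothed max |dV/dt| refined on the
# raw signal, but only when the window actually holds a deflection — the
# smoothed peak-to-peak there must reach `deflection_frac` of the channel's
# own per-beat amplitude, which separates true deflections from band-limited
# noise far more reliably than a raw slope floor. Returns NA when empty.
relocate_in_window <- function(x, fs, w0, w1, ref_amplitude_mv, config,
                               deflection_frac = 0.5) {
  i0 <- max(1L, ms_to_idx(w0, fs)); i1 <- min(length(x), ms_to_idx(w1, fs))
  if (i0 >= i1) return(NA_integer_)
  sm <- smooth_signal(x, config$smooth_window_samples)
  seg <- sm[i0:i1]
  if (!is.finite(ref_amplitude_mv) ||
      (max(seg) - min(seg)) < deflection_frac * ref_amplitude_mv)
    return(NA_integer_)
  js <- argmax_absdvdt(dvdt(sm, fs), i0, i1)
  h <- as.integer(round(config$refine_ms * fs / 1000))
  argmax_absdvdt(dvdt(x, fs), max(i0, js - h), min(i1, js + h))
}

#' Default isochrone band edges
#'
#' The first two edges follow the map legend convention: white earlier
#' than -25 ms, yellow -25 to 15 ms; later bands are uniform 40 ms wide
#' up to the complex's latest activation time.
#'
#' @param latest_ms latest activation time to cover (ms).
#' @param band_width_ms width of the bands after yellow.
#' @return increasing numeric vector of edges starting at -25, 15, ...
#' @export
isochrone_edges <- function(latest_ms, band_width_ms = 40) {
  edges <- c(-25, 15)
  # stop before the latest time so the final (green) band contains it
  while (edges[length(edges)] + band_width_ms < latest_ms) {
    edges <- c(edges, edges[length(edges)] + band_width_ms)
  }
  edges
}

#' Assign isochrone bands to activation times
#'
#' Each finite activation time is assigned the unique band containing
#' it: `"white"` strictly before the first edge, `"yellow"` between the
#' first two edges (inclusive of both, matching the -25 to 15 legend),
#' then `"red"`, intermediate `"band4"`, ..., with the last band labeled
#' `"green"`.
#'
#' @param times_ms activation times (ms relative to QRS onset).
#' @param band_edges increasing edge vector; defaults to
#'   [isochrone_edges()] of the latest time.
#' @return data.frame with `time_ms`, `band` (integer, 0 = white) and
#'   `band_label`.
#' @export
compute_isochrones <- function(times_ms, band_edges = NULL) {
  if (is.null(band_edges)) band_edges <- isochrone_edges(max(times_ms[is.finite(times_ms)]))
  if (is.unsorted(band_edges, strictly = TRUE)) stop("band edges must be strictly increasing")
  # bands are (edge_i, edge_{i+1}] except the first edge itself belongs to
  # yellow: white < -25 <= yellow <= 15 < red ...
  band <- findInterval(times_ms, band_edges, left.open = TRUE)
  band[!is.na(times_ms) & times_ms == band_edges[1L]] <- 1L
  n_bands <- length(band_edges) + 1L
  labels <- c("white", "yellow", "red",
              if (n_bands > 4L) paste0("band", seq(4L, n_bands - 1L)),
              if (n_bands > 3L) "green")
  labels <- labels[seq_len(n_bands)]
  data.frame(time_ms = times_ms, band = band,
             band_label = ifelse(is.finite(times_ms), labels[band + 1L], NA_character_),
             stringsAsFactors = FALSE)
}

#' Assemble an activation map for one complex
#'
#' Turns detected (and sequenced) events of one beat into a per-site
#' activation map with isochrone bands.
#'
#' @param events events data.frame for one beat (after sequencing).
#' @param session the `recording_session`.
#' @param complex complex (beat) index stored on the map.
#' @param band_edges optional isochrone edges.
#' @return object of class `activation_map`: data.frame `sites`
#'   (`site`, `needle`, `layer`, `time_ms`, `band`, `band_label`) plus
#'   attributes `complex` and `qrs_onset_ms`.
#' @export
activation_map <- function(events, session, complex, band_edges = NULL) {
  ok <- !events$missing & is.finite(events$time_ms)
  d <- events[ok, c("channel", "needle", "layer", "time_ms")]
  names(d)[1] <- "site"
  iso <- compute_isochrones(d$time_ms, band_edges)
  d$band <- iso$band
  d$band_label <- iso$band_label
  structure(d, class = c("activation_map", "data.frame"),
            complex = complex, qrs_onset_ms = session$qrs_onsets_ms[complex])
}

#' Plot layered isochrone maps
#'
#' Draws one panel per layer (epi on top, endo at the bottom), each site
#' colored by its isochrone band and annotated with its activation time,
#' the standard presentation of 3-D intramural maps.
#'
#' @param map an [activation_map()].
#' @param grid the `electrode_grid` (for needle positions).
#' @param main plot title.
#' @return invisibly, the map.
#' @export
plot_isochrone_map <- function(map, grid, main = "activation map") {
  layers <- rev(grid$layers)  # epi first
  cols <- c(white = "white", yellow = "gold", red = "firebrick2", green = "forestgreen")
  band_col <- function(lbl) if (lbl %in% names(cols)) cols[[lbl]] else "indianred4"
  op <- graphics::par(mfrow = c(length(layers), 1), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  for (ly in layers) {
    d <- map[map$layer == ly, ]
    xy <- grid$needle_xy[d$needle, , drop = FALSE]
    graphics::plot(grid$needle_xy, type = "n", asp = 1, xlab = "", ylab = "",
                   main = paste(main, "-", ly))
    graphics::points(xy[, 1], xy[, 2], pch = 21, cex = 3,
                     bg = vapply(d$band_label, band_col, character(1)))
    graphics::text(xy[, 1], xy[, 2], labels = round(d$time_ms), cex = 0.6, pos = 3)
  }
  invisible(map)
}
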