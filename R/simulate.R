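#' Specify the ground-truth mechanism of a simulated episode
#'
#' Describes the activation pattern a synthetic recording should contain:
#' a paced drive, a focal tachycardia (single earliest site with
#' centrifugal spread), a reentrant tachycardia (ordered closed circuit of
#' grid-adjacent sites bridged through diastole), or a VF onset (an
#' analyzable mechanism-bearing prefix of 8-40 complexes followed by
#' unlabeled chaotic activity).
#'
#' @param kind `"paced"`, `"focal"`, `"reentry"` or `"vf_onset"`.
#' @param origin_site site id of the focus / pacing site (focal, paced,
#'   vf_onset).
#' @param circuit_sites ordered site ids of the reentrant circuit
#'   (reentry; >= 3 sites, consecutive and wrap-around pairs must be
#'   grid-adjacent).
#' @param layer layer of the origin, one of endo/mid/epi (informational;
#'   derived from `origin_site` when omitted).
#' @param cycle_length_ms tachycardia cycle length (ms).
#' @param conduction_velocity_mm_per_ms myocardial conduction velocity.
#' @param block_site optional site id showing unidirectional block: >75%
#'   amplitude reduction on the first complex, increased voltage on the
#'   next.
#' @param purkinje logical; add a Purkinje prepotential (0.5 mV, 1.5 ms,
#'   5 ms lead by default) on the endocardial origin and its adjacent
#'   endocardial sites.
#' @param n_complexes number of tachycardia complexes (8-40 for
#'   vf_onset).
#' @param entry_offset_ms time of the earliest site relative to the QRS
#'   onset of each complex (ms, negative = pre-QRS).
#' @param bridge_frac fraction of the cycle length taken by one full
#'   circuit traversal (reentry); the remainder is the diastolic gap.
#' @param purkinje_lead_ms prepotential lead time (1-11 ms).
#' @return object of class `mechanism_spec`.
#' @export
mechanism_spec <- function(kind = c("focal", "reentry", "paced", "vf_onset"),
                           origin_site = NULL, circuit_sites = NULL, layer = NULL,
                           cycle_length_ms = 180, conduction_velocity_mm_per_ms = 0.6,
                           block_site = NULL, purkinje = FALSE, n_complexes = 3L,
                           entry_offset_ms = -30, bridge_frac = 0.55,
                           purkinje_lead_ms = 5) {
  kind <- match.arg(kind)
  if (cycle_length_ms <= 0 || conduction_velocity_mm_per_ms <= 0)
    stop("cycle length and conduction velocity must be positive")
  if (kind == "reentry") {
    if (is.null(circuit_sites) || length(circuit_sites) < 3L)
      stop("reentry requires >= 3 circuit sites")
  } else if (is.null(origin_site)) {
    stop("origin_site required for ", kind)
  }
  if (kind == "vf_onset" && (n_complexes < 8L || n_complexes > 40L))
    stop("vf_onset requires n_complexes in [8, 40]")
  if (n_complexes < 1L) stop("n_complexes must be positive")
  structure(list(kind = kind, origin_site = origin_site, circuit_sites = circuit_sites,
                 layer = layer, cycle_length_ms = cycle_length_ms,
                 conduction_velocity_mm_per_ms = conduction_velocity_mm_per_ms,
                 block_site = block_site, purkinje = isTRUE(purkinje),
                 n_complexes = as.integer(n_complexes),
                 entry_offset_ms = entry_offset_ms, bridge_frac = bridge_frac,
                 purkinje_lead_ms = purkinje_lead_ms),
            class = "mechanism_spec")
}

#' Simulate a multichannel plunge-needle electrogram recording
#'
#' Generates a full recording session (channels x samples, 3200 Hz,
#' 3-1300 Hz band) with known ground truth. Focal episodes place the
#' strictly earliest activation at the origin with each site delayed by
#' its geodesic distance over the grid divided by conduction velocity.
#' Reentrant episodes traverse the supplied closed circuit over
#' `bridge_frac` of the cycle length so that the earliest site of every
#' complex is grid-adjacent to the latest site of the previous one, with
#' diastolic bridging; a `block_site` shows >75% amplitude reduction on
#' the blocked beat and increased voltage on the next. VF onsets carry a
#' mechanism-bearing prefix with progressively shortening cycle length
#' followed by unlabeled chaotic activity.
#'
#' @param grid an [make_grid()] electrode grid.
#' @param spec a [mechanism_spec()].
#' @param noise_sd additive band-limited noise SD (mV).
#' @param seed integer seed; identical (seed, arguments) give identical
#'   output.
#' @return An object of class `synthetic_recording`: list with `session`
#'   (a `recording_session`: `signals`, `fs`, `band`, `grid`,
#'   `channel_map`, `qrs_onsets_ms`, `beat_types`, `pacing_onsets_ms`),
#'   `truth_onsets` (site x complex matrix, absolute ms; VF chaos
#'   excluded), `truth_amplitudes`, and `truth_mechanism`.
#' @export
simulate_episode <- function(grid, spec, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(grid, "electrode_grid"), inherits(spec, "mechanism_spec"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(as.integer(seed))
  st <- grid$sites
  ns <- nrow(st)
  geo <- grid_geodesic(grid)
  v <- spec$conduction_velocity_mm_per_ms
  cl <- spec$cycle_length_ms
  nk <- spec$n_complexes
  t_first_qrs <- 150
  qrs <- t_first_qrs + cumsum(c(0, cycle_lengths(spec)[-nk]))

  onsets <- matrix(NA_real_, ns, nk)
  if (spec$kind %in% c("focal", "paced", "vf_onset")) {
    o <- spec$origin_site
    if (is.na(geo[o, 1]) || any(!is.finite(geo[o, ])))
      stop("grid is disconnected from the origin site")
    base <- if (spec$kind == "paced") spec$entry_offset_ms + 20 else spec$entry_offset_ms
    for (k in seq_len(nk)) onsets[, k] <- qrs[k] + base + geo[o, ] / v
  } else {
    cs <- spec$circuit_sites
    adj <- grid$adjacency
    pairs <- cbind(cs, c(cs[-1L], cs[1L]))
    if (!all(adj[pairs])) stop("invalid-spec: reentry circuit is not closed on grid adjacency")
    m <- length(cs)
    # allocate the traversal time over the m-1 forward steps by edge length
    step_d <- sqrt((st$x[cs[-1L]] - st$x[cs[-m]])^2 + (st$y[cs[-1L]] - st$y[cs[-m]])^2 +
                   (st$depth[cs[-1L]] - st$depth[cs[-m]])^2)
    circ_t <- c(0, cumsum(step_d / sum(step_d))) * spec$bridge_frac * cl
    # off-circuit sites are reached from the rotating circuit: each takes the
    # earliest arrival over all circuit sources, so layers on one needle stay
    # within physiologic transmural margins of each other
    off_t <- apply(circ_t + geo[cs, , drop = FALSE] / v, 2, min)
    for (k in seq_len(nk)) {
      tt <- qrs[k] + spec$entry_offset_ms + off_t
      tt[cs] <- qrs[k] + spec$entry_offset_ms + circ_t
      onsets[, k] <- tt
    }
  }

  amps <- matrix(rep(8 + 4 * (seq_len(ns) %% 5) / 4, nk), ns, nk)  # 8-12 mV, per-site
  if (!is.null(spec$block_site)) {
    b <- spec$block_site
    amps[b, 1L] <- amps[b, 1L] * 0.2
    if (nk >= 2L) amps[b, 2L] <- amps[b, 2L] * 1.3
  }

  fs <- 3200
  duration_ms <- max(onsets, na.rm = TRUE) + 200
  chaos <- NULL
  if (spec$kind == "vf_onset") {
    chaos_len <- 400
    duration_ms <- duration_ms + chaos_len
    chaos <- lapply(seq_len(ns), function(i) {
      t0 <- max(onsets[i, ]) + 65
      tt <- t0 + cumsum(65 + stats::rexp(8, rate = 1 / 20))
      tt[tt < duration_ms - 60]
    })
  }

  purk <- NULL
  purk_channels <- integer(0)
  if (spec$purkinje) {
    o <- spec$origin_site
    endo <- st$site[st$layer == "endo"]
    purk_channels <- intersect(c(o, which(grid$adjacency[o, ])), endo)
    purk <- list(lead_ms = spec$purkinje_lead_ms, amplitude_mv = 0.5, width_ms = 1.5)
  }

  signals <- matrix(0, ns, ceiling(duration_ms * fs / 1000))
  for (i in seq_len(ns)) {
    oi <- onsets[i, ]
    ai <- amps[i, ]
    if (!is.null(chaos) && length(chaos[[i]])) {
      oi <- c(oi, chaos[[i]])
      ai <- c(ai, rep(amps[i, 1L] * 0.5, length(chaos[[i]])))
    }
    ord <- order(oi)
    w <- synthesize_waveform(oi[ord], ai[ord], fs = fs, duration_ms = duration_ms,
                             purkinje = if (i %in% purk_channels) purk else NULL,
                             noise_sd = noise_sd)
    signals[i, ] <- w[seq_len(ncol(signals))]
  }

  beat_types <- rep(switch(spec$kind, paced = "paced", vf_onset = "vf", "intracardiac"), nk)
  session <- structure(list(signals = signals, fs = fs, band = c(3, 1300), grid = grid,
                            channel_map = st[, c("site", "needle", "layer")],
                            qrs_onsets_ms = qrs, beat_types = beat_types,
                            pacing_onsets_ms = if (spec$kind == "paced") qrs + spec$entry_offset_ms else NULL,
                            duration_ms = duration_ms),
                       class = "recording_session")
  structure(list(session = session, truth_onsets = onsets, truth_amplitudes = amps,
                 truth_mechanism = spec, qrs_onsets_ms = qrs),
            class = "synthetic_recording")
}

# per-complex cycle lengths; VF onsets shorten linearly to 75% of the
# nominal cycle length over the analyzable prefix (floor 80 ms)
cycle_lengths <- function(spec) {
  nk <- spec$n_complexes
  if (spec$kind == "vf_onset" && nk > 1L) {
    pmax(80, seq(spec$cycle_length_ms, 0.75 * spec$cycle_length_ms, length.out = nk))
  } else rep(spec$cycle_length_ms, nk)
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat("<synthetic_recording> ", x$truth_mechanism$kind, ", ",
      nrow(x$truth_onsets), " channels x ", ncol(x$truth_onsets), " complexes, ",
      round(x$session$duration_ms), " ms @ ", x$session$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Default reentrant circuit on the standard grid
#'
#' Convenience helper returning an ordered, closed, grid-adjacent circuit
#' of sites in one layer around a lattice cell, for building reentry
#' specs in examples and tests.
#'
#' @param grid electrode grid.
#' @param layer circuit layer.
#' @param needles ordered needle ids forming the loop; defaults to the
#'   four needles of the first lattice cell.
#' @return integer site ids.
#' @export
default_circuit <- function(grid, layer = "endo", needles = NULL) {
  if (is.null(needles)) {
    xy <- grid$needle_xy
    s <- grid$spacing_mm
    pick <- function(px, py) which(abs(xy[, 1] - px) < 1e-9 & abs(xy[, 2] - py) < 1e-9)[1]
    needles <- c(pick(0, 0), pick(s, 0), pick(s, s), pick(0, s))
    if (anyNA(needles)) stop("default circuit needs the first lattice cell; supply needles")
  }
  unname(vapply(needles, function(n) grid_site_id(grid, n, layer), integer(1)))
}
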