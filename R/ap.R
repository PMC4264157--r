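#' Action-potential pacing protocol
#'
#' Describes a microelectrode pacing experiment: one or more pacing
#' drives (1-4 Hz, about 30 s each by default) with abrupt cessation,
#' after which delayed afterdepolarizations (DADs) and triggered
#' activity (TA) may appear. TA-rate experiments use at least 4
#' frequencies.
#'
#' @param pacing_frequencies_hz drive frequencies (Hz, 1-4).
#' @param drive_duration_s drive length (s).
#' @param n_paced optional paced complexes per drive (overrides
#'   `drive_duration_s`).
#' @param dad_spec list of `c(latency_ms, amplitude_mv)` pairs injected
#'   after full repolarization of the last paced AP of the final drive;
#'   latencies are relative to the last stimulus.
#' @param ta_probability probability that an injected DAD triggers a
#'   full AP at its peak.
#' @param mdp_mv,peak_mv,apd50_ms,apd90_ms ground-truth AP parameters.
#' @param seed integer seed.
#' @return object of class `ap_protocol`.
#' @export
ap_protocol <- function(pacing_frequencies_hz = 1.5, drive_duration_s = 30,
                        n_paced = NULL, dad_spec = list(), ta_probability = 0,
                        mdp_mv = -80, peak_mv = -7, apd50_ms = 165, apd90_ms = 234,
                        seed = 1L) {
  if (any(pacing_frequencies_hz < 0.5 | pacing_frequencies_hz > 4.5))
    stop("pacing frequencies must be in about 1-4 Hz")
  if (ta_probability < 0 || ta_probability > 1) stop("ta_probability must be in [0, 1]")
  for (d in dad_spec) if (length(d) != 2L || d[2] <= 0)
    stop("each dad_spec entry is c(latency_ms, amplitude_mv) with positive amplitude")
  if (apd90_ms < apd50_ms || apd50_ms <= 0) stop("need apd90 >= apd50 > 0")
  structure(list(pacing_frequencies_hz = pacing_frequencies_hz,
                 drive_duration_s = drive_duration_s, n_paced = n_paced,
                 dad_spec = dad_spec, ta_probability = ta_probability,
                 mdp_mv = mdp_mv, peak_mv = peak_mv, apd50_ms = apd50_ms,
                 apd90_ms = apd90_ms, seed = as.integer(seed)),
            class = "ap_protocol")
}

# sampled AP shape starting at the upstroke (fraction of full length),
# piecewise linear through the 50% / 90% repolarization controls
ap_shape <- function(t_ms, apa, apd50, apd90) {
  # t_ms measured from upstroke start; upstroke 1 ms, full repol 30 ms past apd90
  up_end <- 1
  knots_t <- c(0, up_end, apd50, apd90, apd90 + 30)
  knots_v <- c(0, apa, 0.5 * apa, 0.1 * apa, 0)
  v <- stats::approx(knots_t, knots_v, xout = t_ms, yleft = 0, yright = 0)$y
  v
}

#' Simulate a microelectrode action-potential trace
#'
#' Renders a 2 kHz intracellular voltage trace: paced APs at every
#' stimulus of every drive, then the protocol's DADs injected after full
#' repolarization of the last paced AP, each DAD carrying a full AP at
#' its peak with probability `ta_probability`. The ground truth lists
#' every injected event.
#'
#' @param protocol an [ap_protocol()].
#' @param noise_sd additive Gaussian noise SD (mV).
#' @param fs sampling rate (Hz).
#' @return object of class `ap_trace`: list with `samples` (mV), `fs`,
#'   `stimulus_times_ms`, `drive_frequencies_hz` (per stimulus),
#'   `protocol`, and `truth` (`dads` and `tas` data.frames).
#' @export
simulate_ap_trace <- function(protocol, noise_sd = 0, fs = 2000) {
  stopifnot(inherits(protocol, "ap_protocol"))
  set.seed(protocol$seed)
  apa <- protocol$peak_mv - protocol$mdp_mv
  apd_full <- protocol$apd90_ms + 30 + 1  # ms from upstroke to full repolarization
  stim <- numeric(0); stim_f <- numeric(0)
  t_cur <- 200
  for (f in protocol$pacing_frequencies_hz) {
    n <- if (is.null(protocol$n_paced)) max(1L, round(protocol$drive_duration_s * f))
         else protocol$n_paced
    s <- t_cur + (seq_len(n) - 1L) * 1000 / f
    stim <- c(stim, s); stim_f <- c(stim_f, rep(f, n))
    t_cur <- s[n] + 2000  # 2 s gap after each drive
  }
  last_stim <- stim[length(stim)]
  lat <- vapply(protocol$dad_spec, `[`, 0, 1)
  for (d in lat) if (d <= apd_full)
    stop("invalid-spec: DAD latency ", d, " ms is within the last AP (", apd_full, " ms)")
  # consecutive events must not collide: a triggered AP occupies apd_full ms
  min_gap <- if (protocol$ta_probability > 0) apd_full else 150
  if (length(lat) > 1L && any(diff(sort(lat)) < min_gap))
    stop("invalid-spec: DAD latencies closer than ", min_gap, " ms would overlap")

  dur <- t_cur + (if (length(protocol$dad_spec))
    max(vapply(protocol$dad_spec, `[`, 0, 1)) + 600 else 500)
  n_samp <- ceiling(dur * fs / 1000)
  t <- (seq_len(n_samp) - 1L) * 1000 / fs
  v <- rep(protocol$mdp_mv, n_samp)
  add_ap <- function(v, t0) {
    idx <- which(t >= t0 & t <= t0 + apd_full + 5)
    v[idx] <- protocol$mdp_mv +
      pmax(v[idx] - protocol$mdp_mv, ap_shape(t[idx] - t0, apa, protocol$apd50_ms, protocol$apd90_ms))
    v
  }
  for (s in stim) v <- add_ap(v, s + 1)  # 1 ms latency after the stimulus

  dads <- data.frame(time_ms = numeric(0), amplitude_mv = numeric(0))
  tas <- data.frame(time_ms = numeric(0), dad_id = integer(0))
  dad_sd <- 20  # Gaussian DAD half-width parameter (ms)
  for (i in seq_along(protocol$dad_spec)) {
    d <- protocol$dad_spec[[i]]
    t_peak <- last_stim + 1 + d[1]
    idx <- which(abs(t - t_peak) < 4 * dad_sd)
    v[idx] <- v[idx] + d[2] * exp(-((t[idx] - t_peak)^2) / (2 * dad_sd^2))
    dads <- rbind(dads, data.frame(time_ms = t_peak, amplitude_mv = d[2]))
    if (stats::runif(1) < protocol$ta_probability) {
      v <- add_ap(v, t_peak)
      tas <- rbind(tas, data.frame(time_ms = t_peak, dad_id = i))
    }
  }
  if (noise_sd > 0) v <- v + stats::rnorm(n_samp, sd = noise_sd)
  structure(list(samples = v, fs = fs, stimulus_times_ms = stim,
                 drive_frequencies_hz = stim_f, protocol = protocol,
                 truth = list(dads = dads, tas = tas)),
            class = "ap_trace")
}

#' Extract action-potential features
#'
#' MDP (reported interchangeably as RMP) is the mean over the first 10
#' complexes at the measurement frequency of the mean voltage in a 5 ms
#' window ending 1 ms before each stimulus. APA is the mean difference
#' between the phase-1 peak and the MDP. APD50 and APD90 are measured
#' from the upstroke (max dV/dt after the stimulus) to 50% and 90%
#' repolarization from the peak toward the MDP, averaged over the same
#' complexes.
#'
#' @param trace an `ap_trace` (or compatible list with `samples`, `fs`,
#'   `stimulus_times_ms`).
#' @param frequency_hz measurement frequency; complexes from the drive
#'   closest to it are used (default 1.5 Hz).
#' @param n_complexes complexes to average (>= 10 required).
#' @return object of class `ap_features`: `mdp_mv`, `apa_mv`,
#'   `apd50_ms`, `apd90_ms`.
#' @export
extract_ap_features <- function(trace, frequency_hz = 1.5, n_complexes = 10L) {
  x <- trace$samples; fs <- trace$fs
  t_all <- trace$stimulus_times_ms
  if (!is.null(trace$drive_frequencies_hz)) {
    f <- unique(trace$drive_frequencies_hz)
    fsel <- f[which.min(abs(f - frequency_hz))]
    t_all <- t_all[trace$drive_frequencies_hz == fsel]
  }
  if (length(t_all) < n_complexes)
    stop("insufficient-data: need >= ", n_complexes, " paced complexes")
  stim <- t_all[seq_len(n_complexes)]
  per <- lapply(stim, function(s) {
    i_pre <- ms_to_idx(s - 6, fs):ms_to_idx(s - 1, fs)
    mdp <- mean(x[i_pre])
    win <- ms_to_idx(s, fs):min(length(x), ms_to_idx(s + 80, fs))
    pk_i <- win[which.max(x[win])]
    dv <- dvdt(x, fs)
    up_i <- argmax_absdvdt(dv, ms_to_idx(s, fs), ms_to_idx(s + 15, fs))
    peak <- x[pk_i]
    repol_t <- function(frac) {
      target <- peak - frac * (peak - mdp)
      j <- pk_i
      while (j < length(x) && x[j] > target) j <- j + 1L
      idx_to_ms(j, fs) - idx_to_ms(up_i, fs)
    }
    c(mdp = mdp, apa = peak - mdp, apd50 = repol_t(0.5), apd90 = repol_t(0.9))
  })
  m <- colMeans(do.call(rbind, per))
  structure(list(mdp_mv = m[["mdp"]], apa_mv = m[["apa"]],
                 apd50_ms = m[["apd50"]], apd90_ms = m[["apd90"]]),
            class = "ap_features")
}

# trace-level baseline (diastolic) and amplitude estimates
ap_baseline <- function(trace) {
  x <- trace$samples
  baseline <- stats::quantile(x, 0.2, names = FALSE)  # diastole dominates
  list(baseline = baseline, apa = max(x) - baseline)
}

#' Detect delayed afterdepolarizations
#'
#' Scans the quiescent segment after full repolarization of the last
#' paced AP for transient depolarizations that rise above the diastolic
#' baseline by at least the threshold and return toward it. A
#' depolarization that develops into a full AP (triggered activity) is
#' reported as a DAD at the point where its upstroke begins.
#'
#' @param trace an `ap_trace`.
#' @param last_paced_ap_end_ms start of the search region; computed from
#'   the last stimulus and the trace's repolarization when omitted.
#' @param threshold_frac DAD amplitude threshold as a fraction of the
#'   trace's AP amplitude (about 1 mV for a 73 mV AP); thresholds are
#'   relative so counting is invariant to gain and offset.
#' @param ta_frac amplitude fraction above which an excursion is treated
#'   as a triggered AP rather than a plain DAD.
#' @return data.frame with `time_ms`, `amplitude_mv`, `is_ta_upstroke`.
#' @export
detect_dads <- function(trace, last_paced_ap_end_ms = NULL, threshold_frac = 0.015,
                        ta_frac = 0.6) {
  x <- trace$samples; fs <- trace$fs
  bl <- ap_baseline(trace)
  if (is.null(last_paced_ap_end_ms)) {
    s <- max(trace$stimulus_times_ms)
    j <- ms_to_idx(s + 30, fs)
    # forward to within 10% of the diastolic baseline (past 90% repolarization)
    while (j < length(x) && x[j] > bl$baseline + 0.1 * bl$apa) j <- j + 1L
    last_paced_ap_end_ms <- idx_to_ms(j, fs)
  }
  i0 <- max(1L, ms_to_idx(last_paced_ap_end_ms, fs))
  thr <- threshold_frac * bl$apa
  # advance past the repolarization tail: the region begins only once the
  # trace has actually returned to the diastolic baseline
  while (i0 < length(x) && x[i0] > bl$baseline + thr) i0 <- i0 + 1L
  above <- x > bl$baseline + thr
  above[seq_len(min(i0, length(x)))] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(time_ms = numeric(0), amplitude_mv = numeric(0),
                    is_ta_upstroke = logical(0))
  dv <- dvdt(x, fs)
  for (k in which(r$values)) {
    seg <- starts[k]:ends[k]
    pk <- seg[which.max(x[seg])]
    amp <- x[pk] - bl$baseline
    if (amp >= ta_frac * bl$apa) {
      # full AP riding the DAD: mark the DAD at the start of the upstroke
      up <- seg[which(dv[seg] > 0.2 * max(dv[seg]))[1L]]
      out <- rbind(out, data.frame(time_ms = idx_to_ms(up, fs),
                                   amplitude_mv = x[up] - bl$baseline,
                                   is_ta_upstroke = TRUE))
    } else {
      out <- rbind(out, data.frame(time_ms = idx_to_ms(pk, fs), amplitude_mv = amp,
                                   is_ta_upstroke = FALSE))
    }
  }
  out
}

#' Detect triggered activity
#'
#' TA is a full AP arising at the peak of a DAD: for each detected DAD,
#' the following excursion must reach at least `ta_frac` of the trace's
#' AP amplitude and cross the mid-upstroke level (baseline + 55% of the
#' AP amplitude, about -40 mV for a normal trace).
#'
#' @param trace an `ap_trace`.
#' @param dads data.frame from [detect_dads()].
#' @param ta_frac full-AP amplitude fraction.
#' @param search_ms window after each DAD in which the upstroke must
#'   complete.
#' @return data.frame with `time_ms` (upstroke start) and `dad_id` (row
#'   of `dads`).
#' @export
detect_ta <- function(trace, dads, ta_frac = 0.6, search_ms = 120) {
  x <- trace$samples; fs <- trace$fs
  bl <- ap_baseline(trace)
  out <- data.frame(time_ms = numeric(0), dad_id = integer(0))
  for (i in seq_len(nrow(dads))) {
    i0 <- ms_to_idx(dads$time_ms[i], fs)
    i1 <- min(length(x), ms_to_idx(dads$time_ms[i] + search_ms, fs))
    seg <- x[i0:i1]
    reaches <- max(seg) - bl$baseline >= ta_frac * bl$apa
    crosses <- any(seg >= bl$baseline + 0.55 * bl$apa)
    if (reaches && crosses)
      out <- rbind(out, data.frame(time_ms = dads$time_ms[i], dad_id = i))
  }
  out
}

#' Triggered-activity rate per trial
#'
#' The dose-response metric: total number of TA produced (with pacing of
#' at least 4 frequencies) divided by the number of trials.
#'
#' @param ta_counts TA counts, one per trial.
#' @param n_trials number of trials (defaults to `length(ta_counts)`).
#' @return rate (TA per trial).
#' @export
ta_rate <- function(ta_counts, n_trials = length(ta_counts)) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (any(ta_counts < 0)) stop("counts must be nonnegative")
  sum(ta_counts) / n_trials
}
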