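# Shared fixtures, built in code. The cache avoids re-simulating the same
# episode across test files within one run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

std_grid <- function() fixture("std_grid", function() make_grid())

small_grid <- function() fixture("small_grid", function() make_grid(9, 8))

focal_recording <- function(noise_sd = 0, seed = 9, layer = "endo", needle = 12) {
  g <- std_grid()
  spec <- mechanism_spec("focal", origin_site = grid_site_id_pub(g, needle, layer))
  simulate_episode(g, spec, noise_sd = noise_sd, seed = seed)
}

reentry_recording <- function(noise_sd = 0, seed = 2, n_complexes = 3) {
  g <- std_grid()
  spec <- mechanism_spec("reentry", circuit_sites = default_circuit(g, "endo"),
                         n_complexes = n_complexes)
  simulate_episode(g, spec, noise_sd = noise_sd, seed = seed)
}

# site lookup without relying on the unexported helper
grid_site_id_pub <- function(grid, needle, layer) {
  st <- grid$sites
  st$site[st$needle == needle & st$layer == layer]
}

# detection error (ms) per channel for one beat against ground truth
recovery_errors <- function(rec, events, beat) {
  eb <- events[events$beat == beat, ]
  eb <- eb[order(eb$channel), ]
  abs(eb$abs_ms - rec$truth_onsets[, beat])
}

# brute-force Floyd-Warshall shortest paths, the independent geodesic oracle
fw_geodesic <- function(grid) {
  st <- grid$sites
  n <- nrow(st)
  d <- matrix(Inf, n, n); diag(d) <- 0
  adj <- grid$adjacency
  for (i in seq_len(n)) for (j in seq_len(n)) if (adj[i, j])
    d[i, j] <- sqrt((st$x[i] - st$x[j])^2 + (st$y[i] - st$y[j])^2 +
                    (st$depth[i] - st$depth[j])^2)
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# exhaustive hypergeometric enumeration, the independent Fisher oracle;
# probabilities from choose() only, no stats::dhyper
fisher_oracle <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; k <- a + c_; n <- a + b + c_ + d
  lo <- max(0, k - (n - r1)); hi <- min(r1, k)
  logp <- function(x) lchoose(r1, x) + lchoose(n - r1, k - x) - lchoose(n, k)
  ps <- vapply(lo:hi, function(x) exp(logp(x)), numeric(1))
  p_obs <- exp(logp(a))
  min(1, sum(ps[ps <= p_obs * (1 + 1e-7)]))
}

# Activation maps built directly from the published worked example's printed
# site times (focal endo at -53, endo reentry entered at -69 with progression
# -11/39/60, endo reentry at -38 with 21/105, epicardial focal), used as
# classification fixtures without going through signal detection.
worked_map <- function(grid, kind, layer, entry_time, circuit_times = NULL,
                       cl = 230, complex = 1) {
  st <- grid$sites
  geo <- grid_geodesic(grid)
  circ <- default_circuit(grid, layer)
  if (kind == "focal") {
    origin <- grid_site_id_pub(grid, 12, layer)
    tt <- entry_time + geo[origin, ] / 0.6
  } else {
    tt <- entry_time + apply(circuit_times - entry_time +
                               geo[circ, , drop = FALSE] / 0.6, 2, min)
    tt[circ] <- circuit_times
  }
  m <- data.frame(site = st$site, needle = st$needle, layer = st$layer,
                  time_ms = tt, x_mm = st$x, y_mm = st$y)
  structure(m, class = c("activation_map", "data.frame"), complex = complex,
            qrs_onset_ms = 150 + (complex - 1) * cl)
}

worked_pair <- function(grid, kind, layer, entry_time, circuit_times = NULL, cl = 230) {
  lapply(1:2, function(k) worked_map(grid, kind, layer, entry_time,
                                     circuit_times, cl, complex = k))
}

# hand-built AP trace from an arbitrary voltage shape, repeated for n beats
hand_ap_trace <- function(beat_fun, n_beats = 10, cl_ms = 667, fs = 2000,
                          mdp = -80) {
  stim <- 100 + (seq_len(n_beats) - 1L) * cl_ms
  n <- ceiling((stim[n_beats] + cl_ms) * fs / 1000)
  x <- rep(mdp, n)
  tt <- (seq_len(n) - 1L) * 1000 / fs
  for (s in stim) {
    idx <- which(tt >= s & tt <= s + cl_ms - 1)
    x[idx] <- vapply(tt[idx] - s, beat_fun, numeric(1))
  }
  list(samples = x, fs = fs, stimulus_times_ms = stim,
       drive_frequencies_hz = rep(1000 / cl_ms, n_beats))
}
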