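test_that("focal simulation: origin strictly earliest, delays follow geometry", {
  g <- std_grid()
  origin <- grid_site_id_pub(g, 12, "endo")
  spec <- mechanism_spec("focal", origin_site = origin, cycle_length_ms = 180,
                         conduction_velocity_mm_per_ms = 0.6)
  rec <- simulate_episode(g, spec, noise_sd = 0, seed = 1)
  geo <- grid_geodesic(g)
  for (k in seq_len(ncol(rec$truth_onsets))) {
    on <- rec$truth_onsets[, k]
    expect_equal(which.min(on), origin)
    expect_true(all(on[-origin] > on[origin]))
    # delay equals geodesic distance / velocity, exactly
    expect_equal(on - on[origin], geo[origin, ] / 0.6, tolerance = 1e-9)
    # adjacent sites activate well before half the cycle length
    nb <- which(g$adjacency[origin, ])
    expect_true(all(on[nb] - on[origin] < 0.5 * 180))
  }
})

test_that("nearest-neighbor focal delay equals distance over velocity", {
  g <- make_grid(4, 8, "endo")
  origin <- 1L
  spec <- mechanism_spec("focal", origin_site = origin, n_complexes = 1L,
                         conduction_velocity_mm_per_ms = 0.5)
  rec <- simulate_episode(g, spec, seed = 1)
  on <- rec$truth_onsets[, 1]
  d <- sqrt((g$sites$x - g$sites$x[origin])^2 + (g$sites$y - g$sites$y[origin])^2)
  nn <- which(d == min(d[d > 0]))[1]
  expect_equal(on[nn] - on[origin], 8 / 0.5, tolerance = 1e-9)  # 16 ms
})

test_that("reentry: earliest of each complex is adjacent to latest of previous", {
  rec <- reentry_recording(n_complexes = 4)
  g <- std_grid()
  on <- rec$truth_onsets
  for (k in 2:ncol(on)) {
    e <- which.min(on[, k]); l <- which.max(on[, k - 1])
    expect_true(e == l || g$adjacency[e, l])
  }
  # diastolic bridging: the gap from last activity to the next entry is short
  gaps <- vapply(2:ncol(on), function(k) min(on[, k]) - max(on[, k - 1]), numeric(1))
  expect_true(all(gaps > 0 & gaps <= 0.5 * 180))
})

test_that("reentry requires a closed circuit and >= 3 sites", {
  g <- std_grid()
  expect_error(mechanism_spec("reentry", circuit_sites = c(1, 4)), ">= 3")
  far <- c(grid_site_id_pub(g, 1, "endo"), grid_site_id_pub(g, 5, "endo"),
           grid_site_id_pub(g, 23, "endo"))
  expect_error(simulate_episode(g, mechanism_spec("reentry", circuit_sites = far)),
               "closed")
})

test_that("unidirectional block site loses >75% voltage then recovers", {
  g <- std_grid()
  circ <- default_circuit(g, "endo")
  blk <- circ[2]
  spec <- mechanism_spec("reentry", circuit_sites = circ, block_site = blk)
  rec <- simulate_episode(g, spec, seed = 3)
  a <- rec$truth_amplitudes
  expect_lt(a[blk, 1], 0.25 * a[blk, 3])
  expect_gt(a[blk, 2], a[blk, 1])
})

test_that("simulation is bit-identical for identical seed and arguments", {
  r1 <- simulate_episode(std_grid(), mechanism_spec("focal", origin_site = 34),
                         noise_sd = 0.5, seed = 42)
  r2 <- simulate_episode(std_grid(), mechanism_spec("focal", origin_site = 34),
                         noise_sd = 0.5, seed = 42)
  expect_identical(r1$session$signals, r2$session$signals)
  expect_identical(r1$truth_onsets, r2$truth_onsets)
  r3 <- simulate_episode(std_grid(), mechanism_spec("focal", origin_site = 34),
                         noise_sd = 0.5, seed = 43)
  expect_false(identical(r1$session$signals, r3$session$signals))
})

test_that("per-channel truth onsets always respect the 65 ms refractory bound", {
  for (rec in list(focal_recording(), reentry_recording(),
                   simulate_episode(std_grid(),
                     mechanism_spec("vf_onset", origin_site = 34,
                                    n_complexes = 10, cycle_length_ms = 150),
                     seed = 5))) {
    gaps <- apply(rec$truth_onsets, 1, function(z) min(diff(z)))
    expect_true(all(gaps >= 65))
    expect_true(all(is.finite(rec$truth_onsets)))
    expect_true(max(rec$truth_onsets) < rec$session$duration_ms)
  }
})

test_that("VF prefix size is validated and episodes carry vf beat types", {
  expect_error(mechanism_spec("vf_onset", origin_site = 1, n_complexes = 5),
               "\\[8, 40\\]")
  expect_error(mechanism_spec("vf_onset", origin_site = 1, n_complexes = 50),
               "\\[8, 40\\]")
  spec <- mechanism_spec("vf_onset", origin_site = 34, n_complexes = 8,
                         cycle_length_ms = 150)
  rec <- simulate_episode(std_grid(), spec, seed = 7)
  expect_true(all(rec$session$beat_types == "vf"))
  expect_equal(ncol(rec$truth_onsets), 8)
})

test_that("reentry patterned on the worked endocardial example keeps its order", {
  # endo circuit entered at -69 ms with progression through -11, 39, 60 ms:
  # the simulated circuit times must reproduce that ordering
  g <- std_grid()
  circ <- default_circuit(g, "endo")
  spec <- mechanism_spec("reentry", circuit_sites = circ, cycle_length_ms = 230,
                         entry_offset_ms = -69, bridge_frac = 0.56)
  rec <- simulate_episode(g, spec, seed = 1)
  tt <- rec$truth_onsets[circ, 1] - rec$qrs_onsets_ms[1]
  expect_equal(order(tt), 1:4)
  expect_equal(tt[1], -69)
  expect_equal(tt[4], -69 + 0.56 * 230, tolerance = 1e-9)
})

test_that("study fixture loads with the printed group structure", {
  apo <- load_study_fixture("APO")
  expect_length(apo, 10)
  a1 <- apo[[1]]
  expect_equal(a1$dog_id, "A1")
  expect_equal(vapply(a1$inductions, `[[`, "", "type"), c("VT", "VT", "NI", "NI"))
  expect_equal(a1$inductions[[1]]$mechanisms, "EpFo")

  oxy <- load_study_fixture("OXY")
  o9 <- oxy[[9]]
  expect_equal(o9$dog_id, "O9")
  expect_equal(vapply(o9$inductions, `[[`, "", "type"), c("VF", "VF", "VF", "NI"))
  expect_equal(lapply(o9$inductions, `[[`, "mechanisms")[1:3],
               list("R", "RE", "RE"))

  expect_length(load_study_fixture("CONTROL"), 27)
  expect_length(load_study_fixture("BOTH"), 8)
  expect_error(load_study_fixture("XXX"))

  all_recs <- load_study_fixture("all")
  expect_length(all_recs, 54)
  for (r in all_recs) for (ind in r$inductions) {
    expect_true(ind$type %in% c("VT", "VF", "VT_ns", "NI", "nd"))
    expect_true(all(ind$mechanisms %in% c("EFo", "EpFo", "R", "RE")))
    if (ind$type %in% c("NI", "nd")) expect_length(ind$mechanisms, 0)
  }
})
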