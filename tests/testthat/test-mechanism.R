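test_that("the worked fixtures classify as printed", {
  g <- std_grid()
  # VT-F: endocardial focal, earliest -53
  f <- classify_beat_mechanism(worked_pair(g, "focal", "endo", -53), g, 230)
  expect_equal(f$kind, "focal"); expect_equal(f$layer, "endo")
  # VT-O: epicardial focal
  o <- classify_beat_mechanism(worked_pair(g, "focal", "epi", -20), g, 230)
  expect_equal(o$kind, "focal"); expect_equal(o$layer, "epi")
  # VT-H: endocardial reentry, -69 entry with -11/39/60 progression
  h <- classify_beat_mechanism(
    worked_pair(g, "reentry", "endo", -69, c(-69, -11, 39, 60), cl = 230), g, 230)
  expect_equal(h$kind, "reentry"); expect_equal(h$layer, "endo")
  # VT-L: endocardial reentry, -38 entry with 21/105 progression
  l <- classify_beat_mechanism(
    worked_pair(g, "reentry", "endo", -38, c(-38, 21, 60, 105), cl = 280), g, 280)
  expect_equal(l$kind, "reentry"); expect_equal(l$layer, "endo")
})

test_that("simulated episodes are classified with full ground-truth accuracy", {
  g <- std_grid()
  circ <- default_circuit(g, "endo")
  n_ok <- 0L; n <- 0L
  for (s in 1:5) {
    set.seed(s)
    needle <- sample(1:23, 1); layer <- sample(c("endo", "epi"), 1)
    rec_f <- simulate_episode(g, mechanism_spec("focal",
      origin_site = grid_site_id_pub(g, needle, layer)), seed = s)
    r_f <- classify_session(rec_f$session)
    n <- n + 1L
    n_ok <- n_ok + (r_f$majority$kind == "focal" && r_f$majority$layer == layer)
    rec_r <- simulate_episode(g, mechanism_spec("reentry", circuit_sites = circ),
                              seed = s + 50)
    r_r <- classify_session(rec_r$session)
    n <- n + 1L
    n_ok <- n_ok + (r_r$majority$kind == "reentry" && r_r$majority$layer == "endo")
  }
  expect_equal(n_ok, n)
})

test_that("a complex is never simultaneously focal and reentrant", {
  # the call returns exactly one kind; indeterminate when evidence is absent
  g <- std_grid()
  call <- classify_beat_mechanism(worked_pair(g, "focal", "endo", -30), g, 200)
  expect_true(call$kind %in% c("focal", "reentry", "indeterminate"))
  tiny <- lapply(1:2, function(k) {
    m <- data.frame(site = 1:2, needle = 1, layer = c("endo", "mid"),
                    time_ms = c(0, 10))
    structure(m, class = c("activation_map", "data.frame"), complex = k,
              qrs_onset_ms = k * 200)
  })
  expect_equal(classify_beat_mechanism(tiny, g, 200)$kind, "indeterminate")
  expect_error(classify_beat_mechanism(tiny[1], g, 200), ">= 2")
})

test_that("block evidence is read from the amplitude series", {
  g <- std_grid()
  circ <- default_circuit(g, "endo")
  spec <- mechanism_spec("reentry", circuit_sites = circ, block_site = circ[2])
  rec <- simulate_episode(g, spec, seed = 8)
  r <- classify_session(rec$session)
  expect_equal(r$calls[[1]]$evidence$block_sites, circ[2])
  expect_equal(r$kinds[1], "reentry")
})

test_that("episode typing is total and follows the duration rules", {
  cl <- 300
  t12 <- seq(0, 12000, by = cl)              # 12 s, pace-terminated
  expect_equal(classify_episode(t12, "pacing")$type, "sustained_VT")
  expect_equal(classify_episode(seq(0, 11000, by = cl), "spontaneous")$type,
               "sustained_VT")               # >= 10 s even if self-terminated
  expect_equal(classify_episode(c(0, 300, 600), "spontaneous")$type,
               "nonsustained_VT")            # 3 complexes, < 10 s
  expect_equal(classify_episode(c(0, 300), "spontaneous")$type, "not_an_episode")
  vf <- classify_episode(seq(0, 3000, by = 120), "shock",
                         qrs_variability = TRUE, pressure_collapse = TRUE)
  expect_equal(vf$type, "VF")
  expect_equal(vf$analyzed_prefix, c(1L, 26L))
  vf_long <- classify_episode(seq(0, 8000, by = 120), "shock",
                              qrs_variability = TRUE, pressure_collapse = TRUE)
  expect_equal(vf_long$analyzed_prefix[2], 40L)  # prefix capped at 40
  # variability without pressure collapse is not VF
  expect_equal(classify_episode(t12, "pacing", qrs_variability = TRUE)$type,
               "sustained_VT")
  expect_error(classify_episode(numeric(0)), "complex")
})

purkinje_case <- function(purk, lead = 5, seed = 6) {
  g <- std_grid()
  spec <- mechanism_spec("paced", origin_site = grid_site_id_pub(g, 12, "endo"),
                         purkinje = purk, n_complexes = 2, purkinje_lead_ms = lead)
  rec <- simulate_episode(g, spec, seed = seed)
  ev <- detect_session(rec$session)
  list(session = rec$session, events = ev[ev$beat == 1, ])
}

test_that("Purkinje origin needs the spike on the beat and both references", {
  with_spike <- purkinje_case(TRUE)
  without <- purkinje_case(FALSE)
  expect_true(detect_purkinje_origin(with_spike, with_spike, with_spike))
  expect_false(detect_purkinje_origin(without, without, without))
  # monotone: removing the prepotential anywhere turns the call false
  expect_false(detect_purkinje_origin(without, with_spike, with_spike))
  expect_false(detect_purkinje_origin(with_spike, without, with_spike))
  expect_false(detect_purkinje_origin(with_spike, with_spike, without))
  # lead outside 1-11 ms does not qualify
  far <- purkinje_case(TRUE, lead = 15)
  expect_false(detect_purkinje_origin(far, far, far))
  # missing references are indeterminate
  expect_true(is.na(detect_purkinje_origin(with_spike, NULL, with_spike)))
})
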