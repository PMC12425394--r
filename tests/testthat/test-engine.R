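test_that("empty horizon produces an empty array and no events", {
  dom <- dom_rect40()
  cfg <- sim_config(dom, default_dyn(r_c = 0.002), nucleation_params("LDD"),
                    T_end = 0, obs_interval = 1, seed = 1)
  s <- run_simulation(cfg)
  expect_equal(nrow(array_snapshot(s)), 0)
  expect_equal(unname(s$counts["events"]), 0)
  expect_equal(s$n_c, 0)
})

test_that("identical seeds give identical runs", {
  dom <- dom_rect40()
  mk <- function() {
    cfg <- sim_config(dom, default_dyn(r_c = 0.0025),
                      nucleation_params("LDD"), T_end = 600,
                      obs_interval = 100, seed = 99)
    run_simulation(cfg)
  }
  a <- mk(); b <- mk()
  expect_identical(a$event_log, b$event_log)
  expect_identical(a$snapshot, b$snapshot)
  expect_identical(a$nucleations, b$nucleations)
})

test_that("observation sampling does not perturb the event sequence", {
  dom <- dom_rect40()
  run_with_obs <- function(interval) {
    cfg <- sim_config(dom, default_dyn(r_c = 0.0025),
                      nucleation_params("LDD"), T_end = 500,
                      obs_interval = interval, seed = 12)
    run_simulation(cfg)$event_log
  }
  expect_identical(run_with_obs(500), run_with_obs(5))
})

test_that("array length bookkeeping matches the kinematic rates", {
  # non-interacting parallel microtubules: density grows at
  # n * (v_plus - v_tm) / A between observations
  dom <- dom_rect40()
  im <- data.frame(face = 1L, x = seq(2, 38, by = 4), y = seq(2, 38, by = 4),
                   theta = 0)
  s <- run_simulation(quiet_config(dom, im, T_end = 100))
  ts <- s$time_series
  incr <- diff(ts$density) / diff(ts$time)
  expect_equal(incr, rep(nrow(im) * 0.04 / 1600, length(incr)),
               tolerance = 1e-9)
})

test_that("constructed collisions resolve at the right place and angle", {
  dom <- dom_rect40()
  # zipper at 30 degrees: tip reorients along the target
  im <- data.frame(face = 1L,
                   x = c(10, 12), y = c(12, 10),
                   theta = c(0, pi / 6),
                   length = c(30, 0))
  s <- run_simulation(quiet_config(dom, im, T_end = 120, v_tm = 1e-6))
  expect_identical(s$event_log$event[s$event_log$event != "nucleation"][1],
                   "zipper")
  snap <- array_snapshot(s)
  segs2 <- snap[snap$mt_id == 2, ]
  expect_equal(nrow(segs2), 2)
  expect_equal(segs2$theta[2], 0, tolerance = 1e-9)  # co-aligned with target

  # antiparallel entrainment: incoming at 150 degrees relative to the target
  im2 <- data.frame(face = 1L, x = c(10, 20), y = c(12, 10),
                    theta = c(0, 5 * pi / 6),
                    length = c(30, 0))
  s2 <- run_simulation(quiet_config(dom, im2, T_end = 120, v_tm = 1e-6))
  snap2 <- array_snapshot(s2)
  seg22 <- snap2[snap2$mt_id == 2, ]
  expect_equal(abs(seg22$theta[nrow(seg22)]), pi, tolerance = 1e-9)

  # crossover at 90 degrees with P_cat = 0: the tip passes straight through
  im3 <- data.frame(face = 1L, x = c(10, 20), y = c(12, 10),
                    theta = c(0, pi / 2), length = c(30, 0))
  s3 <- run_simulation(quiet_config(dom, im3, T_end = 60, v_tm = 1e-6,
                                    P_cat = 0))
  el3 <- s3$event_log
  expect_true("crossover" %in% el3$event)
  snap3 <- array_snapshot(s3)
  expect_equal(nrow(snap3[snap3$mt_id == 2, ]), 1)  # still one straight segment
})

test_that("collision with a bundle is a single collision", {
  dom <- dom_rect40()
  # two collinear overlapping targets plus one incoming perpendicular tip
  im <- data.frame(face = 1L, x = c(10, 12, 20), y = c(15, 15, 10),
                   theta = c(0, 0, pi / 2), length = c(20, 20, 0))
  s <- run_simulation(quiet_config(dom, im, T_end = 150, v_tm = 1e-6,
                                   P_cat = 1))
  el <- s$event_log
  hits <- el[el$event == "induced_catastrophe" & el$mt_id == 3, ]
  expect_equal(nrow(hits), 1)
  # bundle bookkeeping: the chosen target is the lowest microtubule id
  expect_equal(hits$other_id, 1)
})

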