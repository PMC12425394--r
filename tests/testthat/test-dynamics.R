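test_that("collision outcomes follow the angle rules", {
  dyn <- default_dyn()
  set.seed(1)
  expect_true(all(replicate(50, resolve_collision(30, dyn)) == "zipper"))
  # the threshold angle itself zippers (closed interval)
  expect_identical(resolve_collision(40, dyn), "zipper")
  # steep angles: catastrophe with probability P_cat, else crossover
  set.seed(2)
  out <- replicate(4000, resolve_collision(60, dyn))
  expect_false(any(out == "zipper"))
  expect_equal(mean(out == "catastrophe"), 0.5,
               tolerance = 3 * sqrt(0.25 / 4000) / 0.5)
  dyn1 <- default_dyn(P_cat = 1)
  expect_true(all(replicate(20, resolve_collision(80, dyn1)) == "catastrophe"))
  expect_error(resolve_collision(95, dyn))
  expect_error(resolve_collision(-1, dyn))
})

test_that("effective rates implement the cap and rescue biases", {
  cyl <- dom_cyl()
  dyn <- default_dyn(cap_rc_factor = 1.08, b_max = 0.08, theta_r = 90)
  expect_equal(effective_rc(cyl, 1L, dyn), dyn$r_c)
  expect_equal(effective_rc(cyl, 2L, dyn), dyn$r_c * 1.08)
  expect_equal(effective_rc(dom_rect40(), 1L, dyn), dyn$r_c)
  # cosine bias anchors: maximum at theta_r, zero at theta_r + 90 degrees,
  # half at theta_r +/- 45 degrees
  rr <- dyn$r_r
  expect_equal(effective_rr(pi / 2, dyn), rr * 1.08)
  expect_equal(effective_rr(0, dyn), rr, tolerance = 1e-12)
  expect_equal(effective_rr(pi / 4, dyn), rr * 1.04)
  expect_equal(effective_rr(3 * pi / 4, dyn), rr * 1.04)
})

test_that("event-free kinematics: growth, shrinkage and disappearance", {
  dom <- dom_rect40()
  # growing for 10 s: net +(v_plus - v_tm) * 10 = 0.4
  s <- run_simulation(quiet_config(dom,
                                   data.frame(face = 1L, x = 5, y = 5, theta = 0.3),
                                   T_end = 10))
  snap <- array_snapshot(s)
  expect_equal(sum(sqrt((snap$u2 - snap$u1)^2 + (snap$v2 - snap$v1)^2)),
               0.4, tolerance = 1e-9)

  # catastrophe then shrink at v_minus + v_tm until disappearance
  cfg <- sim_config(dom, dynamic_params(r_c = 50, r_r = 0),
                    nucleation_params("ISO", r_n = 0),
                    T_end = 60, obs_interval = 30, seed = 5,
                    initial_mts = data.frame(face = 1L, x = 5, y = 5,
                                             theta = 0, length = 2))
  s2 <- run_simulation(cfg)
  el <- s2$event_log
  t_cat <- el$time[el$event == "catastrophe"][1]
  t_dis <- el$time[el$event == "disappearance"][1]
  len_at_cat <- 2 + (0.05 - 0.01) * t_cat
  expect_equal(t_dis - t_cat, len_at_cat / (0.08 + 0.01), tolerance = 1e-6)
  expect_equal(nrow(array_snapshot(s2)), 0)
})

test_that("catastrophe waiting times are exponential with the nominal rate", {
  # many far-apart microtubules on a large domain, no rescue
  dom <- domain_spec("periodic_rectangle", L = 400, H = 400)
  set.seed(8)
  n <- 250
  im <- data.frame(face = 1L, x = stats::runif(n, 0, 400),
                   y = stats::runif(n, 0, 400),
                   theta = stats::runif(n, -pi, pi))
  cfg <- sim_config(dom, dynamic_params(r_c = 0.002, r_r = 0, P_cat = 0),
                    nucleation_params("ISO", r_n = 0),
                    T_end = 4000, obs_interval = 2000, seed = 8,
                    initial_mts = im)
  s <- run_simulation(cfg)
  el <- s$event_log
  waits <- el$time[el$event == "catastrophe"]
  # censoring at T_end = 4000 removes ~0.03 % of the mass; negligible
  expect_gt(length(waits), 200)
  expect_equal(mean(waits), 500, tolerance = 3 / sqrt(length(waits)))
  expect_gt(dist_check_ks(waits, "pexp", rate = 0.002), 0.01)
})

test_that("the engine finds the first crossing of a constructed tip path", {
  dom <- dom_rect40()
  # perpendicular target crossing u = 1 ahead of the tip: collision after
  # 1 micrometre of growth, at 90 degrees
  im <- data.frame(face = 1L, x = c(21, 20), y = c(15, 20),
                   theta = c(pi / 2, 0), length = c(10, 0))
  cfg <- sim_config(dom, dynamic_params(r_c = 0, r_r = 0, P_cat = 1,
                                        v_tm = 1e-9),
                    nucleation_params("ISO", r_n = 0),
                    T_end = 30, obs_interval = 30, seed = 1,
                    initial_mts = im)
  s <- run_simulation(cfg)
  el <- s$event_log
  hit <- el[el$event == "induced_catastrophe", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$time, 1 / 0.05, tolerance = 1e-6)
  expect_equal(hit$mt_id, 2L)
  expect_equal(hit$other_id, 1L)
})

test_that("brute-force crossing sweep is correct on constructed cases", {
  # over random static arrays, the event engine's first collision position
  # and time must equal the first brute-force crossing of the tip path
  # (targets frozen by near-zero kinematic rates for the comparison window)
  dom <- dom_rect40()
  # single perpendicular target 1 micrometre ahead
  segs <- data.frame(mt_id = 1L, face_id = 1L, u1 = 21, v1 = 10,
                     u2 = 21, v2 = 30)
  hits <- brute_force_collisions(dom, segs, 1L, 20, 20, 0, horizon = 5)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$dist, 1)
  expect_equal(abs(hits$theta_seg), pi / 2)
  # empty set
  expect_equal(nrow(brute_force_collisions(dom, segs[0, ], 1L, 20, 20, 0, 5)), 0)
  # crossings are returned in increasing distance and wrap the seam
  set.seed(9)
  segs2 <- toy_uniform_isotropic(dom, 40L, len = 4)
  h2 <- brute_force_collisions(dom, segs2, 1L, 39, 20, 0, horizon = 20)
  expect_true(all(diff(h2$dist) >= -1e-12))
})
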