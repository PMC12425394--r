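test_that("toy generators are deterministic and satisfy segment invariants", {
  cyl <- dom_cyl()
  set.seed(5)
  a <- toy_uniform_isotropic(cyl, 50, len = 2)
  set.seed(5)
  b <- toy_uniform_isotropic(cyl, 50, len = 2)
  expect_identical(a, b)
  # pieces lie within their face bounds and total length is conserved
  for (segs in list(a, toy_transverse_ring(cyl), toy_single_band(cyl, n = 4))) {
    lens <- sqrt((segs$u2 - segs$u1)^2 + (segs$v2 - segs$v1)^2)
    expect_true(all(lens > 0))
    mantle <- segs[segs$face_id == 1L, ]
    expect_true(all(mantle$u1 >= -1e-9 & mantle$u1 <= cyl$L + 1e-9))
    expect_true(all(mantle$v1 >= -1e-9 & mantle$v1 <= cyl$C + 1e-9))
  }
  expect_equal(sum(with(toy_uniform_isotropic(dom_rect40(), 20, len = 3),
                        sqrt((u2 - u1)^2 + (v2 - v1)^2))), 60, tolerance = 1e-9)
})

test_that("the fixed-step reference reproduces simple kinematics", {
  dom <- domain_spec("periodic_rectangle", L = 20, H = 20)
  cfg <- sim_config(dom, dynamic_params(r_c = 0, r_r = 0),
                    nucleation_params("ISO", r_n = 0),
                    T_end = 10, obs_interval = 10, seed = 1,
                    initial_mts = data.frame(face = 1L, x = 5, y = 5,
                                             theta = 0, length = 1))
  ref <- small_dt_reference(cfg, dt = 0.01)
  expect_equal(ref$plus[1] - ref$minus[1], 1 + 0.04 * 10, tolerance = 1e-9)
})

test_that("halving the reference step does not change a toy event sequence", {
  cfg <- toy_oracle_config(123, n_mt = 8L, T_end = 40)
  e1 <- small_dt_reference(cfg, dt = 0.01)$events
  e2 <- small_dt_reference(cfg, dt = 0.005)$events
  expect_identical(e1[, c("event", "mt_id", "other_id")],
                   e2[, c("event", "mt_id", "other_id")])
  if (nrow(e1)) expect_lt(max(abs(e1$time - e2$time)), 0.011)
})

test_that("reference Bernoulli switching matches the exponential rates", {
  dom <- domain_spec("periodic_rectangle", L = 20, H = 20)
  set.seed(77)
  n <- 50
  im <- data.frame(face = 1L, x = stats::runif(n, 0, 20),
                   y = stats::runif(n, 0, 20),
                   theta = stats::runif(n, -pi, pi), length = 0.01)
  cfg <- sim_config(dom, dynamic_params(r_c = 0.01, r_r = 0, P_cat = 0),
                    nucleation_params("ISO", r_n = 0),
                    T_end = 60, obs_interval = 60, seed = 77,
                    initial_mts = im)
  set.seed(78)
  ref <- small_dt_reference(cfg, dt = 0.01)
  ev <- ref$events
  n_cat <- sum(ev$event == "catastrophe")
  # expected fraction switched by t = 60 at rate 0.01: 1 - exp(-0.6)
  p <- 1 - exp(-0.6)
  expect_equal(n_cat / n, p, tolerance = 3 * sqrt(p * (1 - p) / n) / p)
})
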