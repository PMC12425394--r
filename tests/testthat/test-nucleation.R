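test_that("GDD split follows the saturating density dependence", {
  np <- nucleation_params("GDD")
  half <- gdd_split(0.1, np)
  expect_equal(unname(half), c(0.0005, 0.0005))
  expect_equal(unname(gdd_split(0, np)), c(0, 0.001))
  expect_equal(unname(gdd_split(1e9, np)), c(0.001, 0), tolerance = 1e-8)
  # bound + unbound == r_n exactly for any density
  for (rho in c(0.01, 0.3, 2, 40)) {
    expect_equal(sum(gdd_split(rho, np)), np$r_n, tolerance = 1e-15)
  }
  # reduced-unbound variant scales only the unbound share
  npr <- nucleation_params("GDD", unbound_factor = 0.083)
  expect_equal(gdd_split(0.1, npr)[["unbound"]], 0.0005 * 0.083)
  expect_equal(gdd_split(0.1, npr)[["bound"]], 0.0005)
})

test_that("reach probability follows the diffusion-survival closed form", {
  np <- nucleation_params("LDD")
  expect_equal(p_reach(0, np), 1)
  expect_equal(p_reach(1, np), exp(-0.002 / (4 * 0.013)))
  expect_equal(p_reach(1, np), 0.962269, tolerance = 1e-6)
  expect_equal(p_reach(1.5, np), 0.917100, tolerance = 1e-6)
  expect_true(all(diff(p_reach(seq(0, 3, 0.1), np)) < 0))
})

test_that("the relative-angle distribution reproduces its components", {
  np <- nucleation_params("LDD")
  # the full distribution is normalized: point masses + sideways integral
  side <- stats::integrate(function(x) branch_angle_density(x, np),
                           -pi, pi, subdivisions = 2000L,
                           rel.tol = 1e-10)$value
  expect_equal(np$f_forward + np$f_backward + side, 1, tolerance = 1e-6)

  set.seed(31)
  draw <- relative_angle_sampler(np)(1e5)
  se3 <- function(p, n) 3 * sqrt(p * (1 - p) / n)
  expect_equal(mean(draw == 0), 0.31, tolerance = se3(0.31, 1e5) / 0.31)
  expect_equal(mean(draw == pi), 0.07, tolerance = se3(0.07, 1e5) / 0.07)
  # sideways part against the ellipse density (chi-squared on 36 bins)
  sw <- draw[draw != 0 & draw != pi]
  br <- seq(-pi, pi, length.out = 37)
  counts <- table(cut(sw, br))
  probs <- vapply(seq_len(36), function(i) {
    stats::integrate(function(x) branch_angle_density(x, np),
                     br[i], br[i + 1])$value
  }, numeric(1))
  expect_gt(dist_check_chisq(as.numeric(counts), probs), 0.01)
  # branches peak near +/- theta_b
  dens <- branch_angle_density(seq(-pi, pi, 0.001), np)
  peaks <- seq(-pi, pi, 0.001)[order(dens, decreasing = TRUE)[1:2]]
  expect_equal(sort(abs(peaks)), rep(35 * pi / 180, 2), tolerance = 0.01)
})

test_that("effective_rn is the nucleation count per time and area", {
  expect_equal(effective_rn(720, 1000, 1600), 4.5e-4)
  expect_equal(effective_rn(0, 1000, 1600), 0)
  expect_error(effective_rn(10, 0, 1600))
})

test_that("LDD resolution reproduces the dissociation probabilities", {
  dom <- dom_rect40()
  np <- nucleation_params("LDD", rescaled = FALSE)
  # empty domain: unbound with probability alpha_unbound = 0.02
  set.seed(41)
  kinds <- replicate(6000, ldd_resolve(dom, 1L, 20, 20, NULL, np)$kind)
  p_unb <- mean(kinds == "unbound")
  expect_equal(p_unb, 0.02, tolerance = 3 * sqrt(0.02 * 0.98 / 6000) / 0.02)
  expect_false(any(kinds == "bound"))

  # dense array around the appearance point: every trajectory hits at d ~ 0,
  # so bound with probability alpha_bound = 0.24 (16-gon ring of radius 0.05)
  ang16 <- seq(0, 2 * pi, length.out = 17)
  ring <- data.frame(mt_id = seq_len(16), face_id = 1L,
                     u1 = 20 + 0.05 * cos(ang16[-17]),
                     v1 = 20 + 0.05 * sin(ang16[-17]),
                     u2 = 20 + 0.05 * cos(ang16[-1]),
                     v2 = 20 + 0.05 * sin(ang16[-1]))
  set.seed(42)
  kinds2 <- replicate(4000, ldd_resolve(dom, 1L, 20, 20, ring, np)$kind)
  p_b <- mean(kinds2 == "bound")
  expect_equal(p_b, 0.24, tolerance = 3 * sqrt(0.24 * 0.76 / 4000) / 0.24)

  # exactly one hitting trajectory at d ~ 0 with N = 6:
  # bound 0.24/6 = 0.04, unbound 0.02 * (1 - 1/6), none the rest
  seg1 <- data.frame(mt_id = 1L, face_id = 1L,
                     u1 = 20.01, v1 = 19, u2 = 20.01, v2 = 21)
  set.seed(43)
  kinds3 <- replicate(12000, {
    ldd_resolve(dom, 1L, 20, 20, seg1, np, first_angle = 0)$kind
  })
  expect_equal(mean(kinds3 == "bound"), 0.04,
               tolerance = 3 * sqrt(0.04 * 0.96 / 12000) / 0.04)
  expect_equal(mean(kinds3 == "unbound"), 0.02 * 5 / 6,
               tolerance = 3 * sqrt(0.0167 * 0.9833 / 12000) / 0.0167)

  # bound outcomes lie on the parent and use its direction plus the
  # relative angle
  set.seed(44)
  repeat {
    out <- ldd_resolve(dom, 1L, 20, 20, seg1, np, first_angle = 0)
    if (out$kind == "bound") break
  }
  expect_equal(out$x, 20.01, tolerance = 1e-9)
  expect_equal(out$parent, 1L)
  exp_th <- ((pi / 2 + out$rel_angle + pi) %% (2 * pi)) - pi
  expect_equal(out$theta, exp_th, tolerance = 1e-9)
})

test_that("GDD bound nucleation lands on parents in proportion to length,
           uniformly along the parent", {
  # two long parallel parents (30 and 10 um), near-stationary daughters
  dom <- dom_rect40()
  im <- data.frame(face = 1L, x = c(5, 5), y = c(10, 30), theta = 0,
                   length = c(30, 10))
  cfg <- sim_config(dom,
                    dynamic_params(r_c = 0, r_r = 0, v_plus = 0.011,
                                   v_tm = 0.01),
                    nucleation_params("GDD", r_n = 0.02, rho_half = 1e-6),
                    T_end = 15, obs_interval = 15, seed = 88,
                    initial_mts = im)
  s <- run_simulation(cfg)
  nl <- s$nucleations
  # ids are assigned in creation order, so the parents are 1 and 2;
  # restricting to them removes the small daughter-length contamination
  # without biasing the 3:1 ratio
  nb <- nl[nl$kind == "bound" & nl$parent_id %in% c(1L, 2L), ]
  expect_gt(nrow(nb), 200)
  p1 <- mean(nb$parent_id == 1L)
  expect_equal(p1, 0.75, tolerance = 3 * sqrt(0.1875 / nrow(nb)) / 0.75)
  # position uniform along the longer parent
  u1 <- nb$u[nb$parent_id == 1L]
  expect_gt(stats::ks.test(u1, "punif", min(u1) - 1e-6, max(u1) + 1e-6)$p.value,
            0.01)
})

test_that("rescaled and unrescaled LDD parametrizations agree statistically", {
  dom <- dom_rect40()
  seg1 <- data.frame(mt_id = 1L, face_id = 1L,
                     u1 = 20.3, v1 = 10, u2 = 20.3, v2 = 30)
  rates <- sapply(c(FALSE, TRUE), function(resc) {
    np <- nucleation_params("LDD", rescaled = resc)
    appear_rate <- if (resc) np$alpha_bound * np$r_ins else np$r_ins
    set.seed(51)
    kinds <- replicate(8000, ldd_resolve(dom, 1L, 20, 20, seg1, np)$kind)
    c(bound = appear_rate * mean(kinds == "bound"),
      unbound = appear_rate * mean(kinds == "unbound"))
  })
  # per-area event rates (appearance rate x outcome probability) agree
  expect_equal(rates[, 1], rates[, 2], tolerance = 0.15)
})
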