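test_that("planar order parameter matches closed-form anchors", {
  # perfect order at 30 degrees
  st <- s2_theta2(rep(pi / 6, 5), rep(2, 5))
  expect_equal(st$S2, 1)
  expect_equal(st$Theta2, pi / 6)
  # two equal perpendicular segments cancel
  expect_equal(s2_theta2(c(0, pi / 2), c(1, 1))$S2, 0)
  # length weighting: 3 at 0 and 1 at 90 degrees
  st2 <- s2_theta2(c(0, pi / 2), c(3, 1))
  expect_equal(st2$S2, 0.5)
  expect_equal(st2$Theta2, 0)
  # zero total length is reported as missing
  expect_true(is.na(s2_theta2(numeric(0), numeric(0))$S2))
})

test_that("S2 is rotation invariant and vanishes for isotropic angles", {
  set.seed(11)
  th <- stats::runif(400, -pi, pi)
  len <- stats::runif(400, 0.5, 2)
  base <- s2_theta2(th, len)
  rot <- s2_theta2(th + 0.8, len)
  expect_equal(rot$S2, base$S2, tolerance = 1e-12)
  s2s <- replicate(40, s2_theta2(stats::runif(1e4, -pi, pi), rep(1, 1e4))$S2)
  expect_lt(stats::median(s2s), 0.05)
})

test_that("3D orientation metrics satisfy the anchor behaviours", {
  cyl <- dom_cyl()
  ring <- toy_transverse_ring(cyl)
  om <- order_metrics(ring, cyl)
  expect_equal(om$R2, 1, tolerance = 1e-6)
  expect_equal(om$Theta2_3d, 0, tolerance = 1e-6)
  expect_identical(om$class, "transverse")
  expect_equal(abs(om$orientation3d[1]), 1, tolerance = 1e-6)
  expect_equal(om$S2, 1, tolerance = 1e-9)  # mantle S2 of the ring

  lon <- toy_longitudinal_lines(cyl, 6)
  oml <- order_metrics(lon, cyl)
  expect_equal(oml$Theta2_3d, 90, tolerance = 1e-6)
  expect_identical(oml$class, "longitudinal")

  # isotropic planar array: R2 near zero
  rect <- dom_rect40()
  set.seed(21)
  iso <- toy_uniform_isotropic(rect, 5000, len = 1)
  omi <- order_metrics(iso, rect)
  expect_lt(omi$R2, 0.05)

  # perfectly aligned planar array: R2 = 1
  ali <- toy_longitudinal_lines(rect, 5)
  expect_equal(order_metrics(ali, rect)$R2, 1, tolerance = 1e-9)
})

test_that("orientation classification uses the 10/80 degree thresholds", {
  expect_identical(classify_orientation(5), "transverse")
  expect_identical(classify_orientation(85), "longitudinal")
  expect_identical(classify_orientation(45), "other")
  expect_error(classify_orientation(120))
})

test_that("axial density profile is conservative and localized", {
  cyl <- dom_cyl()
  ring <- toy_transverse_ring(cyl, u0 = 10.5)
  pr <- density_profile(ring, cyl)
  expect_equal(pr$density[pr$bin_center == 10.5], 1)
  expect_equal(sum(pr$density[pr$bin_center != 10.5]), 0)
  # conservation on a random array (mantle part)
  set.seed(4)
  segs <- toy_uniform_isotropic(cyl, 300, len = 3)
  pr2 <- density_profile(segs, cyl)
  mantle_len <- with(segs[segs$face_id == 1, ],
                     sum(sqrt((u2 - u1)^2 + (v2 - v1)^2)))
  expect_equal(sum(pr2$density * pr2$bin_area), mantle_len, tolerance = 1e-9)
  # empty array
  empty <- ring[0, ]
  expect_true(all(density_profile(empty, cyl)$density == 0))
})

test_that("control parameter G matches direct evaluation and the printed
           relative changes under rescue-rate increases", {
  expect_equal(control_G(dynamic_params(r_c = 0.002), 0.001),
               -0.137611, tolerance = 1e-5)
  g0 <- control_G(dynamic_params(r_c = 0.00225), 0.001)
  expect_equal(g0, -0.159727, tolerance = 1e-5)
  g8 <- control_G(dynamic_params(r_c = 0.00225, r_r = 0.001 * 1.08), 0.001)
  g24 <- control_G(dynamic_params(r_c = 0.00225, r_r = 0.001 * 1.24), 0.001)
  expect_equal(round(100 * (abs(g0) - abs(g8)) / abs(g0)), 2)
  expect_equal(round(100 * (abs(g0) - abs(g24)) / abs(g0)), 6)
  expect_warning(control_G(dynamic_params(r_c = 1e-5, r_r = 0.01), 0.001),
                 "unbounded")
  # rc_for_G inverts control_G
  dyn <- dynamic_params(r_c = 1)
  rc <- rc_for_G(-0.25, 0.001, dyn)
  expect_equal(control_G(dynamic_params(r_c = rc), 0.001), -0.25,
               tolerance = 1e-10)
})

test_that("octant projection and C2 coordinate match the stated examples", {
  expect_equal(octant_project(c(1, 0, 0)), c(X = 0, Y = 1))
  expect_equal(octant_project(c(0, 1, 0)),
               c(X = -1 / (2 * sqrt(2)), Y = -0.5))
  bd <- rep(1 / sqrt(3), 3)
  expect_equal(octant_project(bd)[["Y"]], 0, tolerance = 1e-12)
  expect_equal(c2_coordinate(c(1, 0, 0)), 1)
  expect_equal(c2_coordinate(c(0, 1, 0)), -0.5)
  expect_equal(c2_coordinate(bd), 1 / sqrt(3) - 0.5 * sqrt(2 / 3))
  # reflections leave the projection unchanged; corners are distinct
  set.seed(2)
  for (k in 1:20) {
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
    expect_equal(octant_project(v), octant_project(-abs(v)))
  }
  corners <- rbind(octant_project(c(1, 0, 0)), octant_project(c(0, 1, 0)),
                   octant_project(c(0, 0, 1)))
  expect_equal(nrow(unique(corners)), 3)
})

test_that("r2_max gives the perfect-array ceilings used for renormalization", {
  cyl <- dom_cyl()
  expect_equal(r2_max(cyl, "transverse"), 1, tolerance = 1e-9)
  expect_gt(r2_max(cyl, "longitudinal"), 0)
  box <- dom_box17()
  expect_equal(r2_max(box, "transverse"), 1, tolerance = 1e-9)
})
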