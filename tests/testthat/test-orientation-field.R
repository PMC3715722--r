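test_that("concentric and radial implied orientations match the tangent-vector oracle", {
  conc <- concentric_field()
  rad <- orientation_field("radial")

  # anchor cases: tangential orientation at the test location, and on the
  # horizontal meridian where the tangent is vertical
  expect_equal(implied_orientation(conc, TEST_POINT), 15, tolerance = 1e-9)
  expect_equal(implied_orientation(conc, c(10, 0)), 0, tolerance = 1e-12)

  pts <- withr::with_seed(101, {
    r <- runif(1000, 0.5, 30)
    a <- runif(1000, 0, 2 * pi)
    cbind(r * cos(a), r * sin(a))
  })
  # oracle: tangent is perpendicular to the radius; radial is along it
  tang <- axis_angle_of(-pts[, 2], pts[, 1])
  radial <- axis_angle_of(pts[, 1], pts[, 2])
  expect_equal(implied_orientation(conc, pts), tang, tolerance = 1e-9)
  expect_equal(implied_orientation(rad, pts), radial, tolerance = 1e-9)

  expect_error(implied_orientation(conc, c(0, 0)), "degenerate")
  expect_error(local_gradient(rad, c(0, 0)), "degenerate")
})

test_that("linear gradients evaluate and wrap correctly", {
  lin <- linear_field(5)
  expect_equal(implied_orientation(lin, c(12.66, 2.59)), 30)  # 15 + 5 * 3
  # evaluating at the anchor returns the anchor orientation exactly
  expect_equal(implied_orientation(lin, c(9.66, 2.59)), 15, tolerance = 1e-12)
  # 180-degree wrap: 15 + 5 * 18 = 105 -> -75
  expect_equal(implied_orientation(lin, c(9.66 + 18, 0)), -75)
  # vertical-axis variant uses the y coordinate
  linv <- linear_field(5, axis = "vertical")
  expect_equal(implied_orientation(linv, c(0, 2.59 + 2)), 25)

  expect_equal(local_gradient(lin, c(-3, 17)), 5)
  expect_equal(local_gradient(orientation_field("iso"), c(1, 1)), 0)
})

test_that("concentric gradient follows 180/(pi r) along the iso-eccentric arc", {
  conc <- concentric_field()
  for (r in c(1, 5, 10, 20)) {
    expect_equal(local_gradient(conc, c(r, 0)), 180 / (pi * r),
                 tolerance = 1e-9)
  }
  # numerical differentiation oracle along the arc at 10 deg eccentricity
  eps <- 1e-5
  p1 <- 10 * c(cos(pi / 12), sin(pi / 12))
  p2 <- 10 * c(cos(pi / 12 + eps / 10), sin(pi / 12 + eps / 10))
  num <- abs(orientation_difference(implied_orientation(conc, p1),
                                    implied_orientation(conc, p2))) / eps
  expect_equal(local_gradient(conc, p1), num, tolerance = 1e-4)
})

test_that("quantization produces anchor-centred bands with space-averaged values", {
  lin <- linear_field(5)
  q8 <- quantize_field(lin, 8)
  # band centred on the anchor keeps the anchor orientation
  expect_equal(implied_orientation(q8, TEST_POINT), 15, tolerance = 1e-9)
  # constant within a band (anchor band spans +-4 deg around the anchor)
  expect_equal(implied_orientation(q8, TEST_POINT + c(3.9, 0)), 15,
               tolerance = 1e-9)
  # adjacent bands differ by band_width * rate = 40 deg
  step <- orientation_difference(
    implied_orientation(q8, TEST_POINT),
    implied_orientation(q8, TEST_POINT + c(8, 0)))
  expect_equal(abs(step), 40)

  # width 12 at rate 5: three distinct orientations per 36-deg cycle,
  # mutually separated by 60 deg
  q12 <- quantize_field(lin, 12)
  th <- implied_orientation(q12, cbind(TEST_POINT[1] + 12 * (0:2),
                                       TEST_POINT[2]))
  expect_length(unique(round(th, 9)), 3L)
  seps <- abs(orientation_difference(th[c(1, 2, 1)], th[c(2, 3, 3)]))
  expect_equal(seps, c(60, 60, 60))

  # width = spatial period (180 / rate = 36): iso-oriented texture
  q36 <- quantize_field(lin, orientation_period(5))
  xs <- cbind(TEST_POINT[1] + 36 * (-2:2), TEST_POINT[2])
  expect_equal(implied_orientation(q36, xs), rep(15, 5), tolerance = 1e-9)

  expect_error(quantize_field(concentric_field(), 8), "linear_gradient")
  expect_error(quantize_field(lin, 0), "band_width")
})

test_that("orientation modulation period is 180/rate for any positive rate", {
  for (rate in c(0.5, 2, 5, 9.7)) {
    p <- orientation_period(rate)
    lin <- linear_field(rate)
    x0 <- TEST_POINT[1]
    th0 <- implied_orientation(lin, c(x0, 0))
    th1 <- implied_orientation(lin, c(x0 + p, 0))
    expect_equal(orientation_difference(th0, th1), 0, tolerance = 1e-9)
    # steps per period times step size covers a full half-turn
    expect_equal(p * rate, 180)
  }
})

test_that("reflectional symmetry mirrors the non-anchor hemifield", {
  lin <- linear_field(3)
  sym <- apply_symmetry(lin, "horizontal")
  # source (anchor-side, y > 0) values unchanged
  pts_src <- cbind(c(0, 5, -8), c(5, 1, 12))
  expect_equal(implied_orientation(sym, pts_src),
               implied_orientation(lin, pts_src))
  # mirror rule: theta(x, -y) = -theta(x, y)
  expect_equal(implied_orientation(sym, c(14.66, -5)),
               -implied_orientation(lin, c(14.66, 5)))
  # implied orientation at the test location (the anchor) is unaffected
  expect_equal(implied_orientation(sym, c(9.66, 2.59)), 15, tolerance = 1e-12)

  # boundary wrap: a mirrored +90 collapses onto the canonical -90
  lin2 <- linear_field(5)
  x90 <- 9.66 + 15  # 15 + 75 = 90 -> wraps to -90
  expect_equal(implied_orientation(apply_symmetry(lin2, "horizontal"),
                                   c(x90, -2)), -90)

  # vertical-axis gradients mirror about the vertical meridian
  linv <- linear_field(3, axis = "vertical")
  symv <- apply_symmetry(linv, "vertical")
  expect_equal(implied_orientation(symv, c(-4, 6)),
               -implied_orientation(linv, c(4, 6)))

  expect_error(apply_symmetry(linv, "horizontal"), "must match")
  expect_error(apply_symmetry(concentric_field(), "horizontal"), "linear")
})

test_that("orientation wrapping identifies -90 with +90 and stays in range", {
  th <- wrap_orientation(c(-90, 90, 0, 89.999, -90.001, 275))
  expect_true(all(th >= -90 & th < 90))
  expect_equal(wrap_orientation(90), -90)
  expect_equal(wrap_orientation(-90), -90)
  expect_equal(orientation_difference(-89, 89), -2)
})
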