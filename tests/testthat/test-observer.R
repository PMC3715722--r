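test_that("gradient tuning is a continuous raised cosine with unit peak at the center", {
  g <- seq(-2, 12, by = 0.01)
  w <- gradient_tuning(g)
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(gradient_tuning(5), 1)
  expect_equal(gradient_tuning(0), 0)
  expect_equal(gradient_tuning(10), 0)
  expect_true(all(w[g < 0 | g > 10] == 0))
  # continuity at the support edges
  expect_lt(abs(gradient_tuning(1e-6) - gradient_tuning(-1e-6)), 1e-5)
  expect_lt(max(abs(diff(w))), 0.01)
})

test_that("effective gradient reads smooth fields locally and banded fields by step", {
  expect_equal(effective_gradient(linear_field(5), TEST_POINT), 5)
  expect_equal(effective_gradient(concentric_field(), TEST_POINT),
               180 / (10 * pi), tolerance = 1e-9)
  lin <- linear_field(5)
  # steps of 1, 10, 20, 40 deg are readable and recover the underlying rate
  for (w in c(0.2, 2, 4, 8)) {
    expect_equal(effective_gradient(quantize_field(lin, w), TEST_POINT), 5)
  }
  # 60- and 120-deg steps exceed the 45-deg ambiguity threshold
  expect_equal(effective_gradient(quantize_field(lin, 12), TEST_POINT), 0)
  expect_equal(effective_gradient(quantize_field(lin, 24), TEST_POINT), 0)
  # a full-period band (step wraps to 0) is an iso texture: no gradient
  expect_equal(effective_gradient(quantize_field(lin, 36), TEST_POINT), 0)
})

test_that("predicted TAE reproduces the calibration anchors", {
  obs <- observer_params()
  # concentric structure at full coherence: approximately 2 degrees
  st <- adaptation_state(concentric_field(), layout_geometry(coherence = 1),
                         obs)
  g_at_test <- local_gradient(concentric_field(), c(9.66, 2.59))
  expect_equal(st$predicted_tae, 2 * gradient_tuning(g_at_test),
               tolerance = 1e-9)
  expect_gt(st$predicted_tae, 1.8)
  expect_lt(st$predicted_tae, 2.0)
  # the printed test location is the polar point (pi/12, 10 deg) to 2 dp
  expect_equal(st$implied_orientation_at_test, 15, tolerance = 0.01)

  # zero coherence: no effect
  st0 <- adaptation_state(concentric_field(), layout_geometry(coherence = 0),
                          obs)
  expect_equal(st0$predicted_tae, 0)

  # no orientation change, or a gradient at the tuning edge: no effect
  lay <- proximal_layout()
  expect_equal(adaptation_state(linear_field(0), lay, obs)$predicted_tae, 0)
  expect_equal(adaptation_state(linear_field(10), lay, obs)$predicted_tae, 0)
})

test_that("predicted TAE scales with coherence and orders the layouts", {
  obs <- observer_params()
  conc <- concentric_field()
  for (expo in c(0.5, 1, 2)) {
    obs_e <- observer_params(coherence_exponent = expo)
    taes <- vapply(seq(0, 1, by = 0.1), function(coh) {
      adaptation_state(conc, layout_geometry(coherence = coh),
                       obs_e)$predicted_tae
    }, numeric(1))
    expect_true(all(diff(taes) >= -1e-12))
  }
  # proximal == intermixed at equal coherence; distal adds a local term
  coh <- 0.75
  prox <- layout_geometry(noise_layout = "proximal")
  prox$annulus_outer_radius <- solve_noise_radius(prox, coh)
  dist <- layout_geometry(noise_layout = "distal")
  dist$annulus_outer_radius <- solve_noise_radius(dist, coh)
  t_int <- adaptation_state(conc, layout_geometry(coherence = coh),
                            obs)$predicted_tae
  t_prox <- adaptation_state(conc, prox, obs)$predicted_tae
  t_dist <- adaptation_state(conc, dist, obs)$predicted_tae
  expect_equal(t_prox, t_int, tolerance = 1e-6)
  expect_gt(t_dist, t_prox)

  # symmetry has no effect on the prediction
  lin <- linear_field(5)
  expect_equal(adaptation_state(apply_symmetry(lin, "horizontal"), prox,
                                obs)$predicted_tae,
               adaptation_state(lin, prox, obs)$predicted_tae)
})

test_that("predicted TAE over a rate grid peaks at the tuning center", {
  obs <- observer_params()
  lay <- proximal_layout()
  rates <- seq(0, 10, by = 1.25)
  taes <- vapply(rates, function(r) {
    adaptation_state(linear_field(r), lay, obs)$predicted_tae
  }, numeric(1))
  expect_equal(rates[which.max(taes)], 5)
})

test_that("the decision stage has the stated psychometric shape", {
  p_cw <- function(obs, pse, th) remoteTAE:::p_clockwise(obs, pse, th)
  obs0 <- lapse_free_observer()
  expect_equal(p_cw(obs0, 1.5, 1.5), 0.5)
  obs <- observer_params(lapse_rate = 0.04)
  # strongly clockwise (negative) tests are called CW up to lapses
  expect_equal(p_cw(obs, 0, -1e4), 1 - 0.04 / 2, tolerance = 1e-9)
  expect_equal(p_cw(obs, 0, 1e4), 0.04 / 2, tolerance = 1e-9)
  # reproducible draws
  r1 <- withr::with_seed(5, replicate(20, simulate_trial(obs, 0, 1)))
  r2 <- withr::with_seed(5, replicate(20, simulate_trial(obs, 0, 1)))
  expect_identical(r1, r2)
  expect_true(all(r1 %in% c("CW", "CCW")))
})

test_that("simulated blocks have the constant-stimuli design and are seed-stable", {
  obs <- observer_params()
  blk <- simulate_block(obs, "cond", true_pse = 2, seed = 21)
  expect_equal(nrow(blk), 70L)
  expect_equal(as.vector(table(blk$test_orientation_deg)), rep(10L, 7))
  expect_setequal(unique(blk$test_orientation_deg), seq(-3, 3, by = 1))
  expect_identical(blk, simulate_block(obs, "cond", true_pse = 2, seed = 21))
  expect_false(identical(blk$response,
                         simulate_block(obs, "cond", 2, seed = 22)$response))

  # baseline blocks are symmetric about 0 in expectation
  obs0 <- lapse_free_observer()
  many <- do.call(rbind, lapply(1:60, function(s) {
    simulate_block(obs0, "base", 0, seed = 300 + s)
  }))
  agg <- aggregate((many$response == "CCW") ~ many$test_orientation_deg, FUN = mean)
  p <- agg[[2]]
  expect_equal(p, rev(1 - p), tolerance = 0.05)
})
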