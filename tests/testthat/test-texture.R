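test_that("element sampling respects counts, bounds and the layout label rules", {
  lay <- layout_geometry(coherence = 1)
  sp <- texture_spec(concentric_field(), lay, seed = 3)
  el <- sample_elements(sp)
  expect_equal(nrow(el), 5000L)
  expect_true(all(abs(el$x_deg) <= 24 & abs(el$y_deg) <= 24))
  expect_true(all(el$orientation_deg >= -90 & el$orientation_deg < 90))
  expect_true(all(el$phase_rad >= 0 & el$phase_rad < 2 * pi))
  # full coherence, intermixed: no noise labels, orientations follow the field
  expect_true(all(el$label == "signal"))
  expect_equal(el$orientation_deg,
               implied_orientation(concentric_field(),
                                   cbind(el$x_deg, el$y_deg)),
               tolerance = 1e-9)

  # proximal rule is spatial: noise exactly inside the annulus
  spp <- texture_spec(concentric_field(), proximal_layout(), seed = 4,
                      n_elements = 2000)
  elp <- sample_elements(spp)
  d <- sqrt((elp$x_deg - 9.66)^2 + (elp$y_deg - 2.59)^2)
  in_ann <- d >= 4.6 & d <= 9.53
  expect_equal(elp$label, ifelse(in_ann, "noise", "signal"))
})

test_that("element sampling is deterministic in the seed", {
  sp <- texture_spec(concentric_field(), layout_geometry(coherence = 0.5),
                     seed = 10)
  expect_identical(sample_elements(sp), sample_elements(sp))
  other <- sample_elements(sp, seed = 11)
  expect_false(identical(sample_elements(sp)$phase_rad, other$phase_rad))
})

test_that("visible signal fraction in proximal layouts matches the geometric expectation", {
  lay <- proximal_layout()
  target <- coherence_for_radius(lay, 9.53)
  sp <- texture_spec(concentric_field(), lay)
  fracs <- vapply(1:20, function(s) {
    el <- sample_elements(sp, seed = 100 + s)
    d <- sqrt((el$x_deg - 9.66)^2 + (el$y_deg - 2.59)^2)
    vis <- d > 4.6
    sum(vis & el$label == "signal") / sum(vis)
  }, numeric(1))
  expect_true(all(abs(fracs - target) < 0.02))
  expect_lt(abs(mean(fracs) - target), 0.005)
})

test_that("rendered textures are normalised then occluded as specified", {
  sp <- texture_spec(concentric_field(), proximal_layout(), seed = 5)
  el <- sample_elements(sp)
  pre <- render_texture(el, sp, occlude = FALSE)
  expect_lt(abs(mean(pre$contrast)), 1e-6)
  expect_equal(sqrt(mean(pre$contrast^2)), 0.09, tolerance = 0.001)

  post <- render_texture(el, sp)
  n <- nrow(post$contrast)
  xc <- -24 + (seq_len(n) - 0.5) * post$deg_per_px
  yc <- 24 - (seq_len(n) - 0.5) * post$deg_per_px
  r <- sqrt(outer((yc - 2.59)^2, (xc - 9.66)^2, "+"))
  expect_true(all(post$contrast[r <= 3.0] == 0))
  # beyond the ramp the mask is unity
  far <- r >= 4.6
  expect_equal(post$contrast[far], pre$contrast[far], tolerance = 1e-12)

  # rendering resolution robustness: RMS stable from 15 to 5 px/deg
  sp5 <- texture_spec(concentric_field(), proximal_layout(), seed = 5,
                      pixels_per_degree = 5)
  pre5 <- render_texture(el, sp5, occlude = FALSE)
  expect_lt(abs(sqrt(mean(pre5$contrast^2)) / sqrt(mean(pre$contrast^2)) - 1),
            0.05)

  expect_error(render_texture(el[0, ], sp), "empty")
})

test_that("occlusion window is a monotone quarter-cycle cosine ramp", {
  r <- seq(2, 6, by = 0.01)
  m <- occlusion_profile(r)
  expect_true(all(m[r <= 3] == 0))
  expect_true(all(m[r >= 4.6] == 1))
  expect_true(all(diff(m) >= -1e-12))
  expect_equal(occlusion_profile(3.8), sin(pi / 2 * 0.5)^2)
})

test_that("test patches have the stated peak contrast, support and symmetry", {
  tst <- render_test(0)
  expect_equal(max(abs(tst$contrast)), 0.25)
  # exact left-right mirror symmetry for a vertical cosine-phase patch
  expect_equal(tst$contrast, tst$contrast[, rev(seq_len(ncol(tst$contrast)))])
  # zero outside the 0.665-deg envelope radius
  m <- (ncol(tst$contrast) - 1) / 2
  off <- (-m:m) / 15
  r <- sqrt(outer(off^2, off^2, "+"))
  expect_true(all(tst$contrast[r >= 0.665] == 0))

  # 8-bit export preserves the peak to within one grey level
  path <- tempfile(fileext = ".png")
  write_stimulus_png(tst, path)
  b <- png::readPNG(path)
  expect_lt(abs(max(abs(b * 2 - 1)) - 0.25), 1 / 255 + 1e-9)
  expect_error(render_test(95), "abs")
})

test_that("adaptor sequences have the right frame counts and distinct frames", {
  sp <- texture_spec(concentric_field(), layout_geometry(coherence = 1),
                     n_elements = 50, seed = 9)
  expect_length(make_adaptor_sequence(sp, 30, 0.1), 300L)
  frames <- make_adaptor_sequence(sp, 3, 0.1)
  expect_length(frames, 30L)
  phases <- vapply(frames, function(f) f$phase_rad[1], numeric(1))
  expect_equal(anyDuplicated(phases), 0L)
  # deterministic in the master seed
  expect_identical(frames, make_adaptor_sequence(sp, 3, 0.1))
})

test_that("element lists and configurations round-trip through text formats", {
  sp <- texture_spec(quantize_field(linear_field(5), 8), proximal_layout(),
                     n_elements = 40, seed = 2)
  el <- sample_elements(sp)
  p <- tempfile(fileext = ".csv")
  write_elements_csv(el, p)
  expect_equal(as.data.frame(read_elements_csv(p)), as.data.frame(el),
               tolerance = 1e-12)

  for (ext in c(".json", ".yaml")) {
    pf <- tempfile(fileext = ext)
    write_config(sp$field, pf)
    f2 <- read_config(pf)
    expect_equal(f2, sp$field, tolerance = 1e-9)
    pl <- tempfile(fileext = ext)
    write_config(sp$layout, pl)
    expect_equal(read_config(pl), sp$layout, tolerance = 1e-9)
    po <- tempfile(fileext = ext)
    write_config(observer_params(lapse_rate = 0.05), po)
    expect_equal(read_config(po), observer_params(lapse_rate = 0.05),
                 tolerance = 1e-9)
    ps <- tempfile(fileext = ext)
    write_config(sp, ps)
    expect_equal(read_config(ps), sp, tolerance = 1e-9)
  }
})
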