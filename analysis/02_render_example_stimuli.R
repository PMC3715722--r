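#!/usr/bin/env Rscript
# Visual QC: render one example frame of each adaptor family and a test
# patch, and confirm the normalisation invariants on the rendered images.
# Writes PNGs and an element CSV under results/figures/.

suppressMessages(library(remoteTAE))

out <- "results/figures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

render_one <- function(field, layout, name, seed) {
  sp <- texture_spec(field, layout, seed = seed)
  el <- sample_elements(sp)
  img <- render_texture(el, sp)
  pre <- render_texture(el, sp, occlude = FALSE)
  write_stimulus_png(img, file.path(out, paste0(name, ".png")))
  cat(sprintf("%-22s mean %+8.1e  RMS %.4f  (pre-occlusion)\n",
              name, mean(pre$contrast), sqrt(mean(pre$contrast^2))))
  invisible(el)
}

conc <- orientation_field("concentric")
prox <- layout_geometry(noise_layout = "proximal", annulus_outer_radius = 9.53)

# intermixed noisy concentric texture at 50% coherence
el <- render_one(conc, layout_geometry(coherence = 0.5),
                 "adaptor_intermixed_c050", seed = 101)
write_elements_csv(el, file.path(out, "adaptor_intermixed_c050_elements.csv"))

# fully coherent concentric structure behind the 90% proximal annulus
render_one(conc, prox, "adaptor_proximal_r9.53", seed = 102)

# linear gradient at the tuning peak, and its 8-deg and 12-deg quantizations
lin5 <- orientation_field("linear_gradient", gradient_rate = 5,
                          axis = "horizontal")
render_one(lin5, prox, "adaptor_linear_rate5", seed = 103)
render_one(quantize_field(lin5, 8), prox, "adaptor_quantized_w8", seed = 104)
render_one(quantize_field(lin5, 12), prox, "adaptor_quantized_w12", seed = 105)

# the near-vertical test patch at the occluded location
tst <- render_test(2)
write_stimulus_png(tst, file.path(out, "test_patch_plus2deg.png"))
cat("test patch peak contrast:", max(abs(tst$contrast)), "\n")
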