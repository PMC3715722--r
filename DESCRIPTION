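Package: remoteTAE
Title: Simulated Remote Tilt Aftereffects from Orientation-Gradient Textures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulation and analysis of spatially remote tilt
    aftereffects (TAEs) induced by adaptation to dense oriented-element
    textures. Provides analytic orientation fields (concentric, radial,
    linear and quantized orientation gradients, with optional reflectional
    symmetry), the signal/noise coherence geometry of annular noise layouts,
    Gabor-element texture rendering with RMS-contrast normalisation and
    cosine-ramped occlusion, a phenomenological simulated observer that
    converts adaptor structure into gradient-tuned, coherence-scaled PSE
    shifts and emits stochastic two-alternative forced-choice responses,
    maximum-likelihood logistic psychometric fitting with bootstrap standard
    errors, and an experiment pipeline reproducing the coherence, gradient
    and quantization manipulations end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
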