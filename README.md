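# remoteTAE

Desk-scale simulation and analysis of **spatially remote tilt
aftereffects** (TAEs): repulsive shifts in perceived orientation measured
at a visual-field location where the adapting pattern was occluded, driven
by the orientation the adaptor's *global structure implies* there rather
than by any physically present contour.

The package is written for visual psychophysicists and computational
modellers who want a fully verifiable version of this paradigm: every stage
— stimulus geometry, texture synthesis, trial generation, psychometric
fitting — is executable, deterministic under a seed, and tested, with a
simulated observer standing in for human participants.

## What it computes

* **Orientation fields.** Implied orientation as a function of position for
  concentric, radial, linear-gradient, quantized-gradient and iso
  structures. Coordinates are degrees of visual angle from fixation;
  orientation is degrees CCW from vertical in [−90, 90), mod 180. A
  concentric field's gradient along the iso-eccentric arc is
  180/(πr) °/° — 5.73 °/° at the 10° test eccentricity. Quantizing a
  rate-g linear gradient into width-w bands (each carrying the
  space-average of the gradient) steps adjacent bands by w·g mod 180, with
  an iso-oriented texture at the 180/g spatial period.
* **Coherence geometry.** For textures whose randomly oriented noise
  elements fill an annulus around the occluded test site, the expected
  fraction of visible elements carrying the structure ("coherence") follows
  from clipped-disc areas under uniform element density;
  `coherence_for_radius()` evaluates it by deterministic area integration
  and `solve_noise_radius()` inverts it. A 9.53° proximal annulus yields
  90% coherence.
* **Texture synthesis.** 5000 Hanning-windowed sinusoidal elements (1 c/°,
  1.33° diameter) on a 48 × 48° square, normalised to zero mean and 9% RMS
  contrast, then occluded within 3° of the test location with a
  quarter-cycle cosine ramp over 1.6°; 2 c/°, 0.25-peak-contrast test
  patches; 100-ms dynamic adaptor sequences; PNG/CSV/YAML/JSON export.
* **A simulated observer.** Predicted TAE = A · c^γ · G(g) (+ a local term
  for distal layouts), with a raised-cosine gradient tuning G peaking at
  5 °/°, linear coherence scaling, and a 45° inter-band-step ambiguity
  threshold that abolishes the effect for coarse quantization; 2AFC
  clockwise/counter-clockwise responses from a lapse-contaminated logistic
  decision stage.
* **Psychometric analysis.** Maximum-likelihood logistic fits of
  constant-stimuli data (7 levels × 10 reps per block), PSE and slope,
  within-level bootstrap standard errors, and TAE = sign(implied) ×
  (PSE_adapt − PSE_baseline).
* **Experiment pipelines.** `build_grid()` / `run_pipeline()` /
  `summarize_results()` reproduce the three experiment designs end to end
  (coherence × noise placement; gradient tuning × symmetry; gradient
  quantization). The numbered drivers under `analysis/` run them and write
  tables and figures to `results/`.

## Worked example

Predict and then recover the collapse of the remote TAE under coarse
quantization of a 5 °/° orientation gradient:

```r
library(remoteTAE)

# the canonical concentric adaptor at full coherence
st <- adaptation_state(orientation_field("concentric"),
                       layout_geometry(coherence = 1), observer_params())
st
#> <adaptation_state>
#>   implied orientation at test: 15.009 deg
#>   effective gradient: 5.729 deg/deg; coherence: 1 ; intermixed
#>   predicted TAE: 1.897 deg

# quantized-gradient conditions: 4- and 8-deg bands survive (steps of 20
# and 40 deg), 12-deg bands (60-deg steps) abolish the effect
grid <- build_grid("exp3", band_widths = c(4, 8, 12), blocks = 4, seed = 7)
res <- run_pipeline(grid, observer_params(), n_boot = 500)
res[, c("condition_id", "band_width", "predicted_tae", "pse", "boot_se", "tae")]
#>   condition_id band_width predicted_tae    pse boot_se    tae
#> 1    band_04.0          4           1.8  1.679   0.250  1.783
#> 2    band_08.0          8           1.8  1.589   0.251  1.693
#> 3    band_12.0         12           0.0 -0.296   0.207 -0.192
#> 4     baseline         NA           0.0 -0.104   0.259  0.000

summarize_results(res)$largest_significant_band_width
#> [1] 8
```

The `tae` column is the fitted PSE shift relative to the baseline
condition, signed so that repulsion away from the +15° implied orientation
is positive; `boot_se` is the bootstrap standard error of the PSE, and the
predicted column is the observer model's analytic expectation. At 4° and 8°
bands the recovered TAE sits near the ~1.8° prediction and exceeds twice
its SE; at 12° bands the inter-band orientation step (60°) is ambiguous and
the effect vanishes.

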