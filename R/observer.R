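#' Parameters of the simulated observer
#'
#' A phenomenological response model calibrated to three anchors: remote
#' TAEs of about 2 degrees at full coherence, a tuned dependence on the
#' adaptor's orientation gradient peaking near 5 degrees of rotation per
#' degree of visual angle (vanishing at 0 and near 10), and abolition of the
#' effect when a quantized gradient's inter-band orientation step becomes
#' ambiguous. The functional forms (raised-cosine gradient tuning, linear
#' coherence scaling, hard step-ambiguity threshold) are modelling choices —
#' stand-ins constrained only by those qualitative anchors, not measured
#' curves.
#'
#' @param tae_peak_amplitude Peak TAE at full coherence and optimal
#'   gradient, degrees (default 2).
#' @param tuning_center Gradient at which the TAE peaks, degrees orientation
#'   per degree visual angle (default 5).
#' @param tuning_halfwidth Half-support of the raised-cosine tuning curve
#'   (default 5, so support `[0, 10]`).
#' @param coherence_exponent Exponent of the coherence scaling (default 1,
#'   linear).
#' @param step_ambiguity_threshold Largest readable inter-band orientation
#'   step for quantized gradients, degrees (default 45, half the 90-degree
#'   orientation-ambiguity limit).
#' @param local_adaptation_gain Additive local-adaptation term for distal
#'   layouts (signal elements adjacent to the test site), degrees per unit
#'   coherence (default 0.5).
#' @param psychometric_slope Logistic slope of the decision stage, degrees
#'   (default 1.5).
#' @param lapse_rate Stimulus-independent response probability (default
#'   0.02; in `[0, 0.1]`).
#' @param seed Default seed for response simulation.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(tae_peak_amplitude = 2.0,
                            tuning_center = 5.0,
                            tuning_halfwidth = 5.0,
                            coherence_exponent = 1.0,
                            step_ambiguity_threshold = 45,
                            local_adaptation_gain = 0.5,
                            psychometric_slope = 1.5,
                            lapse_rate = 0.02,
                            seed = 1L) {
  stopifnot(tae_peak_amplitude >= 0, tuning_center >= 0, tuning_halfwidth > 0,
            coherence_exponent >= 0, step_ambiguity_threshold > 0,
            local_adaptation_gain >= 0, psychometric_slope > 0,
            lapse_rate >= 0, lapse_rate <= 0.1)
  structure(
    list(tae_peak_amplitude = tae_peak_amplitude,
         tuning_center = tuning_center,
         tuning_halfwidth = tuning_halfwidth,
         coherence_exponent = coherence_exponent,
         step_ambiguity_threshold = step_ambiguity_threshold,
         local_adaptation_gain = local_adaptation_gain,
         psychometric_slope = psychometric_slope,
         lapse_rate = lapse_rate,
         seed = as.integer(seed)),
    class = "observer_params")
}

#' Raised-cosine gradient tuning curve
#'
#' `G(g) = 0.5 * (1 + cos(pi * (g - center) / halfwidth))` on
#' `[center - halfwidth, center + halfwidth]`, zero outside. Continuous,
#' unit peak at `center`, vanishing at `center +/- halfwidth` (0 and 10
#' degrees per degree under defaults).
#'
#' @param g Gradient magnitude(s), degrees orientation per degree visual
#'   angle.
#' @param center,halfwidth Tuning parameters.
#' @return Tuning weight(s) in `[0, 1]`.
#' @export
gradient_tuning <- function(g, center = 5, halfwidth = 5) {
  w <- 0.5 * (1 + cos(pi * (g - center) / halfwidth))
  w[abs(g - center) >= halfwidth] <- 0
  w
}

#' Gradient of the adaptor as read by the observer
#'
#' For smooth fields this is the local spatial gradient at the point. For
#' quantized fields the observer reads the inter-band orientation step
#' `S = band_width * gradient_rate`, wrapped to `(-90, 90]` because
#' orientation is 180-degree periodic: if `|S|` does not exceed the
#' ambiguity threshold the perceived rate is `|S| / band_width` (which
#' equals the underlying rate whenever no wrap occurs, and 0 for an
#' iso-oriented texture whose step wraps to 0); larger steps make the
#' structure unreadable and yield 0.
#'
#' @param field An [orientation_field()].
#' @param point Evaluation point (the test location).
#' @param step_ambiguity_threshold Largest readable step, degrees.
#' @return Effective gradient, degrees orientation per degree visual angle.
#' @export
#' @examples
#' lin <- orientation_field("linear_gradient", gradient_rate = 5)
#' effective_gradient(quantize_field(lin, 8), c(9.66, 2.59))   # 5
#' effective_gradient(quantize_field(lin, 12), c(9.66, 2.59))  # 0
effective_gradient <- function(field, point,
                               step_ambiguity_threshold = 45) {
  stopifnot(inherits(field, "orientation_field"))
  if (field$kind == "quantized_gradient") {
    step <- (field$band_width * field$gradient_rate) %% 180
    if (step > 90) step <- step - 180
    if (abs(step) <= step_ambiguity_threshold) {
      abs(step) / field$band_width
    } else {
      0
    }
  } else {
    local_gradient(field, point)
  }
}

#' Adaptation state and predicted TAE for one condition
#'
#' Combines the implied orientation at the test location, the effective
#' orientation gradient, and the structure coherence of the layout into the
#' predicted tilt aftereffect:
#' `TAE = peak * coherence^exponent * G(gradient) + local term`, where `G`
#' is the raised-cosine [gradient_tuning()] and the local term
#' (`local_adaptation_gain * coherence`) applies to distal layouts only, in
#' which signal elements directly abut the test region. Positive TAE means
#' repulsion of the test away from the implied orientation. Reflectional
#' symmetry of the field has no effect on the prediction.
#'
#' @param field An [orientation_field()].
#' @param layout A [layout_geometry()]. For annular layouts the coherence is
#'   derived from the geometry via [coherence_for_radius()]; intermixed
#'   layouts use their stated coherence.
#' @param params An [observer_params()].
#' @return An object of class `adaptation_state`: a list with
#'   `implied_orientation_at_test`, `effective_gradient`, `coherence`,
#'   `layout`, `predicted_tae`.
#' @export
#' @examples
#' st <- adaptation_state(orientation_field("concentric"),
#'                        layout_geometry(coherence = 1),
#'                        observer_params())
#' st$predicted_tae  # ~1.9
adaptation_state <- function(field, layout, params = observer_params()) {
  stopifnot(inherits(field, "orientation_field"),
            inherits(layout, "layout_geometry"),
            inherits(params, "observer_params"))
  coh <- if (layout$noise_layout == "intermixed") {
    if (is.na(layout$coherence)) stop("intermixed layout requires coherence")
    layout$coherence
  } else {
    coherence_for_radius(layout, layout$annulus_outer_radius)
  }
  g <- effective_gradient(field, layout$test_point,
                          params$step_ambiguity_threshold)
  implied <- implied_orientation(field, layout$test_point)
  tae <- params$tae_peak_amplitude * coh^params$coherence_exponent *
    gradient_tuning(g, params$tuning_center, params$tuning_halfwidth)
  if (layout$noise_layout == "distal") {
    tae <- tae + params$local_adaptation_gain * coh
  }
  structure(
    list(implied_orientation_at_test = implied,
         effective_gradient = g,
         coherence = coh,
         layout = layout$noise_layout,
         predicted_tae = tae),
    class = "adaptation_state")
}

#' @export
print.adaptation_state <- function(x, ...) {
  cat("<adaptation_state>\n")
  cat("  implied orientation at test:", round(x$implied_orientation_at_test, 3),
      "deg\n")
  cat("  effective gradient:", round(x$effective_gradient, 3), "deg/deg;",
      "coherence:", round(x$coherence, 3), ";", x$layout, "\n")
  cat("  predicted TAE:", round(x$predicted_tae, 3), "deg\n")
  invisible(x)
}

# P(respond "CW") for a test orientation under the observer's decision stage.
# CW = tilted clockwise of vertical = negative orientation in the CCW-positive
# convention, so P(CW) decreases with test orientation and crosses 0.5 at the
# PSE. Equivalently P(CCW) = lapse/2 + (1-lapse)*logistic((theta - pse)/slope).
p_clockwise <- function(params, true_pse, test_orientation) {
  params$lapse_rate / 2 + (1 - params$lapse_rate) *
    stats::plogis((true_pse - test_orientation) / params$psychometric_slope)
}

#' Simulate one 2AFC orientation judgment
#'
#' Draws a single clockwise / counter-clockwise response from the observer's
#' lapse-contaminated logistic decision stage. Responses are drawn from the
#' current RNG state; seed management belongs to the caller (see
#' [simulate_block()]).
#'
#' @param params An [observer_params()].
#' @param true_pse The observer's current point of subjective equality,
#'   degrees.
#' @param test_orientation Physical test orientation, degrees CCW from
#'   vertical.
#' @return `"CW"` or `"CCW"`.
#' @export
simulate_trial <- function(params, true_pse, test_orientation) {
  p <- p_clockwise(params, true_pse, test_orientation)
  if (stats::runif(1) < p) "CW" else "CCW"
}

#' Simulate one constant-stimuli testing block
#'
#' Ten presentations (by default) of seven linearly spaced test orientations
#' in randomized order, judged by the simulated observer whose PSE is
#' `true_pse` (0 for an unadapted baseline block).
#'
#' @param params An [observer_params()].
#' @param condition_id Condition label carried into the trial table.
#' @param true_pse Observer PSE for this condition, degrees.
#' @param levels Test orientations, degrees; strictly increasing.
#' @param reps Presentations per level (default 10).
#' @param seed Integer seed for ordering and responses.
#' @param block Block index carried into the table.
#' @return A tibble with columns `condition_id`, `block`, `trial`,
#'   `test_orientation_deg`, `response`.
#' @export
simulate_block <- function(params, condition_id, true_pse,
                           levels = seq(-3, 3, length.out = 7),
                           reps = 10, seed = params$seed, block = 1L) {
  stopifnot(inherits(params, "observer_params"),
            all(diff(levels) > 0), reps >= 1)
  with_seed(seed, {
    theta <- sample(rep(levels, each = reps))
    p <- p_clockwise(params, true_pse, theta)
    resp <- ifelse(stats::runif(length(theta)) < p, "CW", "CCW")
    tibble::tibble(condition_id = condition_id,
                   block = as.integer(block),
                   trial = seq_along(theta),
                   test_orientation_deg = theta,
                   response = resp)
  })
}
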