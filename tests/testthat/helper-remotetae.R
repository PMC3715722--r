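# shared fixtures and independent oracles, built in code at test time

TEST_POINT <- 10 * c(cos(pi / 12), sin(pi / 12))  # (9.66, 2.59) to 2 dp

concentric_field <- function() orientation_field("concentric")

linear_field <- function(rate, axis = "horizontal") {
  orientation_field("linear_gradient", gradient_rate = rate, axis = axis)
}

proximal_layout <- function(outer = 9.53) {
  layout_geometry(noise_layout = "proximal", annulus_outer_radius = outer)
}

# orientation (deg CCW from vertical, in [-90, 90)) of a direction vector:
# rotating the vertical unit (0, 1) by a CCW gives (-sin a, cos a)
axis_angle_of <- function(vx, vy) {
  wrap_orientation(atan2(-vx, vy) * 180 / pi)
}

# Monte-Carlo point-count oracle for the coherence geometry
mc_coherence <- function(layout, outer_radius, n = 1e6, seed = 1) {
  withr::with_seed(seed, {
    h <- layout$square_half_width
    x <- runif(n, -h, h)
    y <- runif(n, -h, h)
    d <- sqrt((x - layout$test_point[1])^2 + (y - layout$test_point[2])^2)
    r_eff <- effective_occlusion_radius(layout)
    visible <- d > r_eff
    in_ann <- visible & d <= outer_radius
    if (layout$noise_layout == "proximal") {
      sum(visible & !in_ann) / sum(visible)
    } else {
      sum(in_ann) / sum(visible)
    }
  })
}

# independent maximum-likelihood oracle: direct 2-D optimisation of the
# Bernoulli log-likelihood over (pse, log slope)
direct_ml_fit <- function(trials) {
  th <- trials$test_orientation_deg
  ccw <- as.numeric(trials$response == "CCW")
  nll <- function(par) {
    p <- plogis((th - par[1]) / exp(par[2]))
    p <- pmin(1 - 1e-12, pmax(1e-12, p))
    -sum(ccw * log(p) + (1 - ccw) * log(1 - p))
  }
  fit <- optim(c(0, 0), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  list(pse = fit$par[1], slope = exp(fit$par[2]), loglik = -fit$value)
}

# observer with the lapse stressor switched off, for recovery experiments
lapse_free_observer <- function(...) observer_params(lapse_rate = 0, ...)
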