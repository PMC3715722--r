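#' Construct the spatial layout of an adapting texture
#'
#' Describes the square texture region, the occluded test location, and how
#' randomly oriented noise elements are distributed relative to the test
#' site. In the `proximal` layout all noise elements are confined to an
#' annulus surrounding the test location; in the `distal` layout all signal
#' elements are (noise fills the remainder of the square); `intermixed`
#' assigns signal/noise labels independently of position with probability
#' `coherence`.
#'
#' @param square_half_width Half-width of the square texture region, degrees
#'   of visual angle (default 24, i.e. a 48 x 48 deg region centred on
#'   fixation).
#' @param test_point Test location `(x, y)` in degrees (default
#'   `(9.66, 2.59)`, i.e. polar angle pi/12 at 10 deg eccentricity).
#' @param occlusion_radius Radius of the zero-contrast region centred on the
#'   test location, degrees (default 3).
#' @param ramp_width Width of the quarter-cycle cosine contrast ramp beyond
#'   the occlusion, degrees (default 1.6).
#' @param noise_layout One of `"intermixed"`, `"proximal"`, `"distal"`.
#' @param annulus_outer_radius Outer radius of the noise (proximal) or signal
#'   (distal) annulus, degrees; required for proximal/distal layouts.
#' @param coherence Signal fraction in `[0, 1]`; required for the intermixed
#'   layout (for annular layouts coherence follows from the geometry, see
#'   [coherence_for_radius()]).
#' @return An object of class `layout_geometry`.
#' @export
layout_geometry <- function(square_half_width = 24,
                            test_point = c(9.66, 2.59),
                            occlusion_radius = 3.0,
                            ramp_width = 1.6,
                            noise_layout = c("intermixed", "proximal", "distal"),
                            annulus_outer_radius = NA_real_,
                            coherence = NA_real_) {
  noise_layout <- match.arg(noise_layout)
  stopifnot(square_half_width > 0, length(test_point) == 2L,
            occlusion_radius > 0, ramp_width >= 0)
  if (any(abs(test_point) >= square_half_width)) {
    stop("test_point must lie inside the square texture region")
  }
  if (!is.na(coherence) && (coherence < 0 || coherence > 1)) {
    stop("coherence must lie in [0, 1]")
  }
  r_eff <- occlusion_radius + ramp_width
  if (!is.na(annulus_outer_radius) && annulus_outer_radius < r_eff - 1e-9) {
    stop("annulus_outer_radius must be at least occlusion_radius + ramp_width")
  }
  structure(
    list(square_half_width = square_half_width,
         test_point = as.numeric(test_point),
         occlusion_radius = occlusion_radius,
         ramp_width = ramp_width,
         noise_layout = noise_layout,
         annulus_outer_radius = annulus_outer_radius,
         coherence = coherence),
    class = "layout_geometry")
}

#' @export
print.layout_geometry <- function(x, ...) {
  cat("<layout_geometry>", x$noise_layout, "\n")
  cat("  square: [-", x$square_half_width, ",", x$square_half_width, "]^2 deg;",
      " test point (", x$test_point[1], ",", x$test_point[2], ")\n", sep = "")
  cat("  occlusion", x$occlusion_radius, "deg + ramp", x$ramp_width, "deg\n")
  if (!is.na(x$annulus_outer_radius)) {
    cat("  annulus outer radius:", x$annulus_outer_radius, "deg\n")
  }
  if (!is.na(x$coherence)) cat("  coherence:", x$coherence, "\n")
  invisible(x)
}

#' Effective occlusion radius of a layout
#'
#' Elements centred inside the occlusion disc plus the full contrast ramp are
#' treated as not visible for coherence accounting: `occlusion_radius +
#' ramp_width` (4.6 deg under defaults).
#'
#' @param layout A [layout_geometry()].
#' @return Radius in degrees.
#' @export
effective_occlusion_radius <- function(layout) {
  layout$occlusion_radius + layout$ramp_width
}

# Area of the intersection of a disc (centre (cx, cy), radius R) with the
# axis-aligned rectangle [xmin,xmax] x [ymin,ymax], by piecewise-smooth
# numerical integration of clipped chord lengths (breakpoints where the
# chord meets a horizontal edge).
circle_rect_area <- function(cx, cy, R, xmin, xmax, ymin, ymax) {
  if (R <= 0) return(0)
  lo <- max(xmin, cx - R)
  hi <- min(xmax, cx + R)
  if (lo >= hi) return(0)
  chord <- function(x) {
    s <- sqrt(pmax(0, R^2 - (x - cx)^2))
    pmax(0, pmin(ymax, cy + s) - pmax(ymin, cy - s))
  }
  br <- c(lo, hi)
  for (d in c(abs(ymax - cy), abs(ymin - cy))) {
    if (d < R) {
      x0 <- sqrt(R^2 - d^2)
      br <- c(br, cx - x0, cx + x0)
    }
  }
  br <- sort(unique(pmin(hi, pmax(lo, br))))
  total <- 0
  for (i in seq_len(length(br) - 1L)) {
    if (br[i + 1L] - br[i] < 1e-12) next
    total <- total + stats::integrate(chord, br[i], br[i + 1L],
                                      rel.tol = 1e-10,
                                      subdivisions = 500L)$value
  }
  total
}

#' Structure coherence implied by an annulus outer radius
#'
#' Expected fraction of visible texture elements that carry the structured
#' (signal) orientation, under uniform element density on the square.
#' Visibility excludes elements within the effective occlusion radius of the
#' test point. For the `proximal` layout noise occupies the annulus from the
#' effective occlusion radius to `outer_radius` (clipped to the square) and
#' signal the remainder; the `distal` layout is the complement. Computed by
#' deterministic 2-D area integration.
#'
#' @param layout A [layout_geometry()] with a proximal or distal layout.
#' @param outer_radius Outer radius of the annulus, degrees; must be at least
#'   the effective occlusion radius.
#' @return Coherence as a fraction in `[0, 1]`.
#' @export
#' @examples
#' lay <- layout_geometry(noise_layout = "proximal", annulus_outer_radius = 9.53)
#' coherence_for_radius(lay, 9.53)  # ~0.902
coherence_for_radius <- function(layout, outer_radius) {
  stopifnot(inherits(layout, "layout_geometry"))
  if (layout$noise_layout == "intermixed") {
    stop("coherence_for_radius() applies to proximal/distal annular layouts")
  }
  r_eff <- effective_occlusion_radius(layout)
  if (outer_radius < r_eff - 1e-9) {
    stop("outer_radius is below the effective occlusion radius (", r_eff, " deg)")
  }
  h <- layout$square_half_width
  tx <- layout$test_point[1]
  ty <- layout$test_point[2]
  a_sq <- (2 * h)^2
  a_occ <- circle_rect_area(tx, ty, r_eff, -h, h, -h, h)
  a_outer <- circle_rect_area(tx, ty, outer_radius, -h, h, -h, h)
  visible <- a_sq - a_occ
  annulus <- a_outer - a_occ
  if (layout$noise_layout == "proximal") {
    (visible - annulus) / visible
  } else {
    annulus / visible
  }
}

# farthest corner of the square from the test point: the annulus reaches the
# whole square at (and beyond) this radius
max_annulus_radius <- function(layout) {
  h <- layout$square_half_width
  corners <- rbind(c(-h, -h), c(-h, h), c(h, -h), c(h, h))
  max(sqrt((corners[, 1] - layout$test_point[1])^2 +
             (corners[, 2] - layout$test_point[2])^2))
}

#' Solve for the annulus outer radius yielding a target coherence
#'
#' Inverts [coherence_for_radius()] by root bisection. Coherence is monotone
#' non-increasing in the outer radius for the proximal layout and
#' non-decreasing for the distal layout, so the root is unique within the
#' square's reach.
#'
#' @param layout A proximal or distal [layout_geometry()].
#' @param target_coherence Target signal fraction in `(0, 1]`.
#' @param tol Radius tolerance in degrees (default 1e-8).
#' @return Outer radius in degrees.
#' @export
#' @examples
#' lay <- layout_geometry(noise_layout = "proximal", annulus_outer_radius = 9.53)
#' solve_noise_radius(lay, 0.902)  # ~9.53
solve_noise_radius <- function(layout, target_coherence, tol = 1e-8) {
  stopifnot(inherits(layout, "layout_geometry"))
  if (layout$noise_layout == "intermixed") {
    stop("solve_noise_radius() applies to proximal/distal annular layouts")
  }
  if (target_coherence <= 0 || target_coherence > 1) {
    stop("target_coherence must lie in (0, 1]")
  }
  r_eff <- effective_occlusion_radius(layout)
  r_max <- max_annulus_radius(layout)
  if (target_coherence == 1) {
    return(if (layout$noise_layout == "proximal") r_eff else r_max)
  }
  f <- function(R) coherence_for_radius(layout, R) - target_coherence
  f_lo <- f(r_eff)
  f_hi <- f(r_max)
  if (sign(f_lo) == sign(f_hi)) {
    stop("target coherence ", target_coherence,
         " is unreachable for this layout geometry")
  }
  stats::uniroot(f, c(r_eff, r_max), tol = tol)$root
}
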