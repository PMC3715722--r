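#' Wrap an orientation into [-90, 90) degrees from vertical
#'
#' Orientations are 180-degree periodic. The canonical range is
#' \code{[-90, 90)} degrees counter-clockwise from vertical; \code{-90} and
#' \code{+90} denote the same (horizontal) orientation and the canonical
#' representative is \code{-90}.
#'
#' @param theta Numeric vector of orientations in degrees.
#' @return Numeric vector wrapped into \code{[-90, 90)}.
#' @export
#' @examples
#' wrap_orientation(c(0, 90, -90, 175, 200))
wrap_orientation <- function(theta) {
  ((theta + 90) %% 180) - 90
}

#' Signed orientation difference wrapped to (-90, 90]
#'
#' Smallest signed rotation taking orientation `a` onto orientation `b`,
#' respecting 180-degree periodicity.
#'
#' @param a,b Orientations in degrees.
#' @return Signed difference `b - a` in `(-90, 90]` degrees.
#' @export
orientation_difference <- function(a, b) {
  d <- (b - a) %% 180
  ifelse(d > 90, d - 180, d)
}

#' Construct an orientation field
#'
#' An orientation field is a declarative description of the local orientation
#' implied by a global texture structure at every position in the visual
#' field. Coordinates are degrees of visual angle with the origin at fixation,
#' x rightward and y upward; orientations are degrees counter-clockwise from
#' vertical in \code{[-90, 90)}.
#'
#' Kinds:
#' \describe{
#'   \item{concentric}{tangential orientation of circles centred on
#'     \code{center}; the implied orientation at a point equals its polar
#'     angle (mod 180).}
#'   \item{radial}{orientation along the radius; polar angle minus 90.}
#'   \item{linear_gradient}{orientation is a linear function of the
#'     coordinate along \code{axis}, anchored so that evaluating the field at
#'     \code{anchor_point} returns \code{anchor_orientation}.}
#'   \item{quantized_gradient}{a linear gradient replaced by constant bands
#'     of width \code{band_width} along the gradient axis, one band centred
#'     on the anchor; each band carries the space-average (= value at the
#'     band centre) of the underlying linear function.}
#'   \item{iso}{constant orientation \code{anchor_orientation} everywhere.}
#' }
#'
#' @param kind Field kind, see Details.
#' @param center Centre of a polar (concentric/radial) field, degrees.
#' @param gradient_rate Degrees of orientation per degree of visual angle
#'   (linear/quantized kinds); must be >= 0.
#' @param axis `"horizontal"` (orientation varies with x) or `"vertical"`
#'   (varies with y).
#' @param anchor_point Point whose implied orientation is pinned (the test
#'   location by default).
#' @param anchor_orientation Orientation at the anchor, degrees CCW from
#'   vertical.
#' @param band_width Band width in degrees of visual angle (quantized only).
#' @param symmetry `"none"` or `"about_gradient_axis_meridian"` (see
#'   [apply_symmetry()]).
#' @return An object of class `orientation_field`.
#' @export
#' @examples
#' f <- orientation_field("concentric")
#' implied_orientation(f, c(9.66, 2.59))
orientation_field <- function(kind = c("concentric", "radial", "linear_gradient",
                                       "quantized_gradient", "iso"),
                              center = c(0, 0),
                              gradient_rate = 0,
                              axis = c("horizontal", "vertical"),
                              anchor_point = c(9.66, 2.59),
                              anchor_orientation = 15,
                              band_width = NULL,
                              symmetry = c("none", "about_gradient_axis_meridian")) {
  kind <- match.arg(kind)
  axis <- match.arg(axis)
  symmetry <- match.arg(symmetry)
  stopifnot(is.numeric(gradient_rate), length(gradient_rate) == 1L,
            gradient_rate >= 0,
            length(center) == 2L, length(anchor_point) == 2L)
  if (kind == "quantized_gradient") {
    if (is.null(band_width) || !is.numeric(band_width) || band_width <= 0) {
      stop("`band_width` must be a positive number for quantized_gradient fields")
    }
  }
  structure(
    list(kind = kind,
         center = as.numeric(center),
         gradient_rate = as.numeric(gradient_rate),
         axis = axis,
         anchor_point = as.numeric(anchor_point),
         anchor_orientation = wrap_orientation(as.numeric(anchor_orientation)),
         band_width = if (is.null(band_width)) NULL else as.numeric(band_width),
         symmetry = symmetry),
    class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat("<orientation_field>", x$kind, "\n")
  if (x$kind %in% c("concentric", "radial")) {
    cat("  center: (", x$center[1], ",", x$center[2], ") deg\n")
  }
  if (x$kind %in% c("linear_gradient", "quantized_gradient")) {
    cat("  axis:", x$axis, " rate:", x$gradient_rate, "deg/deg\n")
    cat("  anchor: (", x$anchor_point[1], ",", x$anchor_point[2], ") at",
        x$anchor_orientation, "deg\n")
    if (!is.null(x$band_width)) cat("  band width:", x$band_width, "deg\n")
  }
  if (x$symmetry != "none") cat("  symmetry:", x$symmetry, "\n")
  invisible(x)
}

# coerce a point argument (length-2 vector or n x 2 matrix) to a matrix
as_point_matrix <- function(point) {
  if (is.matrix(point)) {
    stopifnot(ncol(point) == 2L)
    point
  } else {
    stopifnot(is.numeric(point), length(point) == 2L)
    matrix(point, ncol = 2L)
  }
}

# axis coordinate of points for a gradient field: x for horizontal, y for vertical
axis_coordinate <- function(field, pts) {
  if (field$axis == "horizontal") pts[, 1] else pts[, 2]
}

# base (symmetry-free) field evaluation; pts is an n x 2 matrix
implied_orientation_base <- function(field, pts) {
  switch(field$kind,
    iso = rep(field$anchor_orientation, nrow(pts)),
    concentric = ,
    radial = {
      dx <- pts[, 1] - field$center[1]
      dy <- pts[, 2] - field$center[2]
      r <- sqrt(dx^2 + dy^2)
      if (any(r < 1e-12)) {
        stop("degenerate point: polar orientation field evaluated at its center")
      }
      phi <- atan2(dy, dx) * 180 / pi
      if (field$kind == "concentric") wrap_orientation(phi)
      else wrap_orientation(phi - 90)
    },
    linear_gradient = {
      u <- axis_coordinate(field, pts)
      u0 <- if (field$axis == "horizontal") field$anchor_point[1] else field$anchor_point[2]
      wrap_orientation(field$anchor_orientation + field$gradient_rate * (u - u0))
    },
    quantized_gradient = {
      u <- axis_coordinate(field, pts)
      u0 <- if (field$axis == "horizontal") field$anchor_point[1] else field$anchor_point[2]
      k <- round((u - u0) / field$band_width)
      wrap_orientation(field$anchor_orientation +
                         field$gradient_rate * k * field$band_width)
    },
    stop("unknown field kind"))
}

#' Implied orientation of a field at one or more points
#'
#' Evaluates the local orientation a global structure prescribes at a visual
#' field location, whether or not an element is physically present there.
#' For a symmetric gradient field, points in the hemifield opposite the
#' anchor are evaluated at their mirror image with the orientation negated
#' (the mirror rule of [apply_symmetry()]).
#'
#' @param field An [orientation_field()].
#' @param point Length-2 numeric `(x, y)` in degrees, or an `n x 2` matrix.
#' @return Orientation(s) in degrees CCW from vertical, wrapped to
#'   `[-90, 90)`.
#' @export
#' @examples
#' conc <- orientation_field("concentric")
#' implied_orientation(conc, c(10, 0))       # 0: tangent is vertical
#' implied_orientation(conc, 10 * c(cos(pi / 12), sin(pi / 12)))  # 15
implied_orientation <- function(field, point) {
  pts <- as_point_matrix(point)
  if (field$symmetry == "about_gradient_axis_meridian" &&
      field$kind %in% c("linear_gradient", "quantized_gradient")) {
    # source hemifield contains the anchor; mirror coordinate is the one the
    # orientation does NOT vary with (horizontal-axis gradient -> mirror in y)
    mi <- if (field$axis == "horizontal") 2L else 1L
    src <- field$anchor_point[mi]
    if (src == 0) src <- 1  # anchor on the meridian: treat upper/right as source
    mirrored <- sign(pts[, mi]) == -sign(src) & pts[, mi] != 0
    pts_eval <- pts
    pts_eval[mirrored, mi] <- -pts_eval[mirrored, mi]
    th <- implied_orientation_base(field, pts_eval)
    th[mirrored] <- wrap_orientation(-th[mirrored])
    th
  } else {
    implied_orientation_base(field, pts)
  }
}

#' Magnitude of the spatial orientation gradient at a point
#'
#' Spatial rate of change of implied orientation, in degrees of orientation
#' per degree of visual angle. For concentric and radial fields the gradient
#' is measured along the iso-eccentric arc and equals `180 / (pi * r)` at
#' eccentricity `r`; for linear gradients it equals `gradient_rate`
#' everywhere; iso fields have gradient 0, and quantized fields are
#' piecewise constant so their pointwise gradient is 0 (see
#' [effective_gradient()] for the observer-level reading of banded
#' textures).
#'
#' @inheritParams implied_orientation
#' @return Gradient magnitude(s), degrees orientation per degree visual angle.
#' @export
#' @examples
#' local_gradient(orientation_field("concentric"), c(10, 0))  # 5.7296
local_gradient <- function(field, point) {
  pts <- as_point_matrix(point)
  switch(field$kind,
    concentric = ,
    radial = {
      dx <- pts[, 1] - field$center[1]
      dy <- pts[, 2] - field$center[2]
      r <- sqrt(dx^2 + dy^2)
      if (any(r < 1e-12)) {
        stop("degenerate point: polar orientation field evaluated at its center")
      }
      180 / (pi * r)
    },
    linear_gradient = rep(field$gradient_rate, nrow(pts)),
    quantized_gradient = rep(0, nrow(pts)),
    iso = rep(0, nrow(pts)))
}

#' Spatial period of the orientation modulation of a linear gradient
#'
#' Orientation is 180-degree periodic, so a linear gradient of `rate` degrees
#' of orientation per degree of visual angle repeats every `180 / rate`
#' degrees of visual angle.
#'
#' @param gradient_rate Degrees orientation per degree visual angle, > 0.
#' @return Spatial period in degrees of visual angle.
#' @export
#' @examples
#' orientation_period(5)  # 36
orientation_period <- function(gradient_rate) {
  stopifnot(gradient_rate > 0)
  180 / gradient_rate
}

#' Quantize a linear orientation gradient into constant spatial bands
#'
#' Partitions the gradient axis into bands of the stated width with one band
#' centred on the field's anchor point; within each band every element takes
#' the space-average of the underlying linear function (its value at the
#' band centre). Adjacent bands therefore differ by
#' `band_width * gradient_rate` degrees (mod 180); when the band width equals
#' the spatial period of the orientation modulation the result is an
#' iso-oriented texture.
#'
#' @param base A `linear_gradient` [orientation_field()].
#' @param band_width Band width, degrees of visual angle, > 0.
#' @return A `quantized_gradient` orientation field.
#' @export
#' @examples
#' lin <- orientation_field("linear_gradient", gradient_rate = 5)
#' q <- quantize_field(lin, 8)
#' implied_orientation(q, c(9.66 + 8, 2.59)) - implied_orientation(q, c(9.66, 2.59))
quantize_field <- function(base, band_width) {
  stopifnot(inherits(base, "orientation_field"))
  if (base$kind != "linear_gradient") {
    stop("quantize_field() requires a linear_gradient field")
  }
  stopifnot(is.numeric(band_width), length(band_width) == 1L, band_width > 0)
  out <- base
  out$kind <- "quantized_gradient"
  out$band_width <- as.numeric(band_width)
  out
}

#' Impose reflectional symmetry on a gradient field
#'
#' Mirrors the field about the meridian of its gradient axis: a texture whose
#' orientation changes with horizontal (x) position is made symmetric about
#' the horizontal midline (y = 0), and one changing with vertical position
#' about the vertical midline. The hemifield containing the anchor point is
#' the source; in the opposite hemifield the reflection maps `(x, y)` to
#' `(x, -y)` (horizontal meridian) or `(-x, y)` (vertical meridian) and
#' orientation to its negative (mod 180). Values on the anchor side —
#' including the implied orientation at the test location — are unchanged.
#'
#' @param field A `linear_gradient` or `quantized_gradient` field.
#' @param meridian `"horizontal"` or `"vertical"`; must match the field's
#'   gradient axis.
#' @return The field with its symmetry flag set.
#' @export
apply_symmetry <- function(field, meridian = c("horizontal", "vertical")) {
  meridian <- match.arg(meridian)
  stopifnot(inherits(field, "orientation_field"))
  if (!field$kind %in% c("linear_gradient", "quantized_gradient")) {
    stop("symmetry applies to linear or quantized gradient fields")
  }
  if (meridian != field$axis) {
    stop("meridian must match the field's gradient axis (",
         field$axis, " gradient -> ", field$axis, " midline)")
  }
  field$symmetry <- "about_gradient_axis_meridian"
  field
}
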