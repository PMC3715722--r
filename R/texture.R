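# run code under a given seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic sub-seed stream: n seeds below 2^31 derived from a master seed
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Specification of an adapting texture
#'
#' Bundles the orientation field, spatial layout and rendering parameters of
#' one dense oriented-element texture.
#'
#' @param field An [orientation_field()] giving each signal element's
#'   orientation as a function of its position.
#' @param layout A [layout_geometry()].
#' @param n_elements Number of local oriented elements (default 5000).
#' @param element_sf Element carrier spatial frequency, cycles per degree
#'   (default 1 for adaptors; test patches use 2).
#' @param element_diameter Diameter of the isotropic Hanning envelope,
#'   degrees (default 1.33).
#' @param rms_contrast Target RMS contrast of the normalised texture
#'   (default 0.09), measured over the full square before occlusion masking.
#' @param pixels_per_degree Rendering resolution (default 15, i.e. 4
#'   arcmin per pixel).
#' @param seed Integer seed for element sampling.
#' @return An object of class `texture_spec`.
#' @export
texture_spec <- function(field, layout, n_elements = 5000,
                         element_sf = 1.0, element_diameter = 1.33,
                         rms_contrast = 0.09, pixels_per_degree = 15,
                         seed = 1L) {
  stopifnot(inherits(field, "orientation_field"),
            inherits(layout, "layout_geometry"),
            n_elements > 0,
            rms_contrast > 0, rms_contrast < 0.5,
            pixels_per_degree >= 4)
  structure(
    list(field = field, layout = layout,
         n_elements = as.integer(n_elements),
         element_sf = element_sf,
         element_diameter = element_diameter,
         rms_contrast = rms_contrast,
         pixels_per_degree = pixels_per_degree,
         seed = as.integer(seed)),
    class = "texture_spec")
}

#' Sample the elements of one texture frame
#'
#' Draws `n_elements` positions i.i.d. uniform on the square, assigns
#' signal/noise labels according to the layout (intermixed: i.i.d. signal
#' with probability `coherence`; proximal: noise iff the element falls in
#' the annulus between the effective occlusion radius and the outer radius;
#' distal: noise iff beyond the outer radius), gives signal elements the
#' field's implied orientation at their position and noise elements i.i.d.
#' uniform orientations, and draws phases uniform on `[0, 2*pi)`.
#'
#' @param spec A [texture_spec()].
#' @param seed Integer seed (defaults to `spec$seed`). Same seed, same list.
#' @return A tibble with columns `x_deg`, `y_deg`, `orientation_deg`,
#'   `phase_rad`, `label`.
#' @export
sample_elements <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "texture_spec"))
  lay <- spec$layout
  n <- spec$n_elements
  h <- lay$square_half_width
  with_seed(seed, {
    x <- stats::runif(n, -h, h)
    y <- stats::runif(n, -h, h)
    label <- switch(lay$noise_layout,
      intermixed = {
        if (is.na(lay$coherence)) {
          stop("intermixed layout requires a coherence value")
        }
        ifelse(stats::runif(n) < lay$coherence, "signal", "noise")
      },
      proximal = {
        if (is.na(lay$annulus_outer_radius)) {
          stop("proximal layout requires annulus_outer_radius")
        }
        d <- sqrt((x - lay$test_point[1])^2 + (y - lay$test_point[2])^2)
        r_eff <- effective_occlusion_radius(lay)
        ifelse(d >= r_eff & d <= lay$annulus_outer_radius, "noise", "signal")
      },
      distal = {
        if (is.na(lay$annulus_outer_radius)) {
          stop("distal layout requires annulus_outer_radius")
        }
        d <- sqrt((x - lay$test_point[1])^2 + (y - lay$test_point[2])^2)
        ifelse(d > lay$annulus_outer_radius, "noise", "signal")
      })
    noise_or <- stats::runif(n, -90, 90)
    phase <- stats::runif(n, 0, 2 * pi)
    orientation <- noise_or
    is_sig <- label == "signal"
    if (any(is_sig)) {
      orientation[is_sig] <-
        implied_orientation(spec$field, cbind(x[is_sig], y[is_sig]))
    }
    tibble::tibble(x_deg = x, y_deg = y,
                   orientation_deg = wrap_orientation(orientation),
                   phase_rad = phase, label = label)
  })
}

#' Radial occlusion window profile
#'
#' Contrast multiplier as a function of distance from the test location:
#' 0 within the occlusion radius, rising as a quarter-cycle cosine
#' (`sin^2`) ramp over `ramp_width`, 1 beyond.
#'
#' @param r Distances from the test point, degrees.
#' @param occlusion_radius,ramp_width Window parameters, degrees.
#' @return Multipliers in `[0, 1]`.
#' @export
occlusion_profile <- function(r, occlusion_radius = 3.0, ramp_width = 1.6) {
  m <- numeric(length(r))
  ramp <- r > occlusion_radius & r < occlusion_radius + ramp_width
  m[ramp] <- sin(pi / 2 * (r[ramp] - occlusion_radius) / ramp_width)^2
  m[r >= occlusion_radius + ramp_width] <- 1
  m
}

# pixel-centre coordinates of the rendering grid (row 1 = top, +y)
render_grid <- function(half_width, pixels_per_degree) {
  d <- 1 / pixels_per_degree
  n <- round(2 * half_width * pixels_per_degree)
  list(x = -half_width + (seq_len(n) - 0.5) * d,
       y = half_width - (seq_len(n) - 0.5) * d,
       n = n, d = d)
}

# one element's windowed-sinusoid patch and its index window on the grid;
# the caller adds the patch into the image (keeping the large image matrix
# out of the call avoids a full copy per element)
element_patch <- function(grid, half_width, ex, ey, theta_deg, phase, sf,
                          diameter) {
  rad <- diameter / 2
  d <- grid$d
  h <- half_width
  j_lo <- max(1L, as.integer(ceiling((ex - rad + h) / d + 0.5 - 1e-9)))
  j_hi <- min(grid$n, as.integer(floor((ex + rad + h) / d + 0.5 + 1e-9)))
  i_lo <- max(1L, as.integer(ceiling((h - (ey + rad)) / d + 0.5 - 1e-9)))
  i_hi <- min(grid$n, as.integer(floor((h - (ey - rad)) / d + 0.5 + 1e-9)))
  if (j_lo > j_hi || i_lo > i_hi) return(NULL)
  dx <- grid$x[j_lo:j_hi] - ex
  dy <- grid$y[i_lo:i_hi] - ey
  th <- theta_deg * pi / 180
  # carrier varies along (cos th, sin th): vertical stripes at th = 0
  u <- outer(dy * sin(th), dx * cos(th), "+")
  r2 <- outer(dy^2, dx^2, "+")
  w <- cos(pi * sqrt(r2) / diameter)^2
  w[r2 >= rad^2] <- 0
  list(i = i_lo:i_hi, j = j_lo:j_hi,
       patch = cos(2 * pi * sf * u + phase) * w)
}

new_stimulus_image <- function(contrast, deg_per_px, origin, meta) {
  structure(list(contrast = contrast, deg_per_px = deg_per_px,
                 origin = origin, meta = meta),
            class = "stimulus_image")
}

#' @export
print.stimulus_image <- function(x, ...) {
  cat("<stimulus_image> ", nrow(x$contrast), "x", ncol(x$contrast),
      " px, ", x$deg_per_px, " deg/px\n", sep = "")
  cat("  contrast range [", round(min(x$contrast), 3), ", ",
      round(max(x$contrast), 3), "]\n", sep = "")
  invisible(x)
}

#' Render an adapting texture
#'
#' Draws each element as a sinusoid of the element's frequency, orientation
#' and phase under an isotropic raised-cosine (Hanning) window of the stated
#' diameter, sums the elements additively, subtracts the image mean and
#' rescales so the RMS contrast over the full square equals
#' `spec$rms_contrast`, then applies the occlusion window (zero contrast
#' within the occlusion radius of the test point, restored via a
#' quarter-cycle cosine ramp).
#'
#' @param elements An element tibble from [sample_elements()].
#' @param spec The corresponding [texture_spec()].
#' @param occlude Apply the occlusion window (default `TRUE`). Setting
#'   `FALSE` yields the normalised texture before masking, whose spatial
#'   mean is 0 and whose RMS contrast equals `spec$rms_contrast` exactly.
#' @return A `stimulus_image`: a list with the contrast matrix (row 1 = top),
#'   `deg_per_px`, the `(x, y)` of the first pixel centre, and provenance
#'   metadata.
#' @export
render_texture <- function(elements, spec, occlude = TRUE) {
  stopifnot(inherits(spec, "texture_spec"))
  if (nrow(elements) == 0L) stop("empty element list")
  lay <- spec$layout
  grid <- render_grid(lay$square_half_width, spec$pixels_per_degree)
  img <- matrix(0, grid$n, grid$n)
  for (i in seq_len(nrow(elements))) {
    p <- element_patch(grid, lay$square_half_width,
                       elements$x_deg[i], elements$y_deg[i],
                       elements$orientation_deg[i], elements$phase_rad[i],
                       spec$element_sf, spec$element_diameter)
    if (!is.null(p)) img[p$i, p$j] <- img[p$i, p$j] + p$patch
  }
  img <- img - mean(img)
  rms <- sqrt(mean(img^2))
  if (rms < .Machine$double.eps) stop("degenerate texture: zero contrast energy")
  img <- img * (spec$rms_contrast / rms)
  if (occlude) {
    r <- sqrt(outer((grid$y - lay$test_point[2])^2,
                    (grid$x - lay$test_point[1])^2, "+"))
    img <- img * occlusion_profile(r, lay$occlusion_radius, lay$ramp_width)
  }
  new_stimulus_image(img, grid$d, c(grid$x[1], grid$y[1]),
                     meta = list(seed = spec$seed,
                                 n_elements = nrow(elements),
                                 rms_contrast = spec$rms_contrast,
                                 field_kind = spec$field$kind))
}

#' Render a test patch
#'
#' A single sinusoid under a Hanning window, centred at the test location:
#' by default a 2 cycles-per-degree carrier, 1.33-degree envelope and peak
#' contrast 0.25. Background pixels (beyond the envelope radius) are exactly
#' zero.
#'
#' @param orientation Test orientation, degrees CCW from vertical
#'   (`|orientation| < 90`).
#' @param center Patch centre `(x, y)`, degrees.
#' @param element_sf Carrier frequency, cycles per degree.
#' @param element_diameter Envelope diameter, degrees.
#' @param peak_contrast Peak absolute (Michelson) contrast.
#' @param pixels_per_degree Rendering resolution.
#' @param phase Carrier phase in radians (0 = cosine at centre).
#' @return A `stimulus_image` covering the patch support.
#' @export
render_test <- function(orientation, center = c(9.66, 2.59),
                        element_sf = 2.0, element_diameter = 1.33,
                        peak_contrast = 0.25, pixels_per_degree = 15,
                        phase = 0) {
  stopifnot(abs(orientation) < 90, peak_contrast > 0, peak_contrast <= 1)
  rad <- element_diameter / 2
  d <- 1 / pixels_per_degree
  m <- floor(rad / d)
  off <- (-m:m) * d  # symmetric, odd pixel count, centre pixel on the centre
  th <- orientation * pi / 180
  u <- outer(off * sin(th), off * cos(th), "+")  # rows: y top-down handled below
  r2 <- outer(off^2, off^2, "+")
  w <- cos(pi * sqrt(r2) / element_diameter)^2
  w[r2 >= rad^2] <- 0
  img <- peak_contrast * cos(2 * pi * element_sf * u + phase) * w
  # row 1 = top (+y): flip row order of the symmetric offset grid
  img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  new_stimulus_image(img, d,
                     c(center[1] - m * d, center[2] + m * d),
                     meta = list(orientation = orientation,
                                 peak_contrast = peak_contrast))
}

#' Generate a dynamic adaptor sequence
#'
#' The adapting texture is regenerated at every refresh (100 ms by default)
#' to avoid the build-up of a retinal afterimage; each frame is an
#' independent element sample from a per-frame sub-seed derived
#' deterministically from the master seed.
#'
#' @param spec A [texture_spec()].
#' @param duration Sequence duration, seconds (> 0).
#' @param refresh Frame duration, seconds (default 0.1).
#' @param seed Master seed (defaults to `spec$seed`).
#' @return A list of `ceiling(duration / refresh)` element tibbles.
#' @export
make_adaptor_sequence <- function(spec, duration, refresh = 0.1,
                                  seed = spec$seed) {
  stopifnot(duration > 0, refresh > 0)
  n_frames <- ceiling(duration / refresh)
  sub <- derive_seeds(seed, n_frames)
  lapply(sub, function(s) sample_elements(spec, seed = s))
}

#' Export a stimulus image as an 8-bit grayscale PNG
#'
#' Contrast in `[-1, 1]` maps linearly to bytes `0..255` with 0 mapping to
#' 128 (round half up); out-of-range values are clipped.
#'
#' @param image A `stimulus_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_png <- function(image, path) {
  stopifnot(inherits(image, "stimulus_image"))
  b <- floor(127.5 * (pmin(pmax(image$contrast, -1), 1) + 1) + 0.5)
  b <- pmin(pmax(b, 0), 255)
  png::writePNG(b / 255, target = path)
  invisible(path)
}

#' Write / read an element list as CSV
#'
#' Plain-text round trip of the element schema
#' `x_deg,y_deg,orientation_deg,phase_rad,label`.
#'
#' @param elements Element tibble.
#' @param path File path.
#' @return The path (write) or the element tibble (read).
#' @export
write_elements_csv <- function(elements, path) {
  utils::write.csv(as.data.frame(elements), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_elements_csv
#' @export
read_elements_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("x_deg", "y_deg", "orientation_deg", "phase_rad", "label")
                %in% names(df)))
  tibble::as_tibble(df)
}
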