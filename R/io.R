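# flat key-value representations of the configurable objects -----------------

as_config_list <- function(x) {
  UseMethod("as_config_list")
}

#' @export
as_config_list.orientation_field <- function(x) {
  c(list(type = "orientation_field"),
    x[!vapply(x, is.null, logical(1))])
}

#' @export
as_config_list.layout_geometry <- function(x) {
  c(list(type = "layout_geometry"), unclass(x))
}

#' @export
as_config_list.observer_params <- function(x) {
  c(list(type = "observer_params"), unclass(x))
}

#' @export
as_config_list.texture_spec <- function(x) {
  list(type = "texture_spec",
       field = as_config_list(x$field),
       layout = as_config_list(x$layout),
       n_elements = x$n_elements,
       element_sf = x$element_sf,
       element_diameter = x$element_diameter,
       rms_contrast = x$rms_contrast,
       pixels_per_degree = x$pixels_per_degree,
       seed = x$seed)
}

config_to_object <- function(lst) {
  stopifnot(is.list(lst), !is.null(lst$type))
  type <- lst$type
  lst$type <- NULL
  switch(type,
    orientation_field = do.call(orientation_field, lst),
    layout_geometry = {
      lst <- lapply(lst, function(v) if (is.null(v)) NA_real_ else v)
      do.call(layout_geometry, lst)
    },
    observer_params = do.call(observer_params, lst),
    texture_spec = {
      field <- config_to_object(lst$field)
      layout <- config_to_object(lst$layout)
      rest <- lst[setdiff(names(lst), c("field", "layout"))]
      do.call(texture_spec, c(list(field = field, layout = layout), rest))
    },
    stop("unknown config type: ", type))
}

#' Write / read field, layout, observer and texture configurations
#'
#' Serialises [orientation_field()], [layout_geometry()],
#' [observer_params()] and [texture_spec()] objects to a flat key-value
#' schema; the format is chosen from the file extension (`.json`, `.yaml` /
#' `.yml`). Orientations are stored in degrees, positions in degrees of
#' visual angle.
#'
#' @param x An object of one of the types above.
#' @param path Output path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_config()` returns the path invisibly; `read_config()`
#'   returns the reconstructed object.
#' @export
#' @examples
#' f <- orientation_field("linear_gradient", gradient_rate = 5)
#' p <- tempfile(fileext = ".yaml")
#' write_config(f, p)
#' read_config(p)$gradient_rate
write_config <- function(x, path) {
  lst <- as_config_list(x)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(lst, path)
  } else {
    stop("unsupported config extension: .", ext)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported config extension: .", ext)
  }
  config_to_object(lst)
}

#' Write psychometric fits as JSON records
#'
#' @param fits A named list of [fit_psychometric()] objects (names are
#'   condition ids), each optionally carrying a `boot_se` entry.
#' @param path Output `.json` path.
#' @return The path, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  recs <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    list(condition_id = id, pse = f$pse, slope = f$slope,
         log_likelihood = f$log_likelihood, converged = f$converged,
         n_trials = f$n_trials,
         boot_se = if (is.null(f$boot_se)) NA else f$boot_se)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
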