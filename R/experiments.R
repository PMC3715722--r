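default_concentric_field <- function(test_point = c(9.66, 2.59)) {
  orientation_field("concentric", center = c(0, 0),
                    anchor_point = test_point, anchor_orientation = 15)
}

default_linear_field <- function(rate, axis, test_point = c(9.66, 2.59)) {
  orientation_field("linear_gradient", gradient_rate = rate, axis = axis,
                    anchor_point = test_point, anchor_orientation = 15)
}

condition_row <- function(condition_id, field, layout,
                          noise_layout = NA_character_, coherence = NA_real_,
                          gradient_rate = NA_real_, axis = NA_character_,
                          symmetric = NA, band_width = NA_real_) {
  tibble::tibble(condition_id = condition_id,
                 field = list(field), layout = list(layout),
                 noise_layout = noise_layout, coherence = coherence,
                 gradient_rate = gradient_rate, axis = axis,
                 symmetric = symmetric, band_width = band_width)
}

#' Build the condition grid of one experiment
#'
#' Constructs the adaptation conditions of the three texture experiments
#' plus exactly one no-adaptation baseline:
#' \describe{
#'   \item{exp1}{concentric structure; layouts intermixed / proximal /
#'     distal crossed with structure coherences (default 0.25, 0.5, 0.75,
#'     1.0); annulus radii for the segregated layouts are obtained with
#'     [solve_noise_radius()].}
#'   \item{exp2}{linear orientation gradients of rate 0 to 10 degrees per
#'     degree along the horizontal or vertical axis, with and without
#'     reflectional symmetry, all behind the 90%-coherence proximal noise
#'     annulus of outer radius 9.53 degrees.}
#'   \item{exp3}{a rate-5 horizontal gradient quantized into bands of width
#'     0.2 to 36 degrees, same proximal annulus.}
#' }
#' The level sets are defaults, overridable via the arguments.
#'
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @param coherences Coherence levels (exp1).
#' @param rates Gradient rates, degrees per degree (exp2).
#' @param axes Gradient axes (exp2).
#' @param band_widths Band widths, degrees (exp3).
#' @param proximal_radius Outer radius of the exp2/exp3 noise annulus,
#'   degrees.
#' @param blocks Testing blocks per condition (default 4).
#' @param seed Master seed for the grid's simulations.
#' @return An object of class `condition_grid`: experiment id, a conditions
#'   tibble (with list-columns `field` and `layout`; the baseline row has
#'   NULL field), `blocks` and `seed`.
#' @export
#' @examples
#' g <- build_grid("exp3", blocks = 2, seed = 7)
#' g$conditions$condition_id
build_grid <- function(experiment = c("exp1", "exp2", "exp3"),
                       coherences = c(0.25, 0.5, 0.75, 1.0),
                       rates = c(0, 1.25, 2.5, 5, 7.5, 10),
                       axes = c("horizontal", "vertical"),
                       band_widths = c(0.2, 2, 4, 8, 12, 24, 36),
                       proximal_radius = 9.53,
                       blocks = 4, seed = 1L) {
  experiment <- match.arg(experiment)
  rows <- list()
  if (experiment == "exp1") {
    field <- default_concentric_field()
    for (lay_kind in c("intermixed", "proximal", "distal")) {
      for (coh in coherences) {
        lay <- if (lay_kind == "intermixed") {
          layout_geometry(noise_layout = "intermixed", coherence = coh)
        } else {
          base <- layout_geometry(noise_layout = lay_kind,
                                  annulus_outer_radius = NA_real_,
                                  coherence = NA_real_)
          base$annulus_outer_radius <- solve_noise_radius(base, coh)
          base
        }
        id <- sprintf("%s_c%03.0f", lay_kind, 100 * coh)
        rows[[length(rows) + 1L]] <-
          condition_row(id, field, lay, noise_layout = lay_kind,
                        coherence = coh)
      }
    }
  } else if (experiment == "exp2") {
    for (rate in rates) {
      for (ax in axes) {
        for (sym in c(FALSE, TRUE)) {
          f <- default_linear_field(rate, ax)
          if (sym) f <- apply_symmetry(f, meridian = ax)
          lay <- layout_geometry(noise_layout = "proximal",
                                 annulus_outer_radius = proximal_radius)
          id <- sprintf("%s_r%04.1f%s", substr(ax, 1, 1), rate,
                        if (sym) "_sym" else "")
          rows[[length(rows) + 1L]] <-
            condition_row(id, f, lay, noise_layout = "proximal",
                          gradient_rate = rate, axis = ax, symmetric = sym)
        }
      }
    }
  } else {
    for (w in band_widths) {
      f <- quantize_field(default_linear_field(5, "horizontal"), w)
      lay <- layout_geometry(noise_layout = "proximal",
                             annulus_outer_radius = proximal_radius)
      id <- sprintf("band_%04.1f", w)
      rows[[length(rows) + 1L]] <-
        condition_row(id, f, lay, noise_layout = "proximal",
                      gradient_rate = 5, axis = "horizontal", band_width = w)
    }
  }
  rows[[length(rows) + 1L]] <-
    condition_row("baseline", NULL, NULL)
  structure(
    list(experiment = experiment,
         conditions = do.call(rbind, rows),
         blocks = as.integer(blocks),
         seed = as.integer(seed)),
    class = "condition_grid")
}

#' @export
print.condition_grid <- function(x, ...) {
  cat("<condition_grid> ", x$experiment, ": ", nrow(x$conditions),
      " conditions (incl. baseline), ", x$blocks, " blocks, seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Run the simulate-fit pipeline over a condition grid
#'
#' For every condition: derive the observer's adaptation state analytically
#' from the field and layout descriptors (textures are never rendered on the
#' response path), simulate `grid$blocks` constant-stimuli blocks, pool the
#' trials, fit the logistic psychometric function, bootstrap the PSE
#' standard error, and compute the TAE against the grid's baseline fit.
#' Deterministic given `grid$seed` and the observer parameters. Fitting
#' errors are recorded as flagged rows, never dropped silently.
#'
#' @param grid A [build_grid()] object.
#' @param observer An [observer_params()].
#' @param levels Constant-stimuli test orientations, degrees.
#' @param reps Presentations per level per block (default 10).
#' @param n_boot Bootstrap resamples per condition (default 500; 0 skips the
#'   bootstrap and reports `NA` SEs).
#' @param out_dir Optional directory: per-condition trial CSVs and the
#'   summary table are written there.
#' @param render If `TRUE`, additionally renders one example adaptor frame
#'   per adaptation condition into `out_dir` as PNG (visual QC only).
#' @return A `result_table` tibble: one row per condition with descriptors,
#'   `predicted_tae`, fitted `pse`, `slope`, `boot_se`, `tae`, `n_trials`,
#'   `converged` and `flag`.
#' @export
run_pipeline <- function(grid, observer = observer_params(),
                         levels = seq(-3, 3, length.out = 7), reps = 10,
                         n_boot = 500, out_dir = NULL, render = FALSE) {
  stopifnot(inherits(grid, "condition_grid"),
            inherits(observer, "observer_params"))
  conds <- grid$conditions
  n_cond <- nrow(conds)
  seeds <- matrix(derive_seeds(grid$seed, n_cond * (grid$blocks + 1L)),
                  nrow = n_cond)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  fits <- vector("list", n_cond)
  trials_by_cond <- vector("list", n_cond)
  states <- vector("list", n_cond)
  for (i in seq_len(n_cond)) {
    is_base <- conds$condition_id[i] == "baseline"
    st <- if (is_base) NULL else {
      adaptation_state(conds$field[[i]], conds$layout[[i]], observer)
    }
    true_pse <- if (is_base) 0 else {
      sign(st$implied_orientation_at_test) * st$predicted_tae
    }
    blocks <- lapply(seq_len(grid$blocks), function(b) {
      simulate_block(observer, conds$condition_id[i], true_pse,
                     levels = levels, reps = reps,
                     seed = seeds[i, b], block = b)
    })
    trials <- do.call(rbind, blocks)
    states[i] <- list(st)  # st may be NULL for the baseline row
    trials_by_cond[[i]] <- trials
    fits[[i]] <- tryCatch(
      list(fit = fit_psychometric(trials),
           se = if (n_boot > 0) {
             bootstrap_se(trials, n_boot = n_boot,
                          seed = seeds[i, grid$blocks + 1L])
           } else NA_real_,
           flag = NA_character_),
      error = function(e) list(fit = NULL, se = NA_real_,
                               flag = conditionMessage(e)),
      warning = function(w) {
        # refit while keeping the warning text as the row flag
        f <- suppressWarnings(fit_psychometric(trials))
        list(fit = f, se = NA_real_, flag = conditionMessage(w))
      })
    if (!is.null(out_dir)) {
      write_trials_csv(trials, file.path(
        out_dir, paste0("trials_", conds$condition_id[i], ".csv")))
    }
    if (render && !is.null(out_dir) && !is_base) {
      sp <- texture_spec(conds$field[[i]], conds$layout[[i]],
                         seed = seeds[i, 1L])
      img <- render_texture(sample_elements(sp), sp)
      write_stimulus_png(img, file.path(
        out_dir, paste0("adaptor_", conds$condition_id[i], ".png")))
    }
  }

  i_base <- which(conds$condition_id == "baseline")
  fit_base <- fits[[i_base]]$fit
  rows <- lapply(seq_len(n_cond), function(i) {
    f <- fits[[i]]
    ok <- !is.null(f$fit) && isTRUE(f$fit$converged)
    st <- states[[i]]
    tae <- if (i == i_base) 0 else if (ok && !is.null(fit_base) &&
                                         fit_base$converged) {
      compute_tae(f$fit, fit_base, st$implied_orientation_at_test)
    } else NA_real_
    tibble::tibble(
      experiment = grid$experiment,
      condition_id = conds$condition_id[i],
      noise_layout = conds$noise_layout[i],
      coherence = if (is.null(st)) NA_real_ else st$coherence,
      gradient_rate = conds$gradient_rate[i],
      axis = conds$axis[i],
      symmetric = conds$symmetric[i],
      band_width = conds$band_width[i],
      implied_orientation = if (is.null(st)) 0 else
        st$implied_orientation_at_test,
      predicted_tae = if (is.null(st)) 0 else st$predicted_tae,
      pse = if (is.null(f$fit)) NA_real_ else f$fit$pse,
      slope = if (is.null(f$fit)) NA_real_ else f$fit$slope,
      boot_se = as.numeric(f$se),
      tae = tae,
      n_trials = nrow(trials_by_cond[[i]]),
      converged = ok,
      flag = f$flag)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("result_table", class(res))
  if (!is.null(out_dir)) {
    utils::write.csv(as.data.frame(res), file.path(out_dir, "results.csv"),
                     row.names = FALSE)
  }
  res
}

#' Summarize a result table
#'
#' Per-experiment summary of the recovered TAEs: the gradient rate at which
#' the mean TAE peaks (exp2), the sign of the TAE-vs-coherence slope per
#' layout (exp1), and the largest band width whose TAE exceeds twice its
#' bootstrap SE (exp3). "Significant" is the 2-SE shorthand throughout.
#'
#' @param results A `result_table` from [run_pipeline()].
#' @return A list (JSON-serialisable) with the per-experiment summary
#'   components that apply to the table's conditions.
#' @export
summarize_results <- function(results) {
  stopifnot(nrow(results) > 0)
  adapt <- results[results$condition_id != "baseline" &
                     results$converged & !is.na(results$tae), , drop = FALSE]
  out <- list(experiment = unique(results$experiment),
              n_conditions = nrow(results))
  if (nrow(adapt) == 0L) {
    out$note <- "no estimable adaptation conditions after flags"
    return(out)
  }
  if (any(!is.na(adapt$gradient_rate)) && all(is.na(adapt$band_width))) {
    mean_by_rate <- tapply(adapt$tae, adapt$gradient_rate, mean)
    out$peak_gradient_rate <-
      as.numeric(names(mean_by_rate)[which.max(mean_by_rate)])
    out$tae_by_rate <- data.frame(gradient_rate = as.numeric(names(mean_by_rate)),
                                  mean_tae = as.numeric(mean_by_rate))
  }
  if (any(!is.na(adapt$coherence)) && any(!is.na(adapt$noise_layout)) &&
      all(is.na(adapt$gradient_rate))) {
    out$coherence_slope_sign <- vapply(
      split(adapt, adapt$noise_layout), function(d) {
        if (length(unique(d$coherence)) < 2) return(NA_real_)
        sign(unname(stats::coef(stats::lm(tae ~ coherence, data = d))[2]))
      }, numeric(1))
  }
  if (any(!is.na(adapt$band_width))) {
    sig <- adapt$tae > 2 * adapt$boot_se
    sig[is.na(sig)] <- FALSE
    out$largest_significant_band_width <-
      if (any(sig)) max(adapt$band_width[sig]) else NA_real_
  }
  out
}
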