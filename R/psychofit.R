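# aggregate a trial table to per-level binomial counts of CCW responses
aggregate_trials <- function(trials) {
  stopifnot(all(c("test_orientation_deg", "response") %in% names(trials)))
  if (!all(trials$response %in% c("CW", "CCW"))) {
    stop("responses must be 'CW' or 'CCW'")
  }
  th <- sort(unique(trials$test_orientation_deg))
  k <- vapply(th, function(t) {
    sum(trials$response[trials$test_orientation_deg == t] == "CCW")
  }, integer(1))
  n <- vapply(th, function(t) {
    sum(trials$test_orientation_deg == t)
  }, integer(1))
  data.frame(theta = th, k = k, n = n)
}

# Bernoulli log-likelihood of a 2-parameter logistic at aggregated counts
logistic_loglik <- function(pse, slope, agg) {
  p <- stats::plogis((agg$theta - pse) / slope)
  p <- pmin(1 - 1e-12, pmax(1e-12, p))
  sum(agg$k * log(p) + (agg$n - agg$k) * log(1 - p))
}

# complete separation: a cut orientation strictly divides the two response
# types (in either direction); the MLE slope diverges there
separation_gap <- function(trials) {
  th_cw <- trials$test_orientation_deg[trials$response == "CW"]
  th_ccw <- trials$test_orientation_deg[trials$response == "CCW"]
  if (length(th_cw) == 0L || length(th_ccw) == 0L) return(NULL)
  if (max(th_cw) < min(th_ccw)) return(c(max(th_cw), min(th_ccw)))
  if (max(th_ccw) < min(th_cw)) return(c(max(th_ccw), min(th_cw)))
  NULL
}

#' Fit a logistic psychometric function by maximum likelihood
#'
#' Models the probability of a counter-clockwise response as
#' `P(CCW | theta) = logistic((theta - pse) / slope)` and maximises the
#' Bernoulli likelihood over `(pse, slope)`; trials are aggregated to
#' per-level binomial counts and the fit is the canonical logistic-GLM MLE
#' (iteratively reweighted least squares), so it is deterministic given the
#' trials. The PSE is the orientation of equal clockwise /
#' counter-clockwise response proportions.
#'
#' Completely separated data (all CW responses strictly below all CCW
#' responses, or the reverse) have no finite MLE: the fit is flagged
#' non-converged with a warning and the PSE set to the midpoint of the
#' straddling levels. Data containing only one response type raise an
#' error.
#'
#' @param trials A trial table with columns `test_orientation_deg` and
#'   `response` (`"CW"`/`"CCW"`), e.g. from [simulate_block()]; blocks may
#'   be concatenated freely (pooled fitting).
#' @return An object of class `psychometric_fit`: `pse`, `slope` (degrees),
#'   `log_likelihood` (Bernoulli), `converged`, `n_trials`, `n_levels`.
#' @export
#' @examples
#' obs <- observer_params(lapse_rate = 0)
#' tr <- simulate_block(obs, "demo", true_pse = 2, seed = 42)
#' fit_psychometric(tr)
fit_psychometric <- function(trials) {
  agg <- aggregate_trials(trials)
  if (nrow(agg) < 2L) stop("need at least 2 distinct orientation levels")
  if (sum(agg$k) == 0L || sum(agg$k) == sum(agg$n)) {
    stop("all responses identical: psychometric function not estimable")
  }
  gap <- separation_gap(trials)
  if (!is.null(gap)) {
    warning("complete separation: responses perfectly ordered; ",
            "PSE set to the midpoint of the straddling levels")
    return(structure(
      list(pse = mean(gap), slope = NA_real_,
           log_likelihood = 0, converged = FALSE,
           n_trials = sum(agg$n), n_levels = nrow(agg)),
      class = "psychometric_fit"))
  }
  fit <- suppressWarnings(
    stats::glm(cbind(k, n - k) ~ theta, family = stats::binomial(),
               data = agg))
  b <- stats::coef(fit)
  slope <- 1 / b[["theta"]]
  pse <- -b[["(Intercept)"]] / b[["theta"]]
  converged <- isTRUE(fit$converged) && is.finite(slope) && slope > 0
  if (!converged) {
    warning("psychometric fit did not converge to a proper (slope > 0) solution")
  }
  structure(
    list(pse = unname(pse), slope = unname(slope),
         log_likelihood = logistic_loglik(pse, slope, agg),
         converged = converged,
         n_trials = sum(agg$n), n_levels = nrow(agg)),
    class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("<psychometric_fit> PSE = ", round(x$pse, 3), " deg, slope = ",
      round(x$slope, 3), " deg (n = ", x$n_trials, ", logLik = ",
      round(x$log_likelihood, 2), if (!x$converged) ", NOT converged" else "",
      ")\n", sep = "")
  invisible(x)
}

#' Bootstrap standard error of the PSE
#'
#' Nonparametric bootstrap for a method-of-constant-stimuli design:
#' responses are resampled with replacement within each orientation level
#' (for binary responses this is exactly a binomial draw at the observed
#' level proportion), the logistic is refitted, and the SE is the standard
#' deviation of the resampled PSEs. Degenerate resamples — complete
#' separation, a single response type, a non-positive refitted slope, or a
#' refitted PSE so far outside the tested orientation range (more than twice
#' the range span from its midpoint) that the resample does not localize it —
#' are dropped and counted; more than 10% dropped is an error.
#'
#' @param trials Trial table; the fit on the original data must succeed.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return The SE in degrees, with attribute `n_dropped`.
#' @export
bootstrap_se <- function(trials, n_boot = 1000, seed = 1L) {
  fit0 <- fit_psychometric(trials)  # errors propagate; separation warns
  if (!fit0$converged) stop("cannot bootstrap a non-converged fit")
  agg <- aggregate_trials(trials)
  phat <- agg$k / agg$n
  range_mid <- mean(range(agg$theta))
  range_span <- diff(range(agg$theta))
  pses <- with_seed(seed, {
    out <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      kb <- stats::rbinom(nrow(agg), agg$n, phat)
      if (sum(kb) == 0L || sum(kb) == sum(agg$n)) next
      # separation at the aggregated level: proportions 0/1 perfectly ordered
      # with no interior mixed level
      pb <- kb / agg$n
      if (all(pb %in% c(0, 1)) && !is.unsorted(pb)) next
      if (all(pb %in% c(0, 1)) && !is.unsorted(rev(pb))) next
      aggb <- data.frame(theta = agg$theta, k = kb, n = agg$n)
      fb <- suppressWarnings(
        stats::glm(cbind(k, n - k) ~ theta, family = stats::binomial(),
                   data = aggb))
      cb <- stats::coef(fb)
      if (!isTRUE(fb$converged) || !is.finite(cb[["theta"]]) ||
          cb[["theta"]] <= 0) next
      pse_b <- -cb[["(Intercept)"]] / cb[["theta"]]
      if (abs(pse_b - range_mid) > 2 * range_span) next
      out[b] <- pse_b
    }
    out
  })
  n_dropped <- sum(is.na(pses))
  if (n_dropped > 0.1 * n_boot) {
    stop("bootstrap degenerate: ", n_dropped, " of ", n_boot,
         " resamples dropped (> 10%)")
  }
  se <- stats::sd(pses, na.rm = TRUE)
  attr(se, "n_dropped") <- n_dropped
  se
}

#' Tilt aftereffect from adapted and baseline fits
#'
#' `TAE = sign(implied_orientation) * (pse_adapt - pse_base)` under the
#' CCW-positive convention, so a repulsive shift of the perceived test
#' orientation away from the implied adaptor orientation is positive
#' regardless of which side of vertical the implied orientation lies.
#'
#' @param fit_adapt,fit_base Converged [fit_psychometric()] objects for the
#'   adaptation and no-adaptation baseline conditions.
#' @param implied_orientation Implied adaptor orientation at the test
#'   location, degrees CCW from vertical. If exactly zero the repulsion sign
#'   is undefined: the raw PSE difference is returned with a warning and
#'   attribute `sign_undefined = TRUE`.
#' @return TAE in degrees.
#' @export
#' @examples
#' # a +2 deg PSE shift under a +15 deg implied orientation is a +2 deg TAE
compute_tae <- function(fit_adapt, fit_base, implied_orientation) {
  stopifnot(inherits(fit_adapt, "psychometric_fit"),
            inherits(fit_base, "psychometric_fit"))
  if (!fit_adapt$converged || !fit_base$converged) {
    stop("both fits must have converged to compute a TAE")
  }
  d <- fit_adapt$pse - fit_base$pse
  if (implied_orientation == 0) {
    warning("implied orientation is 0: repulsion sign undefined, ",
            "returning the raw PSE difference")
    attr(d, "sign_undefined") <- TRUE
    return(d)
  }
  sign(implied_orientation) * d
}

#' Write / read a trial table as CSV
#'
#' Plain-text round trip of the trial schema
#' `condition_id,block,trial,test_orientation_deg,response`.
#'
#' @param trials Trial tibble.
#' @param path File path.
#' @return The path (write) or the trial tibble (read).
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("condition_id", "block", "trial", "test_orientation_deg",
                  "response") %in% names(df)))
  tibble::as_tibble(df)
}
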