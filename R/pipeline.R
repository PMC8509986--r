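#' Two-stage mediation analysis with a censored mediator
#'
#' Runs the complete pipeline on a subject-level dataset: dummy coding of the
#' categorical exposure, stage-1 IPCW weighted least squares AFT fit with the
#' Kaplan-Meier residual distribution, stage-2 pseudo-likelihood outcome fit,
#' and the frequency-weighted overall indirect, direct, and total effects.
#'
#' @param data A [mediation_data()] tibble (or a plain data frame together
#'   with the column-mapping arguments of [mediation_data()] passed via
#'   `...`).
#' @param reference Reference exposure category (default: first factor
#'   level).
#' @param prevalence Population disease prevalence for case-control data
#'   (binary family); when supplied, inverse-prevalence sampling weights are
#'   attached with [sampling_weights()].
#' @param frequencies Optional `category_freqs` object (external
#'   frequencies); default: estimated from the data with sampling weights.
#' @param z_star Covariate profile for the effect measures (default: the
#'   sampling-weighted covariate mean).
#' @param method,conditional,control Passed to [fit_outcome()].
#' @param normalized Use renormalized non-reference frequency weights
#'   (default `TRUE`).
#' @param ... Column-mapping arguments forwarded to [mediation_data()] when
#'   `data` is a plain data frame.
#' @return An object of class `censored_mediation` bundling the dataset,
#'   design, both stage fits, the frequencies, and the `effect_estimates`
#'   tibble.
#' @examples
#' sc <- simulation_scenario(family = "continuous", n = 300, cp_target = 0.2)
#' d <- simulate_mediation(sc, seed = 7)
#' fit <- mediate_censored(d)
#' tidy(fit)
#' @export
mediate_censored <- function(data, reference = NULL, prevalence = NULL,
                             frequencies = NULL, z_star = NULL,
                             method = "newton", conditional = TRUE,
                             normalized = TRUE, control = list(), ...) {
  if (!inherits(data, "mediation_data")) data <- mediation_data(data, ...)
  if (!is.null(prevalence)) data <- sampling_weights(data, prevalence)
  design <- encode_dummies(data, reference = reference)
  freqs <- frequencies %||% category_frequencies(data, design)
  aft <- fit_aft(data, design)
  outcome <- fit_outcome(data, design, aft, method = method,
                         conditional = conditional, control = control)
  z_star <- z_star %||% {
    z <- covariate_matrix(data)
    if (ncol(z)) apply(z, 2, weighted.mean, w = data$.weight) else numeric(0)
  }
  effects <- overall_effects(aft, outcome, freqs, z_star = z_star,
                             normalized = normalized)
  structure(
    list(data = data, design = design, aft = aft, outcome = outcome,
         frequencies = freqs, effects = effects, z_star = z_star,
         prevalence = prevalence),
    class = "censored_mediation")
}

#' @export
print.censored_mediation <- function(x, ...) {
  cat(sprintf("<censored_mediation> n = %d, %s outcome, %.1f%% censored mediator\n",
              nrow(x$data), x$outcome$family, 100 * mean(x$data$.event == 0)))
  cat("\nStage 1 (AFT, log-time scale):\n")
  print(round(x$aft$coefficients, 4))
  cat("\nStage 2 (outcome model):\n")
  print(round(x$outcome$coefficients, 4))
  cat("\nOverall effects:\n")
  ov <- x$effects[x$effects$term %in% c("IE", "DE", "TE", "PM"), c("term", "estimate")]
  print(as.data.frame(ov), row.names = FALSE)
  invisible(x)
}

#' @rdname mediate_censored
#' @param x A `censored_mediation` object.
#' @param ... Unused.
#' @export
tidy.censored_mediation <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$aft), stage = "aft"),
    dplyr::mutate(tidy(x$outcome), stage = "outcome"),
    dplyr::mutate(
      tibble::tibble(term = x$effects$term, estimate = x$effects$estimate),
      stage = "effects"))
}

#' @rdname mediate_censored
#' @export
glance.censored_mediation <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$data),
    events = sum(x$data$.event),
    censoring_rate = mean(x$data$.event == 0),
    family = x$outcome$family,
    k = x$design$k,
    pseudo_logLik = x$outcome$logLik,
    converged = x$outcome$converged,
    IE = effect_value(x$effects, "IE"),
    DE = effect_value(x$effects, "DE"),
    TE = effect_value(x$effects, "TE"),
    PM = effect_value(x$effects, "PM"))
}
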