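#' Plot methods
#'
#' `autoplot.censored_mediation()` shows the per-category and overall effect
#' estimates; `autoplot.mediation_boot()` adds the BCa intervals;
#' `autoplot.aft_fit()` shows the Kaplan-Meier residual distribution together
#' with the censoring survival curve; `autoplot.simulation_study()` shows the
#' replicate distribution of the overall indirect effect against its
#' theoretical value.
#'
#' @param object The fitted object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name cenmediate-autoplot
NULL

overall_terms <- c("IE", "DE", "TE", "PM")

#' @rdname cenmediate-autoplot
#' @method autoplot censored_mediation
#' @export
autoplot.censored_mediation <- function(object, ...) {
  eff <- dplyr::mutate(object$effects,
                       kind = ifelse(.data$term %in% overall_terms,
                                     "overall", "per-category"))
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$estimate,
                                    y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~kind, scales = "free") +
    ggplot2::labs(x = "estimate", y = NULL,
                  title = "Mediation effect estimates") +
    ggplot2::theme_minimal()
}

#' @rdname cenmediate-autoplot
#' @method autoplot mediation_boot
#' @export
autoplot.mediation_boot <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  tab$kind <- ifelse(tab$term %in% overall_terms, "overall", "per-category")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~kind, scales = "free") +
    ggplot2::labs(x = "estimate (BCa interval)", y = NULL,
                  title = sprintf("Effects with %d%% BCa intervals",
                                  round(100 * (1 - attr(object, "alpha"))))) +
    ggplot2::theme_minimal()
}

#' @rdname cenmediate-autoplot
#' @method autoplot aft_fit
#' @export
autoplot.aft_fit <- function(object, ...) {
  rd <- object$resdist
  ggplot2::ggplot(rd, ggplot2::aes(x = .data$support, y = .data$mass)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$support, yend = 0)) +
    ggplot2::labs(x = "residual (log-time scale)", y = "Kaplan-Meier mass",
                  title = "Estimated AFT residual distribution") +
    ggplot2::theme_minimal()
}

#' @rdname cenmediate-autoplot
#' @method autoplot simulation_study
#' @export
autoplot.simulation_study <- function(object, ...) {
  ie_true <- effect_value(object$theoretical, "IE")
  ggplot2::ggplot(object$results, ggplot2::aes(x = .data$IE)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = ie_true, colour = "red") +
    ggplot2::labs(x = "overall indirect effect",
                  y = "replicates",
                  title = "Replicate distribution of the overall IE",
                  subtitle = sprintf("red line: theoretical value %.4f", ie_true)) +
    ggplot2::theme_minimal()
}
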