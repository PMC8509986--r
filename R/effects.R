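# Expectation of the outcome over a residual distribution given a location
# shift: sum_s p_s g(b0 + b*(e_s + shift) + offset).
residual_expectation <- function(support, mass, b0, b, shift, offset, binary) {
  lp <- b0 + b * (support + shift) + offset
  if (binary) sum(mass * plogis(lp)) else sum(mass * lp)
}

effect_pieces <- function(j, theta, phi, support, mass, z_star, design, binary) {
  k <- design$k
  pz <- length(design$covariates)
  a0 <- theta[1]
  aj <- theta[1 + j]
  gt_z <- if (pz) sum(theta[k + seq_len(pz)] * z_star) else 0
  b0 <- phi[1]
  b <- phi[2]
  cj <- phi[2 + j]
  g_z <- if (pz) sum(phi[1 + k + seq_len(pz)] * z_star) else 0
  list(
    # mediator at its x_j = 1 law, exposure at x_j = 1
    m1x1 = residual_expectation(support, mass, b0, b, a0 + aj + gt_z, cj + g_z, binary),
    # mediator at reference law, exposure at x_j = 1
    m0x1 = residual_expectation(support, mass, b0, b, a0 + gt_z, cj + g_z, binary),
    # mediator at reference law, exposure at reference
    m0x0 = residual_expectation(support, mass, b0, b, a0 + gt_z, g_z, binary))
}

#' Per-category natural indirect and direct effects
#'
#' Counterfactual contrasts of category `d_j` versus the reference `d_0`,
#' computed by integrating the fitted outcome model over the stage-1
#' residual distribution. The indirect effect shifts the mediator law
#' between its `x_j = 1` and reference counterfactuals with the exposure
#' held at `d_j`; the direct effect shifts the exposure with the mediator
#' law held at its reference counterfactual. For the continuous family these
#' reduce algebraically to `b * a_j` and `c_j`.
#'
#' @param j Non-reference category index (1 .. k-1, in design order).
#' @param aft A [fit_aft()] result.
#' @param outcome A [fit_outcome()] result.
#' @param z_star Covariate profile at which effects are evaluated (defaults
#'   to zero; [mediate_censored()] passes the weighted covariate mean).
#' @return The effect estimate (scalar).
#' @export
ie_category <- function(j, aft, outcome, z_star = NULL) {
  design <- aft$design
  stopifnot(j >= 1, j <= design$k - 1)
  z_star <- z_star %||% rep(0, length(design$covariates))
  p <- effect_pieces(j, aft$coefficients, outcome$coefficients,
                     aft$resdist$support, aft$resdist$mass, z_star, design,
                     outcome$family == "binary")
  p$m1x1 - p$m0x1
}

#' @rdname ie_category
#' @export
de_category <- function(j, aft, outcome, z_star = NULL) {
  design <- aft$design
  stopifnot(j >= 1, j <= design$k - 1)
  z_star <- z_star %||% rep(0, length(design$covariates))
  p <- effect_pieces(j, aft$coefficients, outcome$coefficients,
                     aft$resdist$support, aft$resdist$mass, z_star, design,
                     outcome$family == "binary")
  p$m0x1 - p$m0x0
}

effects_table <- function(ie_j, de_j, labels, reference, fw, z_star) {
  IE <- sum(fw * ie_j)
  DE <- sum(fw * de_j)
  TE <- IE + DE
  PM <- if (abs(TE) > 1e-10) IE / TE else NA_real_
  per <- tibble::tibble(
    term = c(paste0("IE_", labels, "_vs_", reference),
             paste0("DE_", labels, "_vs_", reference)),
    estimate = c(ie_j, de_j),
    weight = c(fw, fw))
  overall <- tibble::tibble(
    term = c("IE", "DE", "TE", "PM"),
    estimate = c(IE, DE, TE, PM),
    weight = NA_real_)
  out <- dplyr::bind_rows(per, overall)
  structure(out,
            class = c("effect_estimates", class(tibble::tibble())),
            z_star = z_star, te_degenerate = abs(TE) <= 1e-10)
}

#' Frequency-weighted overall mediation effects
#'
#' Combines the per-category effects into the overall indirect, direct, and
#' total effects by weighting each category-versus-reference contrast with
#' its exposure-category frequency, and reports the proportion mediated
#' `PM = IE / TE`. By default the weights are the non-reference frequencies
#' renormalized to sum to one (column `weight` of a `category_freqs` object);
#' `normalized = FALSE` uses the raw frequencies as printed in the defining
#' sums.
#'
#' @param aft,outcome Stage-1 and stage-2 fits on a common design.
#' @param freqs A `category_freqs` object (see [category_frequencies()]).
#' @param z_star Covariate profile (see [ie_category()]).
#' @param normalized Use renormalized non-reference weights (default `TRUE`).
#' @return An `effect_estimates` tibble with per-category and overall rows
#'   (`term`, `estimate`, `weight`); `PM` is `NA` when `|TE|` is numerically
#'   zero.
#' @export
overall_effects <- function(aft, outcome, freqs, z_star = NULL,
                            normalized = TRUE) {
  design <- aft$design
  stopifnot(inherits(freqs, "category_freqs"))
  labels <- design$labels[-1]
  idx <- match(labels, freqs$category)
  if (anyNA(idx)) abort("`freqs` does not cover all non-reference categories")
  fw <- if (normalized) freqs$weight[idx] else freqs$frequency[idx]
  z_star <- z_star %||% rep(0, length(design$covariates))
  ie_j <- vapply(seq_along(labels), ie_category, numeric(1),
                 aft = aft, outcome = outcome, z_star = z_star)
  de_j <- vapply(seq_along(labels), de_category, numeric(1),
                 aft = aft, outcome = outcome, z_star = z_star)
  effects_table(ie_j, de_j, labels, design$reference, fw, z_star)
}

#' Theoretical effects under known generating parameters
#'
#' Computes the same per-category and overall effect measures as
#' [overall_effects()] but with the AFT error distribution replaced by its
#' generating standard normal law: closed form for the continuous family
#' (`IE_j = b a_j`, `DE_j = c_j`) and Gauss-Hermite quadrature for the
#' binary family.
#'
#' @param a0 AFT intercept.
#' @param a Per-category AFT coefficients `a_j` (length k-1).
#' @param b0,b Outcome-model intercept and mediator coefficient.
#' @param c_tilde Per-category direct-path coefficients (length k-1).
#' @param freqs A `category_freqs` object.
#' @param family `"continuous"` or `"binary"`.
#' @param gamma,gamma_tilde,z_star Covariate coefficients of the outcome and
#'   AFT models and the profile at which to evaluate (all optional).
#' @param nodes Number of Gauss-Hermite nodes (default 40).
#' @param normalized Use renormalized non-reference weights (default `TRUE`).
#' @return An `effect_estimates` tibble (see [overall_effects()]).
#' @examples
#' theoretical_effects(a0 = 6, a = c(0.4, 0.8), b0 = 1, b = 0.4,
#'                     c_tilde = c(0.5, 1), freqs = hwe_frequencies(0.3))
#' @export
theoretical_effects <- function(a0, a, b0, b, c_tilde, freqs,
                                family = c("continuous", "binary"),
                                gamma = NULL, gamma_tilde = NULL, z_star = NULL,
                                nodes = 40, normalized = TRUE) {
  family <- match.arg(family)
  stopifnot(inherits(freqs, "category_freqs"), length(a) == length(c_tilde))
  labels <- freqs$category[freqs$category != attr(freqs, "reference")]
  stopifnot(length(a) == length(labels))
  fw <- if (normalized) freqs$weight[match(labels, freqs$category)] else
    freqs$frequency[match(labels, freqs$category)]
  gz <- if (!is.null(gamma) && !is.null(z_star)) sum(gamma * z_star) else 0
  gtz <- if (!is.null(gamma_tilde) && !is.null(z_star)) sum(gamma_tilde * z_star) else 0

  if (family == "continuous") {
    ie_j <- b * a
    de_j <- c_tilde
  } else {
    gh <- pracma::gaussHermite(nodes)
    eps <- sqrt(2) * gh$x
    wts <- gh$w / sqrt(pi)
    Eg <- function(shift, offset) sum(wts * plogis(b0 + b * (eps + shift) + offset))
    ie_j <- vapply(seq_along(a), function(j)
      Eg(a0 + a[j] + gtz, c_tilde[j] + gz) - Eg(a0 + gtz, c_tilde[j] + gz),
      numeric(1))
    de_j <- vapply(seq_along(a), function(j)
      Eg(a0 + gtz, c_tilde[j] + gz) - Eg(a0 + gtz, gz), numeric(1))
  }
  effects_table(ie_j, de_j, labels, attr(freqs, "reference"), fw,
                z_star %||% numeric(0))
}

#' Monte-Carlo check of the theoretical effects
#'
#' Independent Monte-Carlo integration of the binary-family theoretical
#' effects using common standard-normal draws for all terms; a cross-check
#' for the Gauss-Hermite quadrature in [theoretical_effects()].
#'
#' @inheritParams theoretical_effects
#' @param draws Number of standard-normal draws.
#' @param seed RNG seed.
#' @return An `effect_estimates` tibble.
#' @export
theoretical_effects_mc <- function(a0, a, b0, b, c_tilde, freqs,
                                   draws = 1e6, seed = 1, normalized = TRUE) {
  stopifnot(inherits(freqs, "category_freqs"))
  labels <- freqs$category[freqs$category != attr(freqs, "reference")]
  fw <- if (normalized) freqs$weight[match(labels, freqs$category)] else
    freqs$frequency[match(labels, freqs$category)]
  set.seed(seed)
  eps <- rnorm(draws)
  Eg <- function(shift, offset) mean(plogis(b0 + b * (eps + shift) + offset))
  ie_j <- vapply(seq_along(a), function(j)
    Eg(a0 + a[j], c_tilde[j]) - Eg(a0, c_tilde[j]), numeric(1))
  de_j <- vapply(seq_along(a), function(j)
    Eg(a0, c_tilde[j]) - Eg(a0, 0), numeric(1))
  effects_table(ie_j, de_j, labels, attr(freqs, "reference"), fw, numeric(0))
}

#' @export
print.effect_estimates <- function(x, ...) {
  cat("<effect_estimates>\n")
  NextMethod()
}

# convenience accessor used throughout
effect_value <- function(effects, term) {
  effects$estimate[match(term, effects$term)]
}
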