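#' Assemble a subject-level mediation dataset
#'
#' Validates and standardizes subject-level records for a mediation model with
#' a right-censored mediator: an outcome, the observed mediator time
#' `m = min(t, c)`, the event indicator `delta = I(t <= c)`, a categorical
#' exposure, optional covariates, and optional sampling weights.
#'
#' @param data A data frame with one row per subject.
#' @param outcome,mediator,event,exposure Column names (strings) holding the
#'   outcome, the observed mediator time (must be positive), the event
#'   indicator (1 = mediator observed, 0 = right-censored), and the exposure
#'   category.
#' @param covariates Character vector of covariate column names (optional).
#' @param weights Column name of per-subject sampling weights (optional;
#'   defaults to unit weights).
#' @param family `"continuous"` or `"binary"`; binary outcomes must be 0/1.
#'
#' @return A tibble of class `mediation_data` with standardized columns
#'   `.outcome`, `.time`, `.event`, `.exposure` (factor), `.weight`, and the
#'   covariate columns; the outcome family and covariate names are stored as
#'   attributes.
#' @examples
#' d <- data.frame(y = rnorm(4), m = c(2, 3, 1, 5), d = c(1, 0, 1, 1),
#'                 g = c("rr", "Rr", "rr", "RR"))
#' mediation_data(d, "y", "m", "d", "g")
#' @export
mediation_data <- function(data, outcome, mediator, event, exposure,
                           covariates = NULL, weights = NULL,
                           family = c("continuous", "binary")) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data))
  need <- c(outcome, mediator, event, exposure, covariates, weights)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("column(s) not found in `data`: ",
                 paste(missing_cols, collapse = ", ")))
  }

  y <- data[[outcome]]
  m <- data[[mediator]]
  d <- data[[event]]
  x <- data[[exposure]]
  w <- if (is.null(weights)) rep(1, nrow(data)) else data[[weights]]

  num_cols <- c(outcome, mediator, event, weights, covariates)
  for (cl in num_cols) {
    if (!is.numeric(data[[cl]])) abort(paste0("column `", cl, "` must be numeric"))
    if (anyNA(data[[cl]])) abort(paste0("column `", cl, "` contains missing values"))
  }
  if (anyNA(x)) abort(paste0("column `", exposure, "` contains missing values"))
  bad_m <- which(m <= 0)
  if (length(bad_m)) {
    abort(paste0("mediator times must be positive; first offending row: ", bad_m[1]))
  }
  if (!all(d %in% c(0, 1))) abort("event indicator must be 0/1")
  if (!any(d == 1)) abort("at least one subject must have an observed (uncensored) mediator")
  if (any(w <= 0)) abort("sampling weights must be positive")
  if (family == "binary" && !all(y %in% c(0, 1))) {
    abort("binary family requires a 0/1 outcome")
  }

  out <- tibble::tibble(
    .outcome = as.numeric(y),
    .time = as.numeric(m),
    .event = as.integer(d),
    .exposure = if (is.factor(x)) x else factor(x),
    .weight = as.numeric(w)
  )
  for (cl in covariates) out[[cl]] <- as.numeric(data[[cl]])

  structure(out,
            class = c("mediation_data", class(out)),
            family = family,
            covariates = covariates %||% character(0))
}

#' @export
print.mediation_data <- function(x, ...) {
  cat(sprintf("<mediation_data> %d subjects, %s outcome, %.1f%% censored\n",
              nrow(x), attr(x, "family"), 100 * mean(x$.event == 0)))
  NextMethod()
}

outcome_family <- function(data) attr(data, "family")
covariate_names <- function(data) attr(data, "covariates")

covariate_matrix <- function(data) {
  cn <- covariate_names(data)
  if (!length(cn)) {
    matrix(numeric(0), nrow = nrow(data), ncol = 0)
  } else {
    as.matrix(as.data.frame(data)[, cn, drop = FALSE])
  }
}

#' Dummy-code a categorical exposure against a reference category
#'
#' Builds the k-1 indicator variables `X_j = I(X = d_j)` for a k-category
#' exposure with `d_0` as the reference, together with the stage-1 design rows
#' `A_i = (1, x_1i, ..., x_(k-1)i, z_i)`. The category order is deterministic:
#' reference first, then `order` if given, otherwise the factor's level order.
#'
#' @param data A [mediation_data()] tibble.
#' @param reference Reference category label `d_0`. Defaults to the first
#'   factor level of the exposure.
#' @param order Optional character vector fixing the order of the
#'   non-reference categories.
#'
#' @return An object of class `dummy_design` with elements `labels` (reference
#'   first), `k`, `indicators` (n x (k-1) matrix), and `design` (the A matrix
#'   including intercept and covariates).
#' @examples
#' d <- data.frame(y = rnorm(6), m = rexp(6) + 1, d = rep(1, 6),
#'                 g = c("rr", "Rr", "RR", "rr", "Rr", "rr"))
#' md <- mediation_data(d, "y", "m", "d", "g")
#' encode_dummies(md, reference = "rr")
#' @export
encode_dummies <- function(data, reference = NULL, order = NULL) {
  stopifnot(inherits(data, "mediation_data"))
  x <- data$.exposure
  observed <- levels(droplevels(x))
  if (is.null(reference)) reference <- observed[1]
  reference <- as.character(reference)
  if (!reference %in% observed) {
    abort(paste0("reference category `", reference, "` not present among observed categories"))
  }
  others <- setdiff(observed, reference)
  if (!length(others)) abort("exposure must have at least two observed categories")
  if (!is.null(order)) {
    if (!setequal(order, others)) {
      abort("`order` must be a permutation of the non-reference categories")
    }
    others <- as.character(order)
  }
  labels <- c(reference, others)
  k <- length(labels)

  ind <- vapply(others, function(lab) as.numeric(x == lab), numeric(nrow(data)))
  ind <- matrix(ind, nrow = nrow(data), ncol = k - 1,
                dimnames = list(NULL, paste0("x_", others)))
  z <- covariate_matrix(data)
  design <- cbind(`(Intercept)` = 1, ind, z)

  structure(
    list(labels = labels, reference = reference, k = k,
         indicators = ind, design = design,
         covariates = covariate_names(data)),
    class = "dummy_design")
}

#' @export
print.dummy_design <- function(x, ...) {
  cat(sprintf("<dummy_design> k = %d categories (reference `%s`): %s\n",
              x$k, x$reference, paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Decode indicator rows back to category labels
#'
#' Inverse of the dummy coding: maps each row of the indicator matrix back to
#' its category label.
#'
#' @param design A [encode_dummies()] result.
#' @return Character vector of category labels, one per subject.
#' @export
decode_dummies <- function(design) {
  stopifnot(inherits(design, "dummy_design"))
  idx <- design$indicators %*% seq_len(design$k - 1)
  design$labels[as.integer(idx) + 1]
}

new_category_freqs <- function(labels, raw, reference, source) {
  raw <- as.numeric(raw)
  if (any(raw < 0)) abort("category frequencies must be non-negative")
  if (abs(sum(raw) - 1) > 1e-12) raw <- raw / sum(raw)
  nonref <- labels != reference
  tot <- sum(raw[nonref])
  if (tot <= 0) abort("all non-reference category frequencies are zero")
  weight <- ifelse(nonref, raw / tot, NA_real_)
  structure(
    tibble::tibble(category = labels, frequency = raw, weight = weight),
    class = c("category_freqs", class(tibble::tibble())),
    reference = reference, source = source)
}

#' Hardy-Weinberg genotype frequencies
#'
#' Genotype frequencies `((1-p)^2, 2p(1-p), p^2)` for genotypes (rr, Rr, RR)
#' at minor allele frequency `p`, together with the weights used by the
#' overall-effect measures: the non-reference frequencies renormalized to sum
#' to one (see [category_frequencies()] for the rationale).
#'
#' @param maf Minor allele frequency, strictly between 0 and 1.
#' @param labels Genotype labels, reference (homozygous major) first.
#' @return A `category_freqs` tibble with columns `category`, `frequency`
#'   (raw, summing to 1) and `weight` (normalized over non-reference
#'   categories; `NA` for the reference).
#' @examples
#' hwe_frequencies(0.3) # frequencies 0.49, 0.42, 0.09
#' @export
hwe_frequencies <- function(maf, labels = c("rr", "Rr", "RR")) {
  if (!is.numeric(maf) || length(maf) != 1 || maf <= 0 || maf >= 1) {
    abort("`maf` must be a single probability strictly between 0 and 1")
  }
  stopifnot(length(labels) == 3)
  # 1 - 2p + p^2 rather than (1-p)^2: algebraically identical but lands on
  # the decimal literals (0.49 at p = 0.3) in floating point
  raw <- c(1 - 2 * maf + maf^2, 2 * maf * (1 - maf), maf^2)
  new_category_freqs(labels, raw, reference = labels[1], source = "hwe")
}

#' Category frequencies for the overall effect measures
#'
#' Estimates the exposure-category frequencies `f_j` used to weight the
#' per-category effects into overall IE/DE/TE, either from the data
#' (optionally using the sampling weights, so that case-control samples
#' target population frequencies) or from an external table.
#'
#' The overall measures weight the k-1 non-reference contrasts by `f_j`
#' renormalized to sum to one over the non-reference categories; the raw
#' frequencies are also retained so raw weighting can be requested in
#' [overall_effects()].
#'
#' @param data A [mediation_data()] tibble.
#' @param design A [encode_dummies()] result (fixes labels and reference).
#' @param external Optional data frame with columns `category` and
#'   `frequency` covering all k categories; used verbatim when supplied.
#' @param use_weights Use sampling weights when estimating from data
#'   (default `TRUE`).
#' @return A `category_freqs` tibble (see [hwe_frequencies()]).
#' @export
category_frequencies <- function(data, design, external = NULL,
                                 use_weights = TRUE) {
  stopifnot(inherits(design, "dummy_design"))
  labels <- design$labels
  if (!is.null(external)) {
    stopifnot(is.data.frame(external),
              all(c("category", "frequency") %in% names(external)))
    miss <- setdiff(labels, as.character(external$category))
    if (length(miss)) {
      abort(paste0("external frequency table is missing categories: ",
                   paste(miss, collapse = ", ")))
    }
    raw <- external$frequency[match(labels, as.character(external$category))]
    return(new_category_freqs(labels, raw, design$reference, source = "external"))
  }
  stopifnot(inherits(data, "mediation_data"))
  x <- as.character(data$.exposure)
  w <- if (use_weights) data$.weight else rep(1, nrow(data))
  raw <- vapply(labels, function(lab) sum(w[x == lab]), numeric(1)) / sum(w)
  if (any(raw == 0)) {
    abort(paste0("category `", labels[which(raw == 0)[1]],
                 "` has no subjects; supply `external` frequencies instead"))
  }
  new_category_freqs(labels, raw, design$reference, source = "estimated")
}
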