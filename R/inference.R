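#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Standard BCa construction: the bias-correction `z0` is the normal quantile
#' of the fraction of replicates below the point estimate (ties counted
#' half), the acceleration `a` comes from the jackknife skewness formula,
#' and the adjusted percentiles are read off the empirical replicate
#' distribution with linear-interpolation quantiles.
#'
#' @param point Point estimate on the full sample.
#' @param replicates Numeric vector of bootstrap replicate estimates.
#' @param jackknife Optional leave-one-out estimates for the acceleration
#'   term; when `NULL`, `a = 0` (bias-corrected percentile interval).
#' @param alpha Two-sided miscoverage level (interval level is `1 - alpha`).
#' @return Named numeric `c(lower, upper)` with attributes `z0` and `accel`.
#' @export
bca_interval <- function(point, replicates, jackknife = NULL, alpha = 0.05) {
  replicates <- replicates[is.finite(replicates)]
  B <- length(replicates)
  if (B < 1) abort("no finite bootstrap replicates")
  if (alpha <= 0 || alpha >= 0.5) abort("`alpha` must be in (0, 0.5)")
  if (all(replicates == replicates[1])) {
    out <- c(lower = replicates[1], upper = replicates[1])
    attr(out, "z0") <- 0; attr(out, "accel") <- 0
    return(out)
  }
  prop <- (sum(replicates < point) + 0.5 * sum(replicates == point)) / B
  if (prop <= 0 || prop >= 1) {
    warn("all bootstrap replicates fall on one side of the point estimate; z0 clamped")
    prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))
  }
  z0 <- qnorm(prop)
  a <- 0
  if (!is.null(jackknife) && length(jackknife) > 1) {
    dif <- mean(jackknife) - jackknife
    denom <- sum(dif^2)^1.5
    if (denom > 0) a <- sum(dif^3) / (6 * denom)
  }
  zq <- qnorm(c(alpha / 2, 1 - alpha / 2))
  adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  out <- quantile(replicates, probs = adj, names = FALSE, type = 7)
  out <- c(lower = out[1], upper = out[2])
  attr(out, "z0") <- z0
  attr(out, "accel") <- a
  out
}

#' Significance call from a confidence interval
#'
#' Declares an effect significant when the closed interval excludes the null
#' value; an interval with the null on its boundary is not significant.
#'
#' @param lower,upper Interval endpoints.
#' @param null Null value (default 0).
#' @return Logical.
#' @export
significance_call <- function(lower, upper, null = 0) {
  stopifnot(lower <= upper)
  lower > null || upper < null
}

boot_quantities <- function(fit) {
  eff <- fit$effects
  setNames(eff$estimate, eff$term)
}

#' BCa bootstrap inference for the mediation effects
#'
#' Resamples subjects with replacement (stratified by case/control status in
#' binary case-control mode, preserving the class sizes), reruns the full
#' two-stage pipeline — censoring curve, AFT fit, residual distribution,
#' pseudo-likelihood fit, frequencies, effects — on every replicate, and
#' forms BCa intervals for each per-category and overall effect.
#'
#' @param fit A [mediate_censored()] result.
#' @param B Number of bootstrap replicates (default 200; values below 50 are
#'   rejected, below 999 a note is recorded).
#' @param seed Integer seed; the per-replicate resampling is a fixed seeded
#'   sequence, so results are bit-reproducible.
#' @param alpha Two-sided miscoverage level.
#' @param stratify Stratify resampling by outcome class (default: `TRUE` for
#'   binary case-control fits, i.e. when a prevalence was supplied).
#' @param accel `"jackknife"` computes the acceleration term from leave-one-
#'   out refits (O(n) additional fits); `"none"` sets `a = 0` (bias-corrected
#'   percentile interval), a documented faster variant for large samples.
#' @param warm_start Start each replicate's stage-2 optimizer at the full-
#'   sample estimates (default `TRUE`).
#' @return An object of class `mediation_boot`: a tibble with one row per
#'   quantity (`term`, `estimate`, `lower`, `upper`, `z0`, `accel`,
#'   `significant`), plus the replicate matrix, the failed-replicate count,
#'   `B`, and `seed` as attributes.
#' @export
bootstrap_effects <- function(fit, B = 200, seed = 1, alpha = 0.05,
                              stratify = NULL, accel = c("jackknife", "none"),
                              warm_start = TRUE) {
  stopifnot(inherits(fit, "censored_mediation"))
  accel <- match.arg(accel)
  if (B < 50) abort("B must be at least 50 for interval construction")
  if (B < 999) warn("B < 999; intervals may be unstable", class = "cenmediate_small_B")
  data <- fit$data
  n <- nrow(data)
  stratify <- stratify %||% (!is.null(fit$prevalence))
  strata <- if (stratify) split(seq_len(n), data$.outcome) else list(seq_len(n))

  point <- boot_quantities(fit)
  init <- if (warm_start) {
    phi <- unname(fit$outcome$coefficients)
    if (!is.null(fit$outcome$sigma)) c(phi, log(fit$outcome$sigma)) else phi
  } else NULL

  one_fit <- function(idx) {
    d <- data[idx, , drop = FALSE]
    attr(d, "family") <- attr(data, "family")
    attr(d, "covariates") <- attr(data, "covariates")
    class(d) <- class(data)
    design <- encode_dummies(d, reference = fit$design$reference,
                             order = fit$design$labels[-1])
    freqs <- if (attr(fit$frequencies, "source") == "external")
      fit$frequencies else category_frequencies(d, design)
    aft <- fit_aft(d, design)
    outcome <- fit_outcome(d, design, aft, method = fit$outcome$method,
                           conditional = fit$outcome$conditional, init = init)
    overall_effects(aft, outcome, freqs, z_star = fit$z_star)
  }

  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, B)
  reps <- matrix(NA_real_, nrow = B, ncol = length(point),
                 dimnames = list(NULL, names(point)))
  failed <- 0L
  for (r in seq_len(B)) {
    set.seed(rep_seeds[r])
    idx <- unlist(lapply(strata, function(s) sample(s, length(s), replace = TRUE)),
                  use.names = FALSE)
    est <- tryCatch(boot_quantities(list(effects = one_fit(idx))),
                    error = function(e) NULL)
    if (is.null(est)) failed <- failed + 1L else reps[r, ] <- est[names(point)]
  }
  if (failed > 0.1 * B) {
    abort(sprintf("%d of %d bootstrap replicates failed to fit", failed, B))
  }
  reps <- reps[stats::complete.cases(reps[, "IE", drop = FALSE]), , drop = FALSE]

  jack <- NULL
  if (accel == "jackknife") {
    jack <- matrix(NA_real_, nrow = n, ncol = length(point),
                   dimnames = list(NULL, names(point)))
    for (i in seq_len(n)) {
      est <- tryCatch(boot_quantities(list(effects = one_fit(setdiff(seq_len(n), i)))),
                      error = function(e) rep(NA_real_, length(point)))
      jack[i, ] <- est[names(point)]
    }
  }

  rows <- purrr::map_dfr(names(point), function(tm) {
    rv <- reps[, tm]
    rv <- rv[is.finite(rv)]
    jk <- if (!is.null(jack)) jack[is.finite(jack[, tm]), tm] else NULL
    if (!length(rv) || !is.finite(point[[tm]])) {
      return(tibble::tibble(term = tm, estimate = point[[tm]],
                            lower = NA_real_, upper = NA_real_,
                            z0 = NA_real_, accel = NA_real_,
                            significant = NA))
    }
    ci <- bca_interval(point[[tm]], rv, jackknife = jk, alpha = alpha)
    tibble::tibble(term = tm, estimate = point[[tm]],
                   lower = ci[["lower"]], upper = ci[["upper"]],
                   z0 = attr(ci, "z0"), accel = attr(ci, "accel"),
                   significant = significance_call(ci[["lower"]], ci[["upper"]]))
  })

  structure(rows,
            class = c("mediation_boot", class(tibble::tibble())),
            replicates = reps, B = B, seed = seed, alpha = alpha,
            failed = failed, stratified = stratify, accel = accel)
}

#' @export
print.mediation_boot <- function(x, ...) {
  cat(sprintf("<mediation_boot> B = %d (%d failed), %s, %.0f%% BCa intervals\n",
              attr(x, "B"), attr(x, "failed"),
              if (attr(x, "stratified")) "stratified" else "unstratified",
              100 * (1 - attr(x, "alpha"))))
  NextMethod()
}

#' @rdname bootstrap_effects
#' @param x A `mediation_boot` object.
#' @param ... Unused.
#' @export
glance.mediation_boot <- function(x, ...) {
  tibble::tibble(B = attr(x, "B"), failed = attr(x, "failed"),
                 alpha = attr(x, "alpha"),
                 stratified = attr(x, "stratified"),
                 accel = attr(x, "accel"), seed = attr(x, "seed"))
}
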