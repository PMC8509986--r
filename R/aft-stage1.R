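# Weighted product-limit (Kaplan-Meier) survival at the distinct observation
# times. Equivalent to survival::survfit's weighted KM (cross-checked in the
# test suite); inlined because the bootstrap re-estimates two curves per
# replicate and the formula interface overhead dominates there.
km_jumps <- function(time, status, weights = NULL) {
  n <- length(time)
  if (is.null(weights)) weights <- rep(1, n)
  o <- order(time)
  tt <- time[o]; ss <- status[o]; ww <- weights[o]
  new <- c(TRUE, tt[-1] != tt[-n])
  starts <- which(new)
  ends <- c(starts[-1] - 1L, n)
  cs_ev <- cumsum(ww * ss)
  d <- diff(c(0, cs_ev[ends]))                   # weighted events per time
  at_risk <- rev(cumsum(rev(ww)))[starts]        # weighted risk set
  surv <- cumprod(1 - d / at_risk)
  list(time = tt[starts], surv = surv, events = d)
}

#' Kaplan-Meier estimate of the censoring survival function
#'
#' Estimates `G(t) = Pr(C > t)` by the product-limit estimator with the roles
#' of event and censoring reversed (the censoring time is the "event"). The
#' returned object evaluates at the left limit `G(t-)`, the usual
#' inverse-probability-of-censoring-weighting convention, so events at the
#' largest observed time keep a positive weight.
#'
#' @param data A [mediation_data()] tibble.
#' @param eval `"left-limit"` (default) evaluates `G(t-)`; `"right"`
#'   evaluates the right-continuous `G(t)`, which zeroes the weight of an
#'   event at the largest observed time when that time also censors.
#' @return An object of class `censoring_km`: a list with `fn` (the step
#'   function under the chosen evaluation convention), and a `curve` tibble
#'   (`time`, `surv`).
#' @examples
#' d <- data.frame(y = rnorm(3), m = c(1, 2, 3), d = c(1, 0, 1), g = c(0, 1, 0))
#' G <- censoring_km(mediation_data(d, "y", "m", "d", "g"))
#' G$fn(c(1.5, 2.5)) # 1 up to and including 2, then 1/2
#' @export
censoring_km <- function(data, eval = c("left-limit", "right")) {
  eval <- match.arg(eval)
  stopifnot(inherits(data, "mediation_data"))
  if (all(data$.event == 1)) {
    fn <- function(t) rep(1, length(t))
    curve <- tibble::tibble(time = numeric(0), surv = numeric(0))
  } else {
    km <- km_jumps(data$.time, 1 - data$.event)
    # stepfun(..., right = TRUE) evaluates the left limit G(t-)
    fn <- stats::stepfun(km$time, c(1, km$surv), right = eval == "left-limit")
    curve <- tibble::tibble(time = km$time, surv = km$surv)
  }
  structure(list(fn = fn, curve = curve, eval = eval), class = "censoring_km")
}

#' @export
print.censoring_km <- function(x, ...) {
  cat(sprintf("<censoring_km> %d distinct times\n", nrow(x$curve)))
  invisible(x)
}

#' Stage-1 semiparametric AFT fit for a censored mediator
#'
#' Fits `log t = A' theta + eps` by the closed-form inverse-probability-of-
#' censoring weighted least squares estimator
#' `theta = [sum d_i w_i A_i A_i' / G(m_i-)]^{-1} [sum d_i w_i A_i log(m_i) / G(m_i-)]`,
#' where `G` is the Kaplan-Meier censoring survival function, `d_i` the event
#' indicator, and `w_i` optional sampling weights (case-control designs).
#' The AFT error distribution is then estimated from the residuals
#' `e_i = log(m_i) - A_i' theta` by the Kaplan-Meier estimator
#' (see [residual_distribution()]).
#'
#' @param data A [mediation_data()] tibble.
#' @param design A [encode_dummies()] result.
#' @param G Optional precomputed [censoring_km()] object.
#' @param weighted_residual_km Apply the sampling weights in the residual
#'   Kaplan-Meier estimate as well (default `TRUE`, for consistency with the
#'   weighted least squares stage).
#' @param g_floor Lower guard on `G(m-)` in the weights (default `1e-8`).
#' @return An object of class `aft_fit`: coefficients `theta`, residuals,
#'   the residual distribution (`support`, `mass`), the truncation point
#'   `tau` (largest event residual), and the censoring curve.
#' @export
fit_aft <- function(data, design, G = NULL, weighted_residual_km = TRUE,
                    g_floor = 1e-8) {
  stopifnot(inherits(data, "mediation_data"), inherits(design, "dummy_design"))
  if (is.null(G)) G <- censoring_km(data)
  A <- design$design
  gm <- pmax(G$fn(data$.time), g_floor)
  if (any(G$fn(data$.time) < g_floor)) {
    warn("some censoring-survival weights fell below the guard and were floored")
  }
  v <- data$.event * data$.weight / gm
  fit <- lm.wfit(x = A, y = log(data$.time), w = v)
  if (fit$rank < ncol(A)) {
    bad <- colnames(A)[is.na(fit$coefficients)]
    abort(paste0("stage-1 design is rank deficient; inestimable column(s): ",
                 paste(bad, collapse = ", "),
                 " (a non-reference category may have no observed events)"))
  }
  theta <- fit$coefficients
  resid <- log(data$.time) - drop(A %*% theta)
  rd <- residual_distribution(resid, data$.event,
                              weights = if (weighted_residual_km) data$.weight else NULL)

  structure(
    list(coefficients = theta, residuals = resid, event = data$.event,
         resdist = rd, tau = max(rd$support), G = G, design = design,
         ipcw = v, n = nrow(data)),
    class = "aft_fit")
}

#' Kaplan-Meier estimate of the AFT residual distribution
#'
#' Applies the product-limit estimator to the residuals `(e_i, delta_i)` and
#' returns its jumps: support points are the distinct event residuals and the
#' masses are the Kaplan-Meier increments. Any mass the estimator leaves
#' beyond the largest event residual (when the largest residual is censored)
#' is redistributed by renormalizing the masses to sum to one over the
#' support truncated at `tau`, so the estimate is a proper distribution.
#'
#' @param residuals Numeric vector of residuals on the log-time scale.
#' @param event 0/1 event indicators.
#' @param weights Optional case weights for the risk/event counts.
#' @return A tibble with columns `support` (ordered event residuals) and
#'   `mass` (positive, summing to 1).
#' @export
residual_distribution <- function(residuals, event, weights = NULL) {
  stopifnot(length(residuals) == length(event), any(event == 1))
  km <- km_jumps(residuals, event, weights)
  jump <- -diff(c(1, km$surv))
  keep <- km$events > 0 & jump > 0
  support <- km$time[keep]
  mass <- jump[keep]
  mass <- mass / sum(mass)
  tibble::tibble(support = support, mass = mass)
}

#' @export
print.aft_fit <- function(x, ...) {
  cat(sprintf("<aft_fit> n = %d (%d events), %d residual support points, tau = %.4g\n",
              x$n, sum(x$event), nrow(x$resdist), x$tau))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @rdname fit_aft
#' @param x An `aft_fit` object.
#' @param ... Unused.
#' @export
tidy.aft_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname fit_aft
#' @export
glance.aft_fit <- function(x, ...) {
  tibble::tibble(n = x$n, events = sum(x$event),
                 censoring_rate = mean(x$event == 0),
                 support_size = nrow(x$resdist), tau = x$tau)
}
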