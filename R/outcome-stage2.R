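#' Inverse-prevalence sampling weights for case-control data
#'
#' Attaches the standard case-control sampling weights: cases receive
#' `pi / p_case` and controls `(1 - pi) / (1 - p_case)`, where `pi` is the
#' assumed population disease prevalence and `p_case` the sample case
#' fraction. When the sample case fraction equals the prevalence all weights
#' are 1.
#'
#' @param data A binary-family [mediation_data()] tibble.
#' @param prevalence Assumed population disease prevalence, in (0, 1).
#' @return The dataset with its `.weight` column replaced by the sampling
#'   weights; the prevalence is recorded as an attribute.
#' @examples
#' d <- data.frame(y = rep(c(1, 0), each = 5), m = rexp(10) + 1,
#'                 d = rep(1, 10), g = rep(0:1, 5))
#' md <- mediation_data(d, "y", "m", "d", "g", family = "binary")
#' sampling_weights(md, prevalence = 0.1)$.weight[c(1, 6)] # 0.2, 1.8
#' @export
sampling_weights <- function(data, prevalence) {
  stopifnot(inherits(data, "mediation_data"))
  if (outcome_family(data) != "binary") {
    abort("sampling weights require a binary outcome family")
  }
  if (!is.numeric(prevalence) || length(prevalence) != 1 ||
      prevalence <= 0 || prevalence >= 1) {
    abort("`prevalence` must be a single probability in (0, 1)")
  }
  p_case <- mean(data$.outcome == 1)
  if (p_case == 0 || p_case == 1) abort("both cases and controls must be present")
  w <- ifelse(data$.outcome == 1, prevalence / p_case,
              (1 - prevalence) / (1 - p_case))
  data$.weight <- w
  attr(data, "prevalence") <- prevalence
  data
}

#' Conditional outcome mean given the mediator and exposure
#'
#' Evaluates the outcome model at a given log-scale mediator value: the
#' linear predictor `b0 + b * log_mediator + sum_j c_j x_j + gamma' z` for
#' the continuous family, or its inverse logit for the binary family. The
#' mediator enters on the log (AFT linear-predictor) scale.
#'
#' @param phi Coefficient vector `(b0, b, c_1..c_{k-1}, gamma)`.
#' @param log_mediator Log-scale mediator value(s).
#' @param dummy_row Exposure indicator vector (length k-1).
#' @param z Covariate vector (may be empty).
#' @param family `"continuous"` or `"binary"`.
#' @return Conditional mean (or event probability) of the outcome.
#' @export
conditional_outcome_mean <- function(phi, log_mediator, dummy_row = numeric(0),
                                     z = numeric(0),
                                     family = c("continuous", "binary")) {
  family <- match.arg(family)
  need <- 2 + length(dummy_row) + length(z)
  if (length(phi) != need) {
    abort(sprintf("`phi` has length %d but %d coefficients are required",
                  length(phi), need))
  }
  lp <- phi[1] + phi[2] * log_mediator +
    sum(phi[seq_along(dummy_row) + 2] * dummy_row) +
    (if (length(z)) sum(phi[2 + length(dummy_row) + seq_along(z)] * z) else 0)
  if (family == "binary") plogis(lp) else lp
}

# Precompute the fixed structures the C++ objective needs.
pl_inputs <- function(data, design, aft) {
  xout <- cbind(design$indicators, covariate_matrix(data))
  support <- aft$resdist$support
  e <- aft$residuals
  # first support point strictly greater than the censoring residual
  cstart <- findInterval(e, support) + 1L
  cstart[data$.event == 1] <- 0L
  tailmass <- rev(cumsum(rev(aft$resdist$mass)))
  q <- length(support)
  cnorm <- ifelse(cstart >= 1L & cstart <= q, tailmass[pmin(pmax(cstart, 1L), q)], 1)
  list(y = data$.outcome, delta = data$.event, w = data$.weight,
       logm = log(data$.time), atheta = drop(design$design %*% aft$coefficients),
       xout = xout, support = support, mass = aft$resdist$mass,
       cstart = cstart, cnorm = as.numeric(cnorm),
       binary = outcome_family(data) == "binary")
}

#' Log-pseudo-likelihood of the outcome model
#'
#' Evaluates `(1/n) sum_i w_i [ delta_i log Pr(y_i | log m_i, A_i) +
#' (1 - delta_i) log sum_{e_s > e_i} q_s Pr(y_i | e_s + A_i'theta, A_i) ]`,
#' where the inner sum runs over the Kaplan-Meier residual support beyond
#' subject i's censoring residual and `q_s` are the (by default
#' conditionally renormalized) residual masses. Censored subjects whose
#' residual exceeds the whole support contribute through the largest support
#' point.
#'
#' @param phi Parameter vector `(b0, b, c_1..c_{k-1}, gamma[, log_sigma])`;
#'   `log_sigma` only for the continuous family.
#' @param data,design,aft The dataset, dummy design, and stage-1 [fit_aft()]
#'   result.
#' @param conditional Renormalize the residual masses beyond the censoring
#'   residual to a conditional distribution (default `TRUE`); `FALSE` uses
#'   the literal unnormalized tail sum.
#' @return The scalar log-pseudo-likelihood (`-Inf` for invalid `phi`).
#' @export
pseudo_log_likelihood <- function(phi, data, design, aft, conditional = TRUE) {
  pin <- pl_inputs(data, design, aft)
  res <- pl_eval_cpp(phi, pin$y, pin$delta, pin$w, pin$logm, pin$atheta,
                     pin$xout, pin$support, pin$mass, pin$cstart, pin$cnorm,
                     pin$binary, conditional, 0L)
  res$value
}

stage2_init <- function(data, design, binary) {
  xout <- cbind(design$indicators, covariate_matrix(data))
  X <- cbind(1, log(data$.time), xout)
  keep <- data$.event == 1
  w <- data$.weight
  init <- tryCatch({
    if (binary) {
      f <- suppressWarnings(
        glm.fit(X[keep, , drop = FALSE], data$.outcome[keep],
                weights = w[keep], family = binomial()))
      cf <- f$coefficients
      if (anyNA(cf)) stop("singular")
      cf
    } else {
      f <- lm.wfit(X[keep, , drop = FALSE], data$.outcome[keep], w[keep])
      cf <- f$coefficients
      if (anyNA(cf)) stop("singular")
      r <- data$.outcome[keep] - drop(X[keep, , drop = FALSE] %*% cf)
      c(cf, log(max(sqrt(sum(w[keep] * r^2) / sum(w[keep])), 1e-3)))
    }
  }, error = function(e) NULL)
  if (is.null(init)) init <- rep(0, ncol(X) + !binary)
  unname(init)
}

#' Stage-2 pseudo-likelihood fit of the outcome model
#'
#' Maximizes the log-pseudo-likelihood of [pseudo_log_likelihood()] over the
#' outcome-model coefficients `phi = (b0, b, c_1..c_{k-1}, gamma)` (plus
#' `log sigma` for the continuous family). The default optimizer is a
#' trust-region Newton method ([stats::nlminb]) driven by the analytic
#' gradient and Hessian of the pseudo-likelihood; BFGS (analytic gradient)
#' and Nelder-Mead (derivative-free) are available and reach the same
#' optimum. Initial values come from the complete-case weighted regression
#' of the outcome on `(log m, X, z)`.
#'
#' @inheritParams pseudo_log_likelihood
#' @param method `"newton"` (default), `"bfgs"`, or `"nelder-mead"`.
#' @param init Optional starting values (same layout as `phi`).
#' @param conditional See [pseudo_log_likelihood()].
#' @param control Optimizer control list, passed to [stats::nlminb()] or
#'   [stats::optim()].
#' @return An object of class `outcome_fit` with elements `coefficients`
#'   (named), `sigma` (continuous family), `logLik` (attained
#'   pseudo-likelihood), `converged`, `iterations`, and `family`.
#' @export
fit_outcome <- function(data, design, aft,
                        method = c("newton", "bfgs", "nelder-mead"),
                        init = NULL, conditional = TRUE, control = list()) {
  method <- match.arg(method)
  stopifnot(inherits(aft, "aft_fit"))
  pin <- pl_inputs(data, design, aft)
  binary <- pin$binary
  if (is.null(init)) init <- stage2_init(data, design, binary)

  evaluate <- function(phi, want) {
    pl_eval_cpp(phi, pin$y, pin$delta, pin$w, pin$logm, pin$atheta,
                pin$xout, pin$support, pin$mass, pin$cstart, pin$cnorm,
                binary, conditional, want)
  }
  fn <- function(phi) -evaluate(phi, 0L)$value

  if (!is.finite(fn(init))) init <- rep(0, length(init))
  if (!is.finite(fn(init))) abort("pseudo-likelihood is not finite at the starting values")

  if (method == "newton") {
    cache <- new.env(parent = emptyenv())
    full <- function(phi) {
      key <- paste(phi, collapse = " ")
      if (!identical(cache$key, key)) {
        cache$key <- key
        cache$res <- evaluate(phi, 2L)
      }
      cache$res
    }
    ctl <- utils::modifyList(list(rel.tol = 1e-10, iter.max = 150,
                                  eval.max = 300), control)
    opt <- stats::nlminb(init,
                         objective = function(phi) -full(phi)$value,
                         gradient = function(phi) -full(phi)$grad,
                         hessian = function(phi) {
                           h <- full(phi)$hess
                           if (is.null(h)) diag(length(phi)) else -h
                         },
                         control = ctl)
    par <- opt$par
    value <- opt$objective
    converged <- opt$convergence == 0
    iters <- opt$iterations
  } else if (method == "bfgs") {
    gr <- function(phi) -evaluate(phi, 1L)$grad
    ctl <- utils::modifyList(list(maxit = 500, reltol = 1e-9), control)
    opt <- optim(init, fn, gr, method = "BFGS", control = ctl)
    par <- opt$par; value <- opt$value
    converged <- opt$convergence == 0
    iters <- opt$counts[["function"]]
  } else {
    ctl <- utils::modifyList(list(maxit = 2000 * length(init), reltol = 1e-10),
                             control)
    opt <- optim(init, fn, method = "Nelder-Mead", control = ctl)
    par <- opt$par; value <- opt$value
    converged <- opt$convergence == 0
    iters <- opt$counts[["function"]]
  }
  if (!converged) warn("stage-2 optimizer did not converge; parameters returned as-is")

  others <- setdiff(design$labels, design$reference)
  nm <- c("(Intercept)", "log_mediator", paste0("x_", others), design$covariates)
  phi <- par
  sigma <- NULL
  if (!binary) {
    sigma <- exp(phi[length(phi)])
    phi <- phi[-length(phi)]
  }
  names(phi) <- nm

  structure(
    list(coefficients = phi, sigma = sigma,
         family = if (binary) "binary" else "continuous",
         logLik = -value, converged = converged,
         iterations = iters, method = method,
         conditional = conditional, n = nrow(data)),
    class = "outcome_fit")
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat(sprintf("<outcome_fit> %s outcome, pseudo-logLik = %.5f (%sconverged)\n",
              x$family, x$logLik, if (x$converged) "" else "NOT "))
  print(round(x$coefficients, 4))
  if (!is.null(x$sigma)) cat(sprintf("sigma = %.4f\n", x$sigma))
  invisible(x)
}

#' @rdname fit_outcome
#' @param x An `outcome_fit` object.
#' @param ... Unused.
#' @export
tidy.outcome_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname fit_outcome
#' @export
glance.outcome_fit <- function(x, ...) {
  tibble::tibble(family = x$family, logLik = x$logLik,
                 sigma = x$sigma %||% NA_real_,
                 converged = x$converged, iterations = x$iterations, n = x$n)
}
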