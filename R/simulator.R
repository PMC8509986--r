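#' Define a simulation scenario
#'
#' Collects the generative-model settings for the simulation engine: an
#' additive genetic exposure in Hardy-Weinberg proportion at a given minor
#' allele frequency, a log-normal-error AFT mediator
#' `log t = a0 + a x + gamma_tilde z + eps`, independent uniform censoring
#' calibrated to a target censoring percentage, and a linear or logistic
#' outcome on `(log t, x, z)` with per-allele direct effect `c_tilde`
#' (so the dummy coefficients are `c_tilde` and `2 c_tilde`).
#'
#' @param family `"continuous"` or `"binary"`.
#' @param maf Minor allele frequency.
#' @param a0,a AFT intercept and per-allele mediator-path coefficient.
#' @param b0,b Outcome intercept and mediator coefficient (`b0` controls the
#'   disease prevalence in the binary family).
#' @param c_tilde Per-allele direct-path coefficient.
#' @param cp_target Target censoring percentage (population scale).
#' @param sigma_y Residual SD of the continuous outcome (default 1).
#' @param n Sample size (continuous / cohort designs).
#' @param n_case,n_control Case-control sample sizes (binary designs).
#' @param covariate Include a single `z ~ Normal(0, 0.5^2)` covariate in both
#'   models (default `FALSE`).
#' @param gamma,gamma_tilde Covariate coefficients of the outcome and AFT
#'   models (used when `covariate = TRUE`).
#' @return A `simulation_scenario` list.
#' @export
simulation_scenario <- function(family = c("binary", "continuous"),
                                maf = 0.3, a0 = 6, a = 0.4,
                                b0 = if (family == "binary") -3.7 else 1,
                                b = 0.4, c_tilde = 0.5, cp_target = 0.2,
                                sigma_y = 1, n = 1000,
                                n_case = 500, n_control = 500,
                                covariate = FALSE, gamma = 0.4,
                                gamma_tilde = 0.4) {
  family <- match.arg(family)
  stopifnot(maf > 0, maf < 1, cp_target > 0, cp_target < 1, sigma_y > 0)
  structure(
    list(family = family, maf = maf, a0 = a0, a = a, b0 = b0, b = b,
         c_tilde = c_tilde, cp_target = cp_target, sigma_y = sigma_y,
         n = n, n_case = n_case, n_control = n_control,
         covariate = covariate, gamma = gamma, gamma_tilde = gamma_tilde),
    class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf("<simulation_scenario> %s outcome, MAF %.2f, a = %.2f, b = %.2f, target CP %.0f%%\n",
              x$family, x$maf, x$a, x$b, 100 * x$cp_target))
  invisible(x)
}

#' Theoretical effects implied by a scenario
#'
#' Convenience wrapper mapping a scenario's per-allele coefficients onto the
#' dummy coding (`a_1 = a`, `a_2 = 2a`, `c_1 = c_tilde`, `c_2 = 2 c_tilde`)
#' and calling [theoretical_effects()] with its Hardy-Weinberg frequencies.
#'
#' @param scenario A [simulation_scenario()].
#' @param ... Passed to [theoretical_effects()].
#' @return An `effect_estimates` tibble.
#' @export
scenario_theoretical_effects <- function(scenario, ...) {
  theoretical_effects(
    a0 = scenario$a0, a = c(scenario$a, 2 * scenario$a),
    b0 = scenario$b0, b = scenario$b,
    c_tilde = c(scenario$c_tilde, 2 * scenario$c_tilde),
    freqs = hwe_frequencies(scenario$maf), family = scenario$family, ...)
}

# Draw latent mediator times (no censoring) for censoring calibration.
draw_latent_times <- function(scenario, n) {
  p <- hwe_frequencies(scenario$maf)$frequency
  x <- sample(0:2, n, replace = TRUE, prob = p)
  z <- if (scenario$covariate) rnorm(n, 0, 0.5) else rep(0, n)
  logt <- scenario$a0 + scenario$a * x + scenario$gamma_tilde * z * scenario$covariate +
    rnorm(n)
  list(x = x, z = z, logt = logt, t = exp(logt))
}

#' Calibrate the uniform censoring upper bound to a target rate
#'
#' Finds `U` such that censoring times drawn uniformly on the log-time
#' scale, `log c ~ Uniform(0, U)` independent of everything else, censor the
#' target fraction of mediator times. Censoring is placed on the log scale —
#' the scale on which the AFT model is linear — because a bounded uniform
#' law there covers the whole (light-tailed) support of `log t`, so the
#' positivity condition `G(t-) > 0` behind the inverse-probability-of-
#' censoring weights holds at any censoring rate; a uniform law on the raw
#' time scale cannot reach substantial censoring rates without truncating
#' the log-normal mediator's support. The rate
#' `Pr(log t > log c) = E[min(max(log t, 0), U)] / U` is solved for `U` by
#' root finding on a fixed Monte-Carlo draw of latent times (deterministic
#' given the seed).
#'
#' @param scenario A [simulation_scenario()].
#' @param target Target censoring proportion (default: scenario's
#'   `cp_target`).
#' @param mc_draws Monte-Carlo draws used for the expectation.
#' @param seed RNG seed.
#' @return Named numeric `c(L = 0, U = ...)`, bounds on the log-time scale.
#' @export
calibrate_censoring <- function(scenario, target = scenario$cp_target,
                                mc_draws = 2e5, seed = 1) {
  stopifnot(target > 0, target < 1)
  set.seed(as.integer(seed))
  lt <- draw_latent_times(scenario, mc_draws)$logt
  lt0 <- pmax(lt, 0)
  g <- function(U) mean(pmin(lt0, U)) / U - target
  lo <- max(min(lt0), 1e-6); hi <- max(lt0) / target
  while (g(hi) > 0) hi <- hi * 4
  U <- stats::uniroot(g, c(lo, hi), tol = 1e-10 * hi)$root
  c(L = 0, U = U)
}

#' Simulate a population under a scenario
#'
#' Generates `n` subjects from the scenario's generative model: Hardy-
#' Weinberg genotypes, AFT mediator with standard normal errors, independent
#' uniform censoring on the log-time scale (see [calibrate_censoring()]),
#' and the linear or logistic outcome on the log-scale mediator. Latent (uncensored) times are retained in `.latent_t`
#' for oracle checks.
#'
#' @param scenario A [simulation_scenario()].
#' @param n Number of subjects.
#' @param seed RNG seed (optional; the caller may manage the RNG stream).
#' @param censor_upper Upper bound of the uniform censoring law; default:
#'   calibrated via [calibrate_censoring()].
#' @return A [mediation_data()] tibble with extra columns `.latent_t` and,
#'   for the binary family, the realized population prevalence as attribute
#'   `prevalence_realized`.
#' @export
simulate_population <- function(scenario, n, seed = NULL, censor_upper = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(censor_upper)) {
    censor_upper <- calibrate_censoring(scenario,
                                        seed = if (is.null(seed)) 1 else seed)[["U"]]
    if (!is.null(seed)) set.seed(as.integer(seed) + 1L)
  }
  lat <- draw_latent_times(scenario, n)
  cen <- exp(runif(n, 0, censor_upper))  # log c ~ Uniform(0, U)
  m <- pmin(lat$t, cen)
  delta <- as.integer(lat$t <= cen)
  lp <- scenario$b0 + scenario$b * lat$logt + scenario$c_tilde * lat$x +
    scenario$gamma * lat$z * scenario$covariate
  y <- if (scenario$family == "binary") rbinom(n, 1, plogis(lp)) else
    lp + rnorm(n, 0, scenario$sigma_y)

  df <- data.frame(y = y, m = m, delta = delta,
                   genotype = c("rr", "Rr", "RR")[lat$x + 1])
  cov_names <- NULL
  if (scenario$covariate) { df$z <- lat$z; cov_names <- "z" }
  out <- mediation_data(df, "y", "m", "delta", "genotype",
                        covariates = cov_names, family = scenario$family)
  out$.exposure <- factor(as.character(out$.exposure),
                          levels = c("rr", "Rr", "RR")[sort(unique(lat$x)) + 1])
  out$.latent_t <- lat$t
  attr(out, "censor_upper") <- censor_upper
  if (scenario$family == "binary") {
    attr(out, "prevalence_realized") <- mean(y)
  }
  out
}

#' Case-control sample from a simulated population
#'
#' Draws the requested numbers of cases and controls uniformly without
#' replacement within outcome class and attaches inverse-prevalence
#' sampling weights via [sampling_weights()].
#'
#' @param population A binary-family population from [simulate_population()].
#' @param n_case,n_control Numbers of cases and controls to draw.
#' @param seed RNG seed (optional).
#' @param prevalence Population prevalence used for the weights; default:
#'   the realized prevalence of the population.
#' @return A [mediation_data()] tibble with sampling weights attached.
#' @export
sample_case_control <- function(population, n_case, n_control, seed = NULL,
                                prevalence = NULL) {
  stopifnot(inherits(population, "mediation_data"),
            outcome_family(population) == "binary")
  if (n_case < 1 || n_control < 1) abort("n_case and n_control must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  cases <- which(population$.outcome == 1)
  controls <- which(population$.outcome == 0)
  if (length(cases) < n_case || length(controls) < n_control) {
    abort("population contains too few cases or controls for the requested sample")
  }
  idx <- c(sample(cases, n_case), sample(controls, n_control))
  out <- population[idx, , drop = FALSE]
  attr(out, "family") <- "binary"
  attr(out, "covariates") <- covariate_names(population)
  class(out) <- class(population)
  prevalence <- prevalence %||% attr(population, "prevalence_realized")
  sampling_weights(out, prevalence)
}

#' Simulate one analysis-ready dataset
#'
#' Generates a single replicate under a scenario: for the continuous family,
#' a cohort of `scenario$n` subjects; for the binary family, a population
#' pool (sized so the requested case and control counts are comfortably
#' available) followed by a case-control draw with sampling weights.
#'
#' @param scenario A [simulation_scenario()].
#' @param seed RNG seed.
#' @param censor_upper Optional precomputed censoring bound (saves the
#'   calibration step when simulating many replicates).
#' @return A [mediation_data()] tibble.
#' @export
simulate_mediation <- function(scenario, seed = NULL, censor_upper = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(censor_upper)) {
    censor_upper <- calibrate_censoring(scenario,
                                        seed = if (is.null(seed)) 1 else seed)[["U"]]
    if (!is.null(seed)) set.seed(as.integer(seed) + 1L)
  }
  if (scenario$family == "continuous") {
    return(simulate_population(scenario, scenario$n, censor_upper = censor_upper))
  }
  prev_nominal <- effect_value(scenario_prevalence(scenario), "prevalence")
  need <- max(scenario$n_case / prev_nominal,
              scenario$n_control / (1 - prev_nominal))
  pop <- simulate_population(scenario, n = ceiling(1.5 * need),
                             censor_upper = censor_upper)
  tries <- 0
  while ((sum(pop$.outcome == 1) < scenario$n_case ||
          sum(pop$.outcome == 0) < scenario$n_control) && tries < 5) {
    extra <- simulate_population(scenario, n = ceiling(need),
                                 censor_upper = censor_upper)
    prev_all <- weighted.mean(
      c(attr(pop, "prevalence_realized"), attr(extra, "prevalence_realized")),
      c(nrow(pop), nrow(extra)))
    pop <- dplyr::bind_rows(pop, extra)
    attr(pop, "family") <- "binary"
    attr(pop, "covariates") <- if (scenario$covariate) "z" else character(0)
    attr(pop, "prevalence_realized") <- prev_all
    class(pop) <- c("mediation_data", class(tibble::tibble()))
    tries <- tries + 1
  }
  sample_case_control(pop, scenario$n_case, scenario$n_control)
}

# Theoretical population prevalence of a binary scenario (Gauss-Hermite over
# the AFT error, averaged over genotype frequencies).
scenario_prevalence <- function(scenario, nodes = 40) {
  stopifnot(scenario$family == "binary")
  gh <- pracma::gaussHermite(nodes)
  eps <- sqrt(2) * gh$x; wts <- gh$w / sqrt(pi)
  f <- hwe_frequencies(scenario$maf)$frequency
  prev <- sum(vapply(0:2, function(x)
    f[x + 1] * sum(wts * plogis(scenario$b0 +
      scenario$b * (eps + scenario$a0 + scenario$a * x) +
      scenario$c_tilde * x)), numeric(1)))
  tibble::tibble(term = "prevalence", estimate = prev)
}

#' Replicate-study harness
#'
#' Runs the full two-stage pipeline on many simulated replicates of a
#' scenario and summarizes the path-coefficient and effect estimates
#' (means and standard errors across replicates), optionally with BCa
#' bootstrap intervals and their empirical coverage of the theoretical
#' effects.
#'
#' @param scenario A [simulation_scenario()].
#' @param replicates Number of replicate datasets.
#' @param seed Master seed; per-replicate seeds are drawn once from it, so
#'   reruns are bit-identical.
#' @param with_ci Also compute BCa intervals per replicate (costly).
#' @param B,accel Bootstrap settings when `with_ci = TRUE` (see
#'   [bootstrap_effects()]).
#' @param method Stage-2 optimizer (see [fit_outcome()]).
#' @return An object of class `simulation_study`: list with `results` (one
#'   row per successful replicate), `summary` (mean and SE per quantity,
#'   with theoretical values), `theoretical`, `coverage` (when `with_ci`),
#'   `failed`, and `censor_upper`.
#' @export
run_simulation_study <- function(scenario, replicates = 500, seed = 1,
                                 with_ci = FALSE, B = 200,
                                 accel = "none", method = "newton") {
  stopifnot(replicates >= 2)
  cal <- calibrate_censoring(scenario, seed = seed)
  theo <- scenario_theoretical_effects(scenario)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, replicates)

  one <- function(r) {
    d <- simulate_mediation(scenario, seed = rep_seeds[r],
                            censor_upper = cal[["U"]])
    prevalence <- if (scenario$family == "binary")
      attr(d, "prevalence") else NULL
    fit <- mediate_censored(d, reference = "rr", method = method,
                            prevalence = prevalence)
    cf1 <- fit$aft$coefficients
    cf2 <- fit$outcome$coefficients
    row <- tibble::tibble(
      replicate = r, seed = rep_seeds[r],
      cp = mean(d$.event == 0),
      a0 = cf1[["(Intercept)"]], a1 = cf1[["x_Rr"]], a2 = cf1[["x_RR"]],
      b0 = cf2[["(Intercept)"]], b = cf2[["log_mediator"]],
      c1 = cf2[["x_Rr"]], c2 = cf2[["x_RR"]],
      IE = effect_value(fit$effects, "IE"),
      DE = effect_value(fit$effects, "DE"),
      TE = effect_value(fit$effects, "TE"),
      PM = effect_value(fit$effects, "PM"),
      converged = fit$outcome$converged)
    if (with_ci) {
      bt <- bootstrap_effects(fit, B = B, seed = rep_seeds[r], accel = accel)
      ie_row <- bt[bt$term == "IE", ]
      pm_row <- bt[bt$term == "PM", ]
      row$IE_lower <- ie_row$lower; row$IE_upper <- ie_row$upper
      row$PM_lower <- pm_row$lower; row$PM_upper <- pm_row$upper
    }
    row
  }

  results <- vector("list", replicates)
  failed <- 0L
  for (r in seq_len(replicates)) {
    results[[r]] <- tryCatch(suppressWarnings(one(r)), error = function(e) NULL)
    if (is.null(results[[r]])) failed <- failed + 1L
  }
  results <- dplyr::bind_rows(results)

  stats_cols <- c("a0", "a1", "a2", "b0", "b", "c1", "c2", "IE", "DE", "TE", "PM")
  summary <- tidyr::pivot_longer(results[, stats_cols], dplyr::everything(),
                                 names_to = "quantity", values_to = "value")
  summary <- dplyr::summarise(dplyr::group_by(summary, .data$quantity),
                              mean = mean(.data$value, na.rm = TRUE),
                              se = sd(.data$value, na.rm = TRUE),
                              .groups = "drop")
  summary <- summary[match(stats_cols, summary$quantity), ]

  coverage <- NULL
  if (with_ci) {
    ie_true <- effect_value(theo, "IE")
    pm_true <- effect_value(theo, "PM")
    coverage <- tibble::tibble(
      quantity = c("IE", "PM"),
      truth = c(ie_true, pm_true),
      coverage = c(
        mean(results$IE_lower <= ie_true & ie_true <= results$IE_upper, na.rm = TRUE),
        mean(results$PM_lower <= pm_true & pm_true <= results$PM_upper, na.rm = TRUE)))
  }

  structure(
    list(scenario = scenario, results = results, summary = summary,
         theoretical = theo, coverage = coverage, failed = failed,
         censor_upper = cal[["U"]], seed = seed),
    class = "simulation_study")
}

#' @export
print.simulation_study <- function(x, ...) {
  cat(sprintf("<simulation_study> %d replicates (%d failed), %s outcome\n",
              nrow(x$results), x$failed, x$scenario$family))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  if (!is.null(x$coverage)) {
    cat("\nCI coverage of theoretical values:\n")
    print(as.data.frame(x$coverage), row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @rdname run_simulation_study
#' @param x A `simulation_study` object.
#' @param ... Unused.
#' @export
tidy.simulation_study <- function(x, ...) x$summary

#' @rdname run_simulation_study
#' @export
glance.simulation_study <- function(x, ...) {
  tibble::tibble(replicates = nrow(x$results), failed = x$failed,
                 mean_cp = mean(x$results$cp),
                 theoretical_IE = effect_value(x$theoretical, "IE"),
                 theoretical_PM = effect_value(x$theoretical, "PM"),
                 mean_IE = mean(x$results$IE, na.rm = TRUE),
                 mean_PM = mean(x$results$PM, na.rm = TRUE),
                 seed = x$seed)
}
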