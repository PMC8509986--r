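# Small deterministic datasets used across tests.

toy_continuous <- function(n = 120, seed = 42, cens = TRUE) {
  set.seed(seed)
  x <- sample(0:2, n, replace = TRUE, prob = c(0.49, 0.42, 0.09))
  logt <- 6 + 0.4 * x + rnorm(n)
  cen <- if (cens) exp(runif(n, 0, 16)) else Inf
  m <- pmin(exp(logt), cen)
  delta <- as.integer(exp(logt) <= cen)
  y <- 1 + 0.4 * logt + 0.5 * x + rnorm(n)
  mediation_data(
    data.frame(y = y, m = m, delta = delta,
               g = c("rr", "Rr", "RR")[x + 1]),
    "y", "m", "delta", "g", family = "continuous")
}

toy_binary <- function(n = 160, seed = 24, cens = TRUE) {
  set.seed(seed)
  x <- sample(0:2, n, replace = TRUE, prob = c(0.49, 0.42, 0.09))
  logt <- 6 + 0.4 * x + rnorm(n)
  cen <- if (cens) exp(runif(n, 0, 30)) else Inf
  m <- pmin(exp(logt), cen)
  delta <- as.integer(exp(logt) <= cen)
  y <- rbinom(n, 1, plogis(-3.7 + 0.4 * logt + 0.5 * x))
  mediation_data(
    data.frame(y = y, m = m, delta = delta,
               g = c("rr", "Rr", "RR")[x + 1]),
    "y", "m", "delta", "g", family = "binary")
}

# standard fitted pair on a toy dataset
toy_fits <- function(data) {
  design <- encode_dummies(data, reference = "rr")
  aft <- fit_aft(data, design)
  outcome <- fit_outcome(data, design, aft)
  list(data = data, design = design, aft = aft, outcome = outcome)
}
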