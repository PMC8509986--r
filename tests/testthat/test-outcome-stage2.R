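test_that("inverse-prevalence sampling weights follow the defining arithmetic", {
  d <- mediation_data(
    data.frame(y = rep(c(1, 0), each = 500), m = rexp(1000) + 1,
               delta = 1, g = sample(0:1, 1000, TRUE)),
    "y", "m", "delta", "g", family = "binary")
  w <- sampling_weights(d, prevalence = 0.10)$.weight
  expect_equal(unique(w[d$.outcome == 1]), 0.2)
  expect_equal(unique(w[d$.outcome == 0]), 1.8)

  # representative sample -> all weights 1
  d2 <- mediation_data(
    data.frame(y = rep(c(1, 0), times = c(100, 900)), m = rexp(1000) + 1,
               delta = 1, g = sample(0:1, 1000, TRUE)),
    "y", "m", "delta", "g", family = "binary")
  expect_equal(sampling_weights(d2, prevalence = 0.10)$.weight, rep(1, 1000))

  expect_error(sampling_weights(d, prevalence = 1.2), "probability")
  d_cont <- toy_continuous(30)
  expect_error(sampling_weights(d_cont, 0.1), "binary")
})

test_that("conditional outcome mean evaluates the linear predictor on the log scale", {
  expect_equal(conditional_outcome_mean(c(-5, 0.4), 6, family = "binary"),
               plogis(-2.6))
  # null mediator path: value independent of the mediator
  expect_equal(conditional_outcome_mean(c(1, 0, 0.3), 2, dummy_row = 1,
                                        family = "continuous"),
               conditional_outcome_mean(c(1, 0, 0.3), 9, dummy_row = 1,
                                        family = "continuous"))
  expect_equal(conditional_outcome_mean(c(0, 0), 5, family = "continuous"), 0)
  expect_error(conditional_outcome_mean(c(1, 2, 3), 1, dummy_row = c(1, 0)),
               "coefficients")
})

test_that("with no censoring the pseudo-likelihood is the exact outcome log-likelihood", {
  for (family in c("continuous", "binary")) {
    d <- if (family == "continuous") toy_continuous(90, cens = FALSE) else
      toy_binary(90, seed = 3, cens = FALSE)
    des <- encode_dummies(d, reference = "rr")
    aft <- fit_aft(d, des)
    phi <- if (family == "continuous") c(1, 0.4, 0.5, 1, log(1.1)) else
      c(-3.7, 0.4, 0.5, 1)
    pl <- pseudo_log_likelihood(phi, d, des, aft)
    lp <- phi[1] + phi[2] * log(d$.time) +
      des$indicators %*% phi[3:4]
    direct <- if (family == "continuous")
      mean(dnorm(d$.outcome, lp, 1.1, log = TRUE)) else
      mean(dbinom(d$.outcome, 1, plogis(lp), log = TRUE))
    expect_equal(pl, drop(direct), tolerance = 1e-12)
  }
})

test_that("censored contributions match a brute-force sum over the residual support", {
  for (family in c("continuous", "binary")) {
    d <- if (family == "continuous") toy_continuous(60, seed = 8) else
      toy_binary(80, seed = 8)
    des <- encode_dummies(d, reference = "rr")
    aft <- fit_aft(d, des)
    phi <- if (family == "continuous") c(0.8, 0.35, 0.4, 0.9, log(0.9)) else
      c(-3, 0.35, 0.4, 0.9)
    sig <- if (family == "continuous") exp(phi[5]) else NA
    sup <- aft$resdist$support; mass <- aft$resdist$mass
    atheta <- drop(des$design %*% aft$coefficients)
    # independent reimplementation with explicit loops
    ll <- 0
    for (i in seq_len(nrow(d))) {
      u <- phi[1] + sum(phi[3:4] * des$indicators[i, ])
      if (d$.event[i] == 1) {
        lp <- u + phi[2] * log(d$.time[i])
        li <- if (family == "continuous")
          dnorm(d$.outcome[i], lp, sig, log = TRUE) else
          dbinom(d$.outcome[i], 1, plogis(lp), log = TRUE)
      } else {
        e_i <- log(d$.time[i]) - atheta[i]
        s_in <- which(sup > e_i)
        if (!length(s_in)) s_in <- length(sup)
        q_s <- mass[s_in] / sum(mass[s_in])
        lp_s <- u + phi[2] * (sup[s_in] + atheta[i])
        dens <- if (family == "continuous")
          dnorm(d$.outcome[i], lp_s, sig) else
          dbinom(d$.outcome[i], 1, plogis(lp_s))
        li <- log(sum(q_s * dens))
      }
      ll <- ll + li
    }
    expect_equal(pseudo_log_likelihood(phi, d, des, aft), ll / nrow(d),
                 tolerance = 1e-9)
  }
})

test_that("uncensored fits reproduce closed-form regression estimates", {
  d <- toy_continuous(250, seed = 12, cens = FALSE)
  f <- toy_fits(d)
  X <- cbind(1, log(d$.time), f$design$indicators)
  ls <- lm.fit(X, d$.outcome)
  expect_equal(unname(f$outcome$coefficients), unname(ls$coefficients),
               tolerance = 1e-4)
  # MLE sigma (no df correction)
  expect_equal(f$outcome$sigma, sqrt(mean(ls$residuals^2)), tolerance = 1e-4)

  db <- toy_binary(300, seed = 13, cens = FALSE)
  fb <- toy_fits(db)
  Xb <- cbind(1, log(db$.time), fb$design$indicators)
  gl <- glm.fit(Xb, db$.outcome, family = binomial())
  expect_equal(unname(fb$outcome$coefficients), unname(gl$coefficients),
               tolerance = 1e-4)
})

test_that("newton, bfgs and nelder-mead reach the same optimum", {
  d <- toy_continuous(200, seed = 21)
  des <- encode_dummies(d, reference = "rr")
  aft <- fit_aft(d, des)
  fits <- lapply(c("newton", "bfgs", "nelder-mead"), function(m)
    fit_outcome(d, des, aft, method = m))
  for (f in fits[-1]) {
    expect_equal(fits[[1]]$coefficients, f$coefficients, tolerance = 1e-3)
    expect_equal(fits[[1]]$logLik, f$logLik, tolerance = 1e-7)
  }
  expect_true(all(vapply(fits, function(f) f$converged, logical(1))))
})

test_that("the pseudo-likelihood is invariant to subject permutation and weight scale", {
  d <- toy_binary(120, seed = 17)
  des <- encode_dummies(d, reference = "rr")
  aft <- fit_aft(d, des)
  phi <- c(-3.5, 0.38, 0.5, 1)
  pl <- pseudo_log_likelihood(phi, d, des, aft)

  set.seed(1); perm <- sample(nrow(d))
  dp <- d[perm, ]
  attr(dp, "family") <- "binary"; attr(dp, "covariates") <- character(0)
  class(dp) <- class(d)
  desp <- encode_dummies(dp, reference = "rr")
  aftp <- fit_aft(dp, desp)
  expect_equal(pseudo_log_likelihood(phi, dp, desp, aftp), pl,
               tolerance = 1e-10)

  # constant weight rescaling scales the PL by the same constant
  ds <- d; ds$.weight <- d$.weight * 3
  expect_equal(pseudo_log_likelihood(phi, ds, des, aft), 3 * pl,
               tolerance = 1e-9)
})

test_that("the pseudo-likelihood peaks near the generating parameters", {
  sc <- simulation_scenario(family = "continuous", n = 2000, cp_target = 0.3,
                            b0 = 1)
  d <- simulate_mediation(sc, seed = 19)
  des <- encode_dummies(d, reference = "rr")
  aft <- fit_aft(d, des)
  truth <- c(1, 0.4, 0.5, 1, 0)
  pl_true <- pseudo_log_likelihood(truth, d, des, aft)
  for (j in 1:5) {
    bump <- truth; bump[j] <- bump[j] + 0.25
    expect_lt(pseudo_log_likelihood(bump, d, des, aft), pl_true)
  }
})

test_that("the literal (unnormalized) tail integral is available and differs", {
  d <- toy_continuous(100, seed = 30)
  des <- encode_dummies(d, reference = "rr")
  aft <- fit_aft(d, des)
  phi <- c(1, 0.4, 0.5, 1, 0)
  pl_cond <- pseudo_log_likelihood(phi, d, des, aft, conditional = TRUE)
  pl_lit <- pseudo_log_likelihood(phi, d, des, aft, conditional = FALSE)
  expect_false(isTRUE(all.equal(pl_cond, pl_lit)))
  expect_lt(pl_lit, pl_cond)  # unnormalized tail masses are <= 1
})
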