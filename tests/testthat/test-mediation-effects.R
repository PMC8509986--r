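test_that("continuous-family effects cancel algebraically to b*a_j and c_j", {
  f <- toy_fits(toy_continuous(150, seed = 4))
  b <- f$outcome$coefficients[["log_mediator"]]
  for (j in 1:2) {
    aj <- f$aft$coefficients[[j + 1]]
    cj <- f$outcome$coefficients[[j + 2]]
    expect_equal(ie_category(j, f$aft, f$outcome), b * aj, tolerance = 1e-10)
    expect_equal(de_category(j, f$aft, f$outcome), cj, tolerance = 1e-10)
  }
})

test_that("TE is exactly IE + DE and PM their ratio", {
  f <- toy_fits(toy_binary(200, seed = 6))
  freqs <- category_frequencies(f$data, f$design)
  eff <- overall_effects(f$aft, f$outcome, freqs)
  ie <- eff$estimate[eff$term == "IE"]
  de <- eff$estimate[eff$term == "DE"]
  te <- eff$estimate[eff$term == "TE"]
  pm <- eff$estimate[eff$term == "PM"]
  expect_identical(te, ie + de)
  expect_identical(pm, ie / te)
  # overall effects are the weighted sums of the per-category rows
  per_ie <- eff$estimate[grepl("^IE_", eff$term)]
  w <- eff$weight[grepl("^IE_", eff$term)]
  expect_equal(ie, sum(w * per_ie), tolerance = 1e-12)
})

test_that("theoretical continuous effects reproduce the closed-form values", {
  th <- theoretical_effects(a0 = 6, a = c(0.4, 0.8), b0 = 1, b = 0.4,
                            c_tilde = c(0.5, 1), freqs = hwe_frequencies(0.3))
  ie <- th$estimate[th$term == "IE"]
  pm <- th$estimate[th$term == "PM"]
  expect_equal(ie, (0.42 * 0.16 + 0.09 * 0.32) / 0.51, tolerance = 1e-12)
  expect_equal(round(ie, 3), 0.188)
  expect_equal(round(pm, 3), 0.242)
  # raw (unnormalized) weighting is exposed as an option and differs
  th_raw <- theoretical_effects(a0 = 6, a = c(0.4, 0.8), b0 = 1, b = 0.4,
                                c_tilde = c(0.5, 1),
                                freqs = hwe_frequencies(0.3),
                                normalized = FALSE)
  expect_equal(th_raw$estimate[th_raw$term == "IE"],
               0.42 * 0.16 + 0.09 * 0.32, tolerance = 1e-12)
})

test_that("binary effects match a hand-computed sum over a 3-point residual law", {
  # hand-built stage-1/2 objects with a known 3-point eta-hat
  design <- list(labels = c("rr", "Rr", "RR"), reference = "rr", k = 3,
                 covariates = character(0))
  class(design) <- "dummy_design"
  aft <- structure(
    list(coefficients = c(`(Intercept)` = 6, x_Rr = 0.4, x_RR = 0.8),
         resdist = tibble::tibble(support = c(-1, 0, 2),
                                  mass = c(0.2, 0.5, 0.3)),
         tau = 2, design = design),
    class = "aft_fit")
  outcome <- structure(
    list(coefficients = c(`(Intercept)` = -3.7, log_mediator = 0.4,
                          x_Rr = 0.5, x_RR = 1),
         family = "binary"),
    class = "outcome_fit")
  p <- c(0.2, 0.5, 0.3); e <- c(-1, 0, 2)
  ie1_hand <- sum(p * plogis(-3.7 + 0.4 * (e + 6 + 0.4) + 0.5)) -
    sum(p * plogis(-3.7 + 0.4 * (e + 6) + 0.5))
  de1_hand <- sum(p * plogis(-3.7 + 0.4 * (e + 6) + 0.5)) -
    sum(p * plogis(-3.7 + 0.4 * (e + 6)))
  expect_equal(ie_category(1, aft, outcome), ie1_hand, tolerance = 1e-12)
  expect_equal(de_category(1, aft, outcome), de1_hand, tolerance = 1e-12)
})

test_that("a blocked mediator path gives zero indirect effect", {
  f <- toy_fits(toy_binary(150, seed = 10))
  out0 <- f$outcome
  out0$coefficients[["log_mediator"]] <- 0
  expect_equal(ie_category(1, f$aft, out0), 0, tolerance = 1e-12)
  expect_equal(ie_category(2, f$aft, out0), 0, tolerance = 1e-12)
})

test_that("k = 2 reduces the overall IE to the single category contrast", {
  set.seed(44)
  df <- data.frame(y = rnorm(120), m = exp(rnorm(120, 2)),
                   delta = rbinom(120, 1, 0.8),
                   g = sample(c("u", "e"), 120, TRUE))
  d <- mediation_data(df, "y", "m", "delta", "g")
  fit <- mediate_censored(d, reference = "u")
  ie1 <- fit$effects$estimate[fit$effects$term == "IE_e_vs_u"]
  ie <- fit$effects$estimate[fit$effects$term == "IE"]
  expect_equal(ie, ie1, tolerance = 1e-12)
})

test_that("Gauss-Hermite and Monte-Carlo theoretical oracles agree", {
  freqs <- hwe_frequencies(0.3)
  gh <- theoretical_effects(a0 = 6, a = c(0.4, 0.8), b0 = -3.7, b = 0.4,
                            c_tilde = c(0.5, 1), freqs = freqs,
                            family = "binary")
  mc <- theoretical_effects_mc(a0 = 6, a = c(0.4, 0.8), b0 = -3.7, b = 0.4,
                               c_tilde = c(0.5, 1), freqs = freqs,
                               draws = 1e6, seed = 2)
  expect_equal(gh$estimate[gh$term == "IE"], mc$estimate[mc$term == "IE"],
               tolerance = 5e-4)
  # node count is stable: 40 vs 80 nodes agree to near machine precision
  gh80 <- theoretical_effects(a0 = 6, a = c(0.4, 0.8), b0 = -3.7, b = 0.4,
                              c_tilde = c(0.5, 1), freqs = freqs,
                              family = "binary", nodes = 80)
  expect_equal(gh$estimate[gh$term == "IE"],
               gh80$estimate[gh80$term == "IE"], tolerance = 1e-10)
})

test_that("the binary IE increases with the mediator-path coefficient", {
  freqs <- hwe_frequencies(0.3)
  ies <- vapply(seq(0, 0.8, by = 0.2), function(a) {
    th <- theoretical_effects(a0 = 6, a = c(a, 2 * a), b0 = -3.7, b = 0.4,
                              c_tilde = c(0.5, 1), freqs = freqs,
                              family = "binary")
    th$estimate[th$term == "IE"]
  }, numeric(1))
  expect_true(all(diff(ies) > 0))
})

test_that("PM is flagged NA when the total effect is numerically zero", {
  th <- theoretical_effects(a0 = 6, a = c(0, 0), b0 = 1, b = 0,
                            c_tilde = c(0, 0), freqs = hwe_frequencies(0.3))
  expect_true(is.na(th$estimate[th$term == "PM"]))
  expect_equal(th$estimate[th$term == "IE"], 0)
})
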