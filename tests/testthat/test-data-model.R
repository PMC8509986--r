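test_that("dummy coding maps genotypes to indicators with rr as reference", {
  d <- mediation_data(
    data.frame(y = rnorm(6), m = rexp(6) + 1, delta = rep(1, 6),
               g = c("rr", "Rr", "RR", "rr", "Rr", "rr")),
    "y", "m", "delta", "g")
  des <- encode_dummies(d, reference = "rr", order = c("Rr", "RR"))
  expect_equal(des$labels, c("rr", "Rr", "RR"))
  # without a user-supplied order the non-reference categories sort
  # lexicographically
  expect_equal(encode_dummies(d, reference = "rr")$labels,
               c("rr", "RR", "Rr"))
  expect_equal(des$k, 3)
  expect_equal(unname(des$indicators[, "x_Rr"]), c(0, 1, 0, 0, 1, 0))
  expect_equal(unname(des$indicators[, "x_RR"]), c(0, 0, 1, 0, 0, 0))
  # at most one indicator per subject; reference rows all zero
  expect_true(all(rowSums(des$indicators) <= 1))
  expect_equal(ncol(des$design), 1 + 2)
})

test_that("dummy coding handles k = 2 and k = 4 exposures", {
  d2 <- mediation_data(
    data.frame(y = rnorm(4), m = rexp(4) + 1, delta = rep(1, 4),
               g = c("a", "b", "a", "b")),
    "y", "m", "delta", "g")
  des2 <- encode_dummies(d2, reference = "a")
  expect_equal(ncol(des2$indicators), 1)

  d4 <- mediation_data(
    data.frame(y = rnorm(4), m = rexp(4) + 1, delta = rep(1, 4),
               g = c("d0", "d1", "d2", "d3")),
    "y", "m", "delta", "g")
  des4 <- encode_dummies(d4, reference = "d0")
  # subject in d3 has indicator pattern (0, 0, 1)
  expect_equal(unname(des4$indicators[4, ]), c(0, 0, 1))
})

test_that("decoding the indicators recovers the original categories", {
  d <- toy_continuous(n = 80)
  des <- encode_dummies(d, reference = "rr")
  expect_equal(decode_dummies(des), as.character(d$.exposure))
})

test_that("encode_dummies validates the reference category", {
  d <- toy_continuous(n = 30)
  expect_error(encode_dummies(d, reference = "AA"), "not present")
})

test_that("Hardy-Weinberg frequencies match the genotype proportions", {
  f <- hwe_frequencies(0.3)
  expect_identical(f$frequency, c(0.49, 0.42, 0.09))
  expect_identical(f$category, c("rr", "Rr", "RR"))
  expect_equal(f$weight[2:3], c(0.42, 0.09) / 0.51)
  expect_true(is.na(f$weight[1]))

  f5 <- hwe_frequencies(0.5)
  expect_equal(f5$frequency, c(0.25, 0.5, 0.25))

  expect_error(hwe_frequencies(0), "probability")
  expect_error(hwe_frequencies(1.2), "probability")
})

test_that("estimated category frequencies are sample proportions", {
  g <- rep(c("rr", "Rr", "RR"), times = c(49, 42, 9))
  d <- mediation_data(
    data.frame(y = rnorm(100), m = rexp(100) + 1, delta = rep(1, 100), g = g),
    "y", "m", "delta", "g")
  des <- encode_dummies(d, reference = "rr", order = c("Rr", "RR"))
  f <- category_frequencies(d, des)
  expect_equal(f$frequency[match(c("rr", "Rr", "RR"), f$category)],
               c(0.49, 0.42, 0.09))
  expect_equal(attr(f, "source"), "estimated")

  # invariant under duplicating every row
  d2 <- dplyr::bind_rows(d, d)
  attr(d2, "family") <- "continuous"; attr(d2, "covariates") <- character(0)
  class(d2) <- class(d)
  f2 <- category_frequencies(d2, des)
  expect_equal(f2$frequency, f$frequency)

  # raw frequencies sum to 1; normalized non-reference weights sum to 1
  expect_equal(sum(f$frequency), 1, tolerance = 1e-12)
  expect_equal(sum(f$weight, na.rm = TRUE), 1, tolerance = 1e-12)
})

test_that("external frequency tables pass through verbatim", {
  d <- toy_continuous(n = 40)
  des <- encode_dummies(d, reference = "rr", order = c("Rr", "RR"))
  ext <- data.frame(category = c("rr", "Rr", "RR"),
                    frequency = c(0.49, 0.42, 0.09))
  f <- category_frequencies(d, des, external = ext)
  expect_equal(f$frequency, c(0.49, 0.42, 0.09))
  expect_equal(attr(f, "source"), "external")

  expect_error(
    category_frequencies(d, des, external = data.frame(category = "rr",
                                                       frequency = 1)),
    "missing categories")
})

test_that("k = 2 normalization always gives the exposed category weight 1", {
  for (p_exposed in c(0.1, 0.5, 0.9)) {
    n <- 50
    g <- c(rep("u", round(n * (1 - p_exposed))), rep("e", round(n * p_exposed)))
    d <- mediation_data(
      data.frame(y = rnorm(length(g)), m = rexp(length(g)) + 1,
                 delta = rep(1, length(g)), g = g),
      "y", "m", "delta", "g")
    des <- encode_dummies(d, reference = "u")
    f <- category_frequencies(d, des)
    expect_equal(f$weight[f$category == "e"], 1)
  }
})

test_that("sampling-weighted frequencies recover population proportions in case-control data", {
  sc <- simulation_scenario(family = "binary", maf = 0.3, cp_target = 0.2,
                            b0 = -3.7, n_case = 400, n_control = 400)
  d <- simulate_mediation(sc, seed = 31)
  des <- encode_dummies(d, reference = "rr")
  fw <- category_frequencies(d, des, use_weights = TRUE)
  fu <- category_frequencies(d, des, use_weights = FALSE)
  hwe <- hwe_frequencies(0.3)$frequency
  # weighted estimate should be closer to the generating HWE proportions
  expect_lt(max(abs(fw$frequency - hwe)), max(abs(fu$frequency - hwe)))
  expect_lt(max(abs(fw$frequency - hwe)), 0.06)
})

test_that("dataset validation rejects malformed input", {
  base <- data.frame(y = rnorm(4), m = c(1, 2, 3, 4), delta = c(1, 0, 1, 1),
                     g = c("a", "b", "a", "b"))
  expect_error(mediation_data(base, "y", "missing", "delta", "g"), "not found")
  bad_m <- base; bad_m$m[2] <- -1
  expect_error(mediation_data(bad_m, "y", "m", "delta", "g"), "positive")
  bad_d <- base; bad_d$delta <- c(1, 2, 0, 1)
  expect_error(mediation_data(bad_d, "y", "m", "delta", "g"), "0/1")
  bad_y <- base; bad_y$y <- c(0, 1, 2, 0)
  expect_error(mediation_data(bad_y, "y", "m", "delta", "g", family = "binary"),
               "binary")
  none_obs <- base; none_obs$delta <- 0
  expect_error(mediation_data(none_obs, "y", "m", "delta", "g"), "observed")
})
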