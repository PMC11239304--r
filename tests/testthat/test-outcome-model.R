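test_that("the closed-form backend equals an independent least-squares fit", {
  dat <- simulate_orct(cs_design, cs_effects, seed = 31)
  ps <- fit_expected_outcomes(dat)
  # independent route: dummy-coded lm on the raw 0/1 indicators; predictions
  # are invariant to the coding, so the two must agree exactly
  ref <- lm(outcome ~ (A + B + C + D)^2, data = dat)
  grid <- as.data.frame(condition_matrix(cs_design))
  expect_equal(ps$estimate, unname(predict(ref, newdata = grid)),
               tolerance = 1e-10)
})

test_that("a saturated fit returns the raw cell means", {
  dat <- simulate_orct(cs_design, cs_effects, seed = 32)
  ps <- fit_expected_outcomes(dat, terms = "saturated")
  cell_means <- tapply(dat$outcome, dat$condition, mean)
  expect_equal(ps$estimate, as.numeric(cell_means[ps$condition]),
               tolerance = 1e-10)
})

test_that("noise-free data are reproduced by the model", {
  dat <- simulate_orct(cs_design, cs_effects, noise_sd = 0, seed = 33)
  sat <- fit_expected_outcomes(dat, terms = "saturated")
  # every outcome in the BC cells is exactly 1 regardless of S
  expect_equal(unname(predict_cell_mean(sat, "BC")["estimate"]), 1.0,
               tolerance = 1e-10)
  # the parsimonious fit deviates from the generator only through the
  # within-stratum advantage draws
  tw <- fit_expected_outcomes(dat)
  expect_equal(tw$estimate, unname(cs_true_mean[tw$condition]),
               tolerance = 0.06)
  expect_equal(unname(predict_cell_mean(tw, "AB")["estimate"]), 1.25,
               tolerance = 0.06)
})

test_that("estimates are unbiased for the population-average gains", {
  est <- matrix(NA_real_, 30, 16)
  for (r in 1:30) {
    dat <- simulate_orct(cs_design, cs_effects, seed = 400 + r)
    est[r, ] <- fit_expected_outcomes(dat)$estimate
  }
  # MC SE of each mean ~ 0.117 / sqrt(30) = 0.021; allow 4 SEs
  expect_equal(colMeans(est), unname(cs_true_mean[cs_conditions]),
               tolerance = 0.09)
})

test_that("the sampling backend agrees with the closed form", {
  dat <- simulate_orct(cs_design, cs_effects, seed = 34)
  closed <- fit_expected_outcomes(dat)
  samp <- fit_expected_outcomes(dat, backend = "sampling", draws = 8000,
                                seed = 1)
  mc_se <- samp$sd / sqrt(8000)
  expect_true(all(abs(samp$estimate - closed$estimate) < 4 * mc_se))
  # posterior spread matches the closed-form standard error (t vs normal
  # inflation is below 10% at these degrees of freedom)
  expect_equal(samp$sd, closed$sd, tolerance = 0.1)
})

test_that("group-scope fits use only that group's records", {
  dat <- simulate_orct(cs_design, cs_effects, seed = 35)
  g2 <- fit_expected_outcomes(dat, scope = 2)
  manual <- fit_expected_outcomes(dat[dat$group == 2, ], cs_design)
  expect_equal(g2$estimate, manual$estimate, tolerance = 1e-12)
  go <- fit_group_outcomes(dat)
  expect_identical(dim(go$estimate), c(16L, 5L))
  expect_equal(go$estimate[, 2], stats::setNames(g2$estimate, g2$condition),
               tolerance = 1e-12)
  expect_equal(go$weights, rep(0.2, 5))
})

test_that("inestimable terms raise an informative fitting error", {
  dat <- simulate_orct(cs_design, cs_effects, seed = 36)
  dropped <- dat[dat$condition != "ABCD", ]
  expect_error(fit_expected_outcomes(dropped, cs_design, terms = "saturated"),
               "rank deficient")
  expect_error(fit_expected_outcomes(dat, scope = 9), "no records")
  expect_error(predict_cell_mean(fit_expected_outcomes(dat), "AE"),
               "parse|component")
})
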