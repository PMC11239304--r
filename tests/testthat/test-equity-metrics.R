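test_that("rank boundaries cumulate the group weights", {
  expect_equal(rank_boundaries(rep(0.2, 5)), seq(0, 1, by = 0.2))
  expect_equal(rank_boundaries(1), c(0, 1))
  expect_equal(rank_boundaries(c(0.5, 0.3, 0.2)), c(0, 0.5, 0.8, 1.0))
  expect_error(rank_boundaries(c(0.5, -0.1, 0.6)), "positive")
  expect_error(rank_boundaries(c(0.5, 0.3)), "sum to 1")
})

test_that("the exclusion rule removes non-positive total gains", {
  expect_true(apply_exclusion(rep(0, 5)))
  expect_true(apply_exclusion(c(-1, -1, 1, 1)))           # boundary: total 0
  expect_false(apply_exclusion(c(-0.5, 0.2, 0.5, 0.8, 1)))  # total 0.4
  ex <- apply_exclusion(rbind(a = c(0.1, 0.1), b = c(-0.2, 0.1)))
  expect_identical(as.logical(ex), c(FALSE, TRUE))
  expect_equal(unname(attr(ex, "total")), c(0.1, -0.05))
  # positive tolerance widens the exclusion band
  expect_true(apply_exclusion(c(0.01, 0.01, 0.01, 0.01, 0.01), tolerance = 0.05))
})

test_that("concentration curves have pinned endpoints and exact heights", {
  # uniform gains sit on the 45-degree line
  cc <- concentration_curve(rep(0.7, 5))
  expect_equal(cc$h, seq(0, 1, by = 0.2))
  # condition D true quintile gains
  ccD <- concentration_curve(1 - cs_quintile_mid)
  expect_equal(ccD$h, c(0, 0.36, 0.64, 0.84, 0.96, 1))
  # condition A true quintile gains
  ccA <- concentration_curve(0.5 + 0.5 * cs_quintile_mid)
  expect_equal(ccA$h, c(0, 0.55, 1.2, 1.95, 2.8, 3.75) / 3.75)
  expect_error(concentration_curve(c(-1, 1)), "total gain is zero")
})

test_that("the concentration index matches the hand-computed references", {
  expect_equal(concentration_index(concentration_curve(rep(2, 5))), 0)
  H_D <- concentration_index(concentration_curve(1 - cs_quintile_mid))
  expect_equal(H_D, -0.32, tolerance = 1e-12)
  H_A <- concentration_index(concentration_curve(0.5 + 0.5 * cs_quintile_mid))
  expect_equal(H_A, 8 / 75, tolerance = 1e-12)  # +0.10667
  expect_equal(equitability(H_D), 0.32, tolerance = 1e-12)
  H_AB <- concentration_index(concentration_curve(0.5 + 1.5 * cs_quintile_mid))
  expect_equal(equitability(H_AB), -0.192, tolerance = 1e-12)
})

test_that("index properties hold over random gain profiles", {
  set.seed(123)
  for (r in 1:50) {
    G <- sample(2:8, 1)
    w <- as.numeric(rexp(G) + 0.05)
    w <- w / sum(w)
    gains <- rnorm(G, mean = 1, sd = 1)
    if (sum(gains) <= 0.05) gains <- gains + 1.2 - sum(gains) / G
    cc <- concentration_curve(gains, w)
    H <- concentration_index(cc)
    # endpoints pinned
    expect_identical(cc$h[1], 0)
    expect_identical(cc$h[length(cc$h)], 1)
    # equals the fine-grid numeric integration oracle
    expect_equal(H, oracle_concentration_index(gains, w), tolerance = 1e-12)
    # mirror in advantage negates H (for symmetric weights)
    cc_rev <- concentration_curve(rev(gains), rev(w))
    expect_equal(concentration_index(cc_rev), -H, tolerance = 1e-12)
    # scale invariance
    cc_scaled <- concentration_curve(3.7 * gains, w)
    expect_equal(concentration_index(cc_scaled), H, tolerance = 1e-12)
    # Q = -H is an involution
    expect_identical(equitability(equitability(H)), H)
  }
})

test_that("a negative-gain group can push |H| beyond 1", {
  # total gain is +1 but the curve dips to -4: outside the classical band
  H <- concentration_index(concentration_curve(c(-4, 5)))
  expect_equal(H, 4.5, tolerance = 1e-12)
  expect_gt(abs(H), 1)
})

test_that("the equity table flags exclusions and carries no H for them", {
  gg <- true_group_gains(cs_conditions, cs_effects, 5)
  et <- equity_table(gg)
  expect_identical(et$condition, cs_conditions)
  expect_identical(et$condition[et$excluded], c("Min", "C"))
  expect_true(all(is.na(et$H[et$excluded])))
  expect_equal(et$Q, -et$H)
  expect_equal(et$Q[et$condition == "D"], 0.32, tolerance = 1e-12)
  expect_equal(et$total, unname(cs_true_mean[cs_conditions]), tolerance = 1e-8)
  # the credibility-based tolerance needs the SD matrix
  expect_error(equity_table(gg, tolerance = "2sd"), "needs the 'sd' matrix")
  et2 <- equity_table(gg, tolerance = "2sd", sd = matrix(0.1, 16, 5))
  expect_true(all(c("Min", "C") %in% et2$condition[et2$excluded]))
})
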