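cs_points <- data.frame(
  condition = cs_conditions,
  cost = intervention_cost(cs_conditions, cs_design),
  gain = unname(cs_true_mean[cs_conditions]),
  stringsAsFactors = FALSE
)

test_that("net health value is the exact affine combination", {
  expect_equal(net_health_value(0.5, 250, 580), 40)
  expect_equal(net_health_value(0, 0, 170), 0)
  expect_equal(net_health_value(0.75, 100, 170), 27.5)
  expect_equal(net_health_value(c(1, 2), c(10, 20), 100), c(90, 180))
  expect_error(net_health_value(1, 1, -5), "positive")
  # strictly increasing in lambda whenever the gain is positive
  expect_true(all(diff(net_health_value(0.4, 100, c(100, 200, 300))) > 0))
})

test_that("the analytic case-study value frontier is Min-A-AB-ABC-ABCD", {
  vf <- value_efficiency_frontier(cs_points, design = cs_design)
  expect_identical(vf$condition, c("Min", "A", "AB", "ABC", "ABCD"))
  expect_true(all(diff(vf$cost) > 0) && all(diff(vf$gain) > 0))
  expect_equal(icers(vf), c(400 / 3, 250, 400, 500), tolerance = 1e-10)
  expect_true(all(diff(icers(vf)) > 0))
})

test_that("degenerate frontier inputs are handled", {
  one <- data.frame(condition = "X", cost = 5, gain = 1)
  f1 <- value_efficiency_frontier(one)
  expect_identical(f1$condition, "X")
  expect_error(icers(f1), "at least two")
  # equal cost: only the higher-gain point survives
  two <- data.frame(condition = c("lo", "hi"), cost = c(10, 10), gain = c(1, 2))
  expect_identical(value_efficiency_frontier(two)$condition, "hi")
  # collinear middle point is extended-dominated under the strict hull
  col3 <- data.frame(condition = c("p", "q", "r"), cost = c(0, 100, 200),
                     gain = c(0, 1, 2))
  f3 <- value_efficiency_frontier(col3)
  expect_identical(f3$condition, c("p", "r"))
  expect_equal(icers(f3), 100)
  f3c <- value_efficiency_frontier(col3, include_collinear = TRUE)
  expect_identical(f3c$condition, c("p", "q", "r"))
  two_flat <- data.frame(condition = c("a", "b"), cost = c(0, 10), gain = c(1, 1))
  expect_identical(value_efficiency_frontier(two_flat)$condition, "a")
})

test_that("representative thresholds bracket the decision ranges", {
  expect_equal(representative_wtp(values = c(580, 170, 830, 330)),
               c(170, 330, 580, 830))
  expect_equal(representative_wtp(100), c(50, 150))
  e <- c(400 / 3, 250, 400, 500)
  w <- representative_wtp(e)
  expect_length(w, 5L)
  # one value below the smallest ICER, one between each pair, one above
  expect_lt(w[1], e[1])
  for (i in 1:3) expect_true(w[i + 1] > e[i] && w[i + 1] < e[i + 1])
  expect_gt(w[5], e[4])
  expect_error(representative_wtp(), "either ICERs or")
  expect_error(representative_wtp(values = c(-1, 10)), "positive")
})

test_that("analytic equity frontiers recover the expected contenders", {
  gg <- true_group_gains(cs_conditions, cs_effects, 5)
  et <- equity_table(gg)
  keep <- !et$excluded
  for (lam in c(170, 830)) {
    p <- data.frame(condition = cs_conditions,
                    Q = et$Q,
                    NHV = net_health_value(cs_points$gain, cs_points$cost, lam),
                    stringsAsFactors = FALSE)[keep, ]
    f <- net_health_equity_frontier(p, design = cs_design)
    if (lam == 170) {
      expect_identical(f$condition, c("A", "D"))
      expect_identical(f$quadrant, c("upper-left", "lower-right"))
    } else {
      # BCD lies below the ABCD-D segment at its equitability
      expect_identical(f$condition, c("ABCD", "D"))
      expect_false("BCD" %in% f$condition)
    }
    # members run from highest NHV to highest Q
    expect_true(all(diff(f$NHV) <= 0) && all(diff(f$Q) >= 0))
  }
  one <- data.frame(condition = "Z", Q = 0.1, NHV = 5)
  expect_identical(net_health_equity_frontier(one)$condition, "Z")
})

test_that("quadrant labels follow the signs of Q and NHV", {
  expect_identical(quadrant(0.32, -165), "lower-right")
  expect_identical(quadrant(-0.107, 27.5), "upper-left")
  expect_identical(quadrant(0, 0), "on-axis")
  expect_identical(quadrant(c(0.1, -0.1), c(5, -5)),
                   c("upper-right", "lower-left"))
  expect_identical(quadrant(0.001, 5, tol = 0.01), "on-axis")
})

test_that("hull routines equal brute-force enumeration on random inputs", {
  set.seed(2024)
  for (r in 1:120) {
    n <- sample(2:16, 1)
    pts <- data.frame(
      condition = sprintf("c%02d", seq_len(n)),
      cost = round(runif(n, 0, 700), 1),
      gain = round(rnorm(n, 1, 0.8), 3),
      stringsAsFactors = FALSE
    )
    pts <- pts[!duplicated(pts[c("cost", "gain")]), ]
    vf <- value_efficiency_frontier(pts)
    expect_identical(sort(vf$condition), oracle_value_frontier(pts))
    if (nrow(vf) >= 2L) {
      # non-members lie weakly below the hull at their cost
      hull_at <- approx(vf$cost, vf$gain, xout = pts$cost, rule = 2)$y
      out <- !(pts$condition %in% vf$condition)
      expect_true(all(pts$gain[out] <= hull_at[out] + 1e-9))
    }

    qp <- data.frame(
      condition = sprintf("c%02d", seq_len(n)),
      Q = round(rnorm(n, 0, 0.3), 3),
      NHV = round(rnorm(n, 0, 200), 2),
      stringsAsFactors = FALSE
    )
    qp <- qp[!duplicated(qp[c("Q", "NHV")]), ]
    ef <- net_health_equity_frontier(qp)
    expect_identical(sort(ef$condition), oracle_equity_frontier(qp))
    if (nrow(ef) >= 2L) {
      ord <- order(ef$Q)
      hull_at_q <- approx(ef$Q[ord], ef$NHV[ord], xout = qp$Q, rule = 2)$y
      out_q <- !(qp$condition %in% ef$condition)
      expect_true(all(qp$NHV[out_q] <= hull_at_q[out_q] + 1e-9))
    }
  }
})

test_that("estimated value frontiers are reliable at large cell sizes", {
  hits <- 0L
  for (s in 1:5) {
    dat <- simulate_orct(cs_design, cs_effects, per_cell_n = 1000, seed = s)
    est <- fit_expected_outcomes(dat)
    pts <- data.frame(condition = cs_conditions, cost = cs_points$cost,
                      gain = est$estimate, stringsAsFactors = FALSE)
    vf <- value_efficiency_frontier(pts, design = cs_design)
    hits <- hits + identical(sort(setdiff(vf$condition, "Min")),
                             c("A", "AB", "ABC", "ABCD"))
  }
  expect_gte(hits, 4L)
})
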