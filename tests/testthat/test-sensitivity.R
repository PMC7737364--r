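base <- base_parameters()

test_that("one-way sweeps reproduce the qualitative preference claims", {
  # risk-adapted preferred for any relapse rate of the low-risk group
  sw <- one_way_sweep(param_range("pRelapseLowrisk", 0.10, 0.20), base)
  expect_true(all(sw$preferred == "risk_adapted"))

  # and for any proportion of low-risk patients short of 1 (indifferent there)
  sw2 <- one_way_sweep(param_range("pLowRisk", 0, 1), base)
  expect_true(all(sw2$preferred[sw2$value < 1] == "risk_adapted"))
  expect_identical(sw2$preferred[sw2$value == 1], "indifferent")

  # and for any toxicity multiplier in the elicited range
  sw3 <- one_way_sweep(param_range("tSecondChemo", 1.0, 2.0), base)
  expect_true(all(sw3$preferred == "risk_adapted"))
})

test_that("sweep engines agree and grids are well formed", {
  rng <- param_range("pRelapsePostPrimChemo", 0, 0.3, n = 7)
  a <- one_way_sweep(rng, base, engine = "closed_form")
  b <- one_way_sweep(rng, base, engine = "rollback")
  expect_equal(a$surveillance, b$surveillance, tolerance = 1e-12)
  expect_equal(a$risk_adapted, b$risk_adapted, tolerance = 1e-12)
  expect_true(all(diff(a$value) > 0))
  expect_error(param_range("pLowRisk", 0.5, 0.2), "below")
  expect_error(param_range("nope"), "must be one of")
})

test_that("the strategy difference is affine along every one-way sweep", {
  for (nm in c(
    "pLowRisk", "pRelapseLowrisk", "pRelapseHighrisk",
    "pRelapsePostPrimChemo", "pRelapsePostSalvChemo", "tSecondChemo"
  )) {
    sw <- one_way_sweep(param_range(nm, n = 41), base)
    second_diff <- diff(sw$difference, differences = 2)
    expect_lt(max(abs(second_diff)), 1e-10)
  }
})

test_that("closed-form thresholds match the analytic roots and bisection", {
  R <- 3 + 0.05 * 3 * 1.3
  thr <- find_threshold("pRelapsePostPrimChemo", base)
  expect_equal(thr$threshold, 0.60 - 1 / R, tolerance = 1e-12)
  expect_equal(thr$threshold_display, 0.287)
  expect_identical(thr$preferred_below, "risk_adapted")
  expect_identical(thr$preferred_above, "surveillance")

  thr2 <- find_threshold("pRelapseHighrisk", base)
  expect_equal(thr2$threshold, 0.05 + 1 / R, tolerance = 1e-12)
  expect_equal(thr2$threshold_display, 0.363)
  expect_identical(thr2$preferred_above, "risk_adapted")

  # bisection is an independent cross-check of the affine solve
  for (nm in c("pRelapsePostPrimChemo", "pRelapseHighrisk")) {
    cf <- find_threshold(nm, base, method = "closed_form")
    bi <- find_threshold(nm, base, method = "bisection")
    expect_equal(cf$threshold, bi$threshold, tolerance = 1e-9)
  }
})

test_that("parameters the difference ignores yield no threshold, with a flag", {
  thr <- find_threshold("pRelapseLowrisk", base,
    range = param_range("pRelapseLowrisk", 0.10, 0.20)
  )
  expect_true(is.na(thr$threshold))
  expect_match(thr$flag, "does not depend")
  expect_identical(thr$preferred_below, "risk_adapted")

  # coincident arms: difference identically zero
  thr0 <- find_threshold("pRelapseLowrisk", parameter_set(pLowRisk = 1))
  expect_true(is.na(thr0$threshold))
  expect_match(thr0$flag, "identically zero")
  expect_identical(thr0$preferred_below, "indifferent")

  # monotone difference with no crossing inside a narrow range
  thr1 <- find_threshold("pRelapsePostPrimChemo", base,
    range = param_range("pRelapsePostPrimChemo", 0, 0.1)
  )
  expect_true(is.na(thr1$threshold))
})

test_that("two-way regions respect the factorization of the difference", {
  # preference is constant along the pRelapseLowrisk axis
  reg <- two_way_sweep(
    param_range("pRelapseHighrisk", n = 21),
    param_range("pRelapseLowrisk", 0.10, 0.20, n = 11),
    base
  )
  for (i in seq_along(reg$grid_a)) {
    expect_length(unique(reg$risk_adapted_preferred[i, ]), 1L)
  }

  # risk-adapted preferred everywhere except the pLowRisk = 1 edge
  reg2 <- two_way_sweep(
    param_range("pLowRisk", n = 21),
    param_range("tSecondChemo", n = 11),
    base
  )
  edge <- reg2$grid_a == 1
  expect_true(all(reg2$risk_adapted_preferred[!edge, ]))
  expect_true(all(is.na(reg2$risk_adapted_preferred[edge, ])))

  expect_error(
    two_way_sweep(param_range("pLowRisk"), param_range("pLowRisk"), base),
    "distinct"
  )
})

test_that("the preference boundary is the line pHigh = pPrim + 1/R", {
  R <- 3 + 0.05 * 3 * 1.3
  reg <- two_way_sweep(
    param_range("pRelapsePostPrimChemo", 0, 0.3, n = 31),
    param_range("pRelapseHighrisk", 0.3, 0.8, n = 51),
    base
  )
  # cell-by-cell: sign of the difference matches the side of the line
  for (i in seq_along(reg$grid_a)) {
    cut <- reg$grid_a[i] + 1 / R
    above <- reg$grid_b > cut + 1e-9
    below <- reg$grid_b < cut - 1e-9
    expect_true(all(reg$risk_adapted_preferred[i, above]))
    expect_true(all(!reg$risk_adapted_preferred[i, below]))
  }
  # interpolated boundary points sit on the line (difference is linear in b)
  expect_equal(
    reg$boundary$pRelapseHighrisk,
    reg$boundary$pRelapsePostPrimChemo + 1 / R,
    tolerance = 1e-9
  )
  # engines agree on a coarse grid
  reg_rb <- two_way_sweep(
    param_range("pRelapsePostPrimChemo", 0, 0.3, n = 5),
    param_range("pRelapseHighrisk", 0.3, 0.8, n = 5),
    base,
    engine = "rollback"
  )
  reg_cf <- two_way_sweep(
    param_range("pRelapsePostPrimChemo", 0, 0.3, n = 5),
    param_range("pRelapseHighrisk", 0.3, 0.8, n = 5),
    base
  )
  expect_equal(reg_rb$difference, reg_cf$difference, tolerance = 1e-12)
})
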