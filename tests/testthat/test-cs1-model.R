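test_that("hand-evaluated exposures of the strategy arms are reproduced", {
  # all high risk: surveillance = 0.60 * (3 + 0.05 * 3 * 1.3)
  p0 <- parameter_set(pLowRisk = 0)
  expect_equal(rollback(build_surveillance_tree(), p0), 1.9170, tolerance = 1e-12)
  # all high risk, risk-adapted: 1 + 0.05 * (3 + 0.05 * 3.9)
  expect_equal(rollback(build_risk_adapted_tree(), p0), 1.159750, tolerance = 1e-12)

  # no relapses, no chemotherapy
  none <- parameter_set(pRelapseLowrisk = 0, pRelapseHighrisk = 0)
  expect_equal(rollback(build_surveillance_tree(), none), 0)
  expect_equal(
    rollback(build_surveillance_tree(), parameter_set(
      pRelapseLowrisk = 0, pRelapseHighrisk = 0, pLowRisk = 0.8
    )), 0
  )
  expect_equal(
    rollback(build_risk_adapted_tree(), parameter_set(
      pLowRisk = 1, pRelapseLowrisk = 0
    )), 0
  )
})

test_that("closed form and rollback agree on both trees over random parameters", {
  set.seed(101)
  trees <- list(
    surveillance = build_surveillance_tree(),
    risk_adapted = build_risk_adapted_tree()
  )
  for (i in 1:1000) {
    p <- random_params()
    for (nm in names(trees)) {
      expect_equal(
        closed_form_exposure(nm, p), rollback(trees[[nm]], p),
        tolerance = 1e-12
      )
    }
  }
})

test_that("exposure difference factorizes through the high-risk arm", {
  # surveillance - risk_adapted =
  #   (1 - pLowRisk) * [pRelapseHighrisk*R - nPrimaryCycles - pPrim*R]
  # so the preferred strategy never depends on pLowRisk (< 1) or
  # pRelapseLowrisk
  set.seed(202)
  for (i in 1:200) {
    p <- random_params()
    R <- p$nSalvageCycles +
      p$pRelapsePostSalvChemo * p$nSecondLineCycles * p$tSecondChemo
    expected <- (1 - p$pLowRisk) *
      (p$pRelapseHighrisk * R - p$nPrimaryCycles - p$pRelapsePostPrimChemo * R)
    cmp <- compare_strategies(p, engine = "closed_form")
    expect_equal(cmp$difference, expected, tolerance = 1e-12)
  }
})

test_that("arms coincide when there are no high-risk patients", {
  set.seed(303)
  for (i in 1:50) {
    p <- random_params()
    p$pLowRisk <- 1
    expect_equal(
      rollback(build_risk_adapted_tree(), p),
      rollback(build_surveillance_tree(), p),
      tolerance = 1e-14
    )
  }
  expect_identical(compare_strategies(parameter_set(pLowRisk = 1))$preferred, "indifferent")
})

test_that("exposures are monotone in the relapse probabilities", {
  set.seed(404)
  for (i in 1:100) {
    p <- random_params()
    lo <- sort(runif(2))
    p_hi <- p
    p$pRelapseHighrisk <- lo[1]
    p_hi$pRelapseHighrisk <- lo[2]
    expect_gte(
      closed_form_exposure("surveillance", p_hi) + 1e-12,
      closed_form_exposure("surveillance", p)
    )
    q <- random_params()
    q_hi <- q
    q$pRelapsePostPrimChemo <- lo[1]
    q_hi$pRelapsePostPrimChemo <- lo[2]
    expect_gte(
      closed_form_exposure("risk_adapted", q_hi) + 1e-12,
      closed_form_exposure("risk_adapted", q)
    )
  }
})

test_that("strategy comparison at the base case prefers risk-adapted treatment", {
  cmp <- compare_strategies(base_parameters())
  expect_equal(cmp$surveillance, 1.3419, tolerance = 1e-12)
  expect_equal(cmp$risk_adapted, 0.88755, tolerance = 1e-12)
  expect_identical(cmp$preferred, "risk_adapted")

  # weak stratification + poor primary chemotherapy flips the preference
  flip <- parameter_set(pRelapseHighrisk = 0.2, pRelapsePostPrimChemo = 0.3)
  expect_identical(compare_strategies(flip)$preferred, "surveillance")
})
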