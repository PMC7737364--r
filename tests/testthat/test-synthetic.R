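test_that("survey generation is reproducible, bounded and well shaped", {
  cfg <- survey_config(n_respondents = 24)
  s1 <- generate_survey(cfg, seed = 42)
  s2 <- generate_survey(cfg, seed = 42)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 24L)
  scores <- as.matrix(s1[, c("vas_no_chemo", "vas_first_line", "vas_second_line")])
  expect_true(all(scores >= 0 & scores <= 100))
  expect_true(all(s1$vas_no_chemo >= 85 & s1$vas_no_chemo <= 100))
  expect_false(identical(s1, generate_survey(cfg, seed = 43)))
})

test_that("zero spread pins relative values to the target mean up to quantization", {
  cfg <- survey_config(n_respondents = 50, sd_first = 0, sd_second = 0)
  s <- generate_survey(cfg, seed = 1)
  rv <- survey_relative_values(s, digits = NULL)
  # integer VAS scores quantize the ratio by at most 0.5 / anchor
  bound <- 0.5 / min(s$vas_no_chemo) + 1e-12
  expect_lt(max(abs(rv$rel_first_line - 0.841)), bound)
  expect_lt(max(abs(rv$rel_second_line - 0.635)), bound)
})

test_that("a large generated survey recovers the configured means", {
  s <- generate_survey(survey_config(n_respondents = 2000), seed = 99)
  summ <- summarize_survey(s)
  expect_lt(abs(summ$arms$mean[1] - 0.841), 0.02)
  expect_lt(abs(summ$arms$mean[2] - 0.635), 0.02)
})

test_that("infeasible generator configurations are rejected", {
  expect_error(survey_config(mean_first = 1.2), "\\(0, 1\\]")
  expect_error(survey_config(sd_second = -0.1), ">= 0")
  expect_error(survey_config(no_chemo_bounds = c(0, 50)), "within \\[1, 100\\]")
  expect_error(survey_config(n_respondents = 0), "at least one")
})

test_that("degenerate cohorts take the only available path", {
  none <- parameter_set(pRelapseLowrisk = 0, pRelapseHighrisk = 0)
  cc <- simulate_cohort("surveillance", none, n = 500, seed = 3)
  expect_equal(cc$mean_exposure, 0)
  expect_equal(cc$se, 0)

  certain <- parameter_set(pLowRisk = 0, pRelapsePostPrimChemo = 0)
  cc2 <- simulate_cohort("risk_adapted", certain, n = 500, seed = 3)
  expect_equal(cc2$mean_exposure, 1) # exactly one primary cycle each
  expect_equal(cc2$se, 0)
  expect_identical(sum(cc2$path_counts), 500L)
  expect_identical(unname(cc2$path_counts[["high:no_relapse"]]), 500L)
})

test_that("cohort simulation agrees with rollback within Monte-Carlo error", {
  set.seed(2024)
  n <- 100000L
  failures <- 0L
  for (i in 1:20) {
    p <- random_params()
    strat <- if (i %% 2 == 0) "surveillance" else "risk_adapted"
    cc <- simulate_cohort(strat, p, n = n, seed = 1000L + i)
    expected <- closed_form_exposure(strat, p)
    se <- max(cc$se, 1e-12)
    if (abs(cc$mean_exposure - expected) > 3 * se) failures <- failures + 1L
    expect_identical(sum(cc$path_counts), n)
  }
  # a 3-SE band admits the occasional excursion among 20 draws
  expect_lte(failures, 2L)
})

test_that("empirical branch rates match the configured probabilities", {
  p <- base_parameters()
  n <- 50000L
  cc <- simulate_cohort("surveillance", p, n = n, seed = 77)
  frac_low <- sum(cc$path_counts[grep("^low", names(cc$path_counts))]) / n
  expect_lt(
    abs(frac_low - p$pLowRisk),
    3 * sqrt(p$pLowRisk * (1 - p$pLowRisk) / n)
  )
  n_high <- sum(cc$path_counts[grep("^high", names(cc$path_counts))])
  frac_relapse_high <- sum(cc$path_counts[c(
    "high:salvage_cr", "high:salvage_second_line"
  )]) / n_high
  expect_lt(
    abs(frac_relapse_high - p$pRelapseHighrisk),
    3 * sqrt(p$pRelapseHighrisk * (1 - p$pRelapseHighrisk) / n_high)
  )
})

test_that("seeded calls leave the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_survey(survey_config(), seed = 5))
  invisible(simulate_cohort("surveillance", n = 10, seed = 5))
  expect_identical(.Random.seed, before)
})
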