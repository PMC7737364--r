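test_that("packaged survey loads and relative values match the tabulation", {
  survey <- cs1_vas_survey()
  expect_s3_class(survey, "cs1_survey")
  expect_identical(nrow(survey), 24L)

  expect_equal(relative_value(95, 85), 0.895)
  expect_equal(relative_value(85, 58), 0.682)
  expect_equal(relative_value(85, 37), 0.435)
  expect_equal(relative_value(70, 70), 1.0)
  # the tabulation rounds halves up: 65/80 = 0.8125 -> 0.813
  expect_equal(relative_value(80, 65), 0.813)
  expect_equal(relative_value(80, 65, digits = NULL), 0.8125)

  rv <- survey_relative_values(survey)
  expect_equal(rv$rel_first_line[1], 0.895)
  expect_equal(rv$rel_second_line[14], 0.435)
  expect_true(all(rv$rel_first_line >= rv$rel_second_line))
})

test_that("survey summaries reproduce the published means and SDs", {
  summ <- summarize_survey(cs1_vas_survey())
  first <- summ$arms[summ$arms$arm == "first_line", ]
  second <- summ$arms[summ$arms$arm == "second_line", ]
  expect_equal(round_half_up(first$mean, 3), 0.841)
  expect_equal(round_half_up(first$sd, 3), 0.081)
  expect_equal(round_half_up(second$mean, 3), 0.635)
  expect_equal(round_half_up(second$sd, 3), 0.151)

  # t-based confidence interval straddles the mean
  expect_lt(first$ci_low, first$mean)
  expect_gt(first$ci_high, first$mean)
  expect_equal(
    first$ci_high - first$mean,
    qt(0.975, 23) * first$sd / sqrt(24),
    tolerance = 1e-12
  )

  expect_equal(derive_toxicity_ratio(summ), 1.3)
  expect_equal(derive_toxicity_ratio(summ, digits = NULL), 0.841 / 0.635,
    tolerance = 1e-12
  )
})

test_that("degenerate and invalid surveys are handled", {
  two <- as_cs1_survey(data.frame(
    respondent_id = 1:2, vas_no_chemo = c(90, 90),
    vas_first_line = c(80, 80), vas_second_line = c(60, 60)
  ))
  summ <- summarize_survey(two)
  expect_equal(summ$arms$sd, c(0, 0))

  one <- as_cs1_survey(data.frame(
    respondent_id = 1, vas_no_chemo = 90,
    vas_first_line = 80, vas_second_line = 60
  ))
  expect_error(summarize_survey(one), "at least 2")

  expect_error(
    as_cs1_survey(data.frame(
      respondent_id = 1, vas_no_chemo = 0,
      vas_first_line = 10, vas_second_line = 5
    )),
    "positive"
  )
  expect_error(
    as_cs1_survey(data.frame(
      respondent_id = 1, vas_no_chemo = 90,
      vas_first_line = 120, vas_second_line = 5
    )),
    "\\[0, 100\\]"
  )
  expect_error(relative_value(0, 10), "anchor")
})

test_that("the toxicity ratio is invariant to rescaling a respondent's scores", {
  set.seed(5)
  for (i in 1:20) {
    nc <- runif(1, 50, 100)
    fl <- runif(1, 10, nc)
    sl <- runif(1, 10, nc)
    k <- runif(1, 0.2, 1.0)
    expect_equal(
      relative_value(nc, fl, digits = NULL),
      relative_value(k * nc, k * fl, digits = NULL),
      tolerance = 1e-12
    )
    expect_equal(
      relative_value(nc, sl, digits = NULL) / relative_value(nc, fl, digits = NULL),
      relative_value(k * nc, k * sl, digits = NULL) /
        relative_value(k * nc, k * fl, digits = NULL),
      tolerance = 1e-12
    )
  }
})

test_that("summaries from raw scores equal summaries from printed relative values", {
  survey <- cs1_vas_survey()
  rv <- survey_relative_values(survey)
  # recompute the arm statistics directly from the tabulated columns
  expect_equal(mean(rv$rel_first_line), summarize_survey(survey)$arms$mean[1],
    tolerance = 1e-12
  )
  expect_equal(sd(rv$rel_second_line), summarize_survey(survey)$arms$sd[2],
    tolerance = 1e-12
  )
})
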