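test_that("base-case reports carry the rollback numbers and the caveat", {
  cmp <- run_base_case()
  expect_equal(cmp$surveillance, 1.3419, tolerance = 1e-12)

  out <- withr::local_tempdir()
  run_base_case(base_parameters(), out_dir = out)
  js <- jsonlite::read_json(file.path(out, "base_case.json"), simplifyVector = TRUE)
  expect_equal(js$expected_exposure$surveillance, 1.3419, tolerance = 1e-12)
  expect_identical(js$preferred, "risk_adapted")
  expect_match(js$note, "0.7965")
  txt <- readLines(file.path(out, "base_case.txt"))
  expect_true(any(grepl("1.3419", txt, fixed = TRUE)))
  # the 4-dp display of the risk-adapted expectation matches the JSON value
  expect_true(any(grepl(
    sprintf("%.4f", js$expected_exposure$risk_adapted), txt,
    fixed = TRUE
  )))

  # overrides flow through: poor primary chemotherapy flips the preference
  flipped <- run_base_case(parameter_set(pRelapsePostPrimChemo = 0.30))
  expect_identical(flipped$preferred, "surveillance")
  expect_identical(run_base_case(parameter_set(pLowRisk = 1))$preferred, "indifferent")
})

test_that("the replication bundle is complete, indexed and deterministic", {
  out <- withr::local_tempdir()
  idx <- run_full_replication(file.path(out, "run1"), grid_size = 3L)
  expect_true(idx$ok)
  expect_length(idx$errors, 0L)

  # every indexed file exists
  files <- unlist(idx$files, use.names = FALSE)
  expect_true(all(file.exists(file.path(out, "run1", files))))
  expect_length(grep("^oneway_", files), 6L)
  expect_length(grep("^twoway_", files), 6L)

  thr <- jsonlite::read_json(
    file.path(out, "run1", "thresholds.json"),
    simplifyVector = TRUE
  )
  expect_equal(thr$pRelapsePostPrimChemo$display, 0.287)
  expect_equal(thr$pRelapseHighrisk$display, 0.363)

  summ <- jsonlite::read_json(
    file.path(out, "run1", "survey_summary.json"),
    simplifyVector = TRUE
  )
  expect_equal(round_half_up(summ$arms$mean[1], 3), 0.841)
  expect_equal(round_half_up(summ$arms$mean[2], 3), 0.635)
  expect_equal(summ$toxicity_ratio_1dp, 1.3)

  # key numbers in the index match the artifact files (no report-only numbers)
  expect_equal(idx$results$thresholds$pRelapsePostPrimChemo$display, 0.287)
  expect_equal(idx$results$base_case$surveillance, 1.3419, tolerance = 1e-12)

  # byte-identical re-run
  run_full_replication(file.path(out, "run2"), grid_size = 3L)
  for (f in c(files, "index.json")) {
    expect_identical(
      readLines(file.path(out, "run1", f)),
      readLines(file.path(out, "run2", f)),
      info = f
    )
  }
})
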