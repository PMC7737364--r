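#' Read a VAS toxicity-elicitation survey
#'
#' Loads a survey in the standard CSV layout: one row per respondent with
#' columns `respondent_id`, `vas_no_chemo`, `vas_first_line`,
#' `vas_second_line` — raw visual-analog-scale scores on 0-100 where higher
#' means a more desirable health state. The no-chemotherapy score is the
#' respondent's anchor and must be positive.
#'
#' @param path path to the CSV file.
#' @return a data frame of class `cs1_survey`.
#' @seealso [cs1_vas_survey()] for the packaged 24-respondent survey.
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_cs1_survey(df)
}

#' @rdname read_survey
#' @param df a data frame with the survey columns.
#' @export
as_cs1_survey <- function(df) {
  needed <- c("respondent_id", "vas_no_chemo", "vas_first_line", "vas_second_line")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("survey is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  scores <- df[, c("vas_no_chemo", "vas_first_line", "vas_second_line")]
  if (any(!vapply(scores, is.numeric, logical(1L)))) {
    stop("VAS scores must be numeric", call. = FALSE)
  }
  if (any(as.matrix(scores) < 0 | as.matrix(scores) > 100)) {
    stop("VAS scores must lie in [0, 100]", call. = FALSE)
  }
  if (any(df$vas_no_chemo <= 0)) {
    stop("no-chemotherapy VAS score must be positive (it anchors the ratios)",
      call. = FALSE
    )
  }
  class(df) <- c("cs1_survey", "data.frame")
  df
}

#' The packaged elicitation survey
#'
#' VAS scores from the 24 urological oncologists interviewed about the
#' toxicity of chemotherapy for pediatric testicular cancer; the data behind
#' the shipped `tSecondChemo = 1.3` toxicity multiplier.
#'
#' @return a `cs1_survey` data frame with 24 rows.
#' @export
cs1_vas_survey <- function() {
  read_survey(system.file("extdata", "vas_survey.csv",
    package = "cs1decision", mustWork = TRUE
  ))
}

#' Relative value of a chemotherapy health state
#'
#' The respondent-level utility of a treatment arm: the arm's VAS score
#' divided by the same respondent's no-chemotherapy score. Values are
#' rounded half-up to `digits` decimals for tabulation (pass `digits = NULL`
#' for full precision).
#'
#' @param no_chemo anchor VAS score(s), > 0.
#' @param arm_score VAS score(s) of the chemotherapy arm.
#' @param digits decimals for tabulation (default 3), or `NULL`.
#' @return numeric vector of relative values.
#' @export
#' @examples
#' relative_value(95, 85) # 0.895
relative_value <- function(no_chemo, arm_score, digits = 3) {
  if (any(no_chemo == 0)) {
    stop("no-chemotherapy VAS score of 0 cannot anchor a relative value",
      call. = FALSE
    )
  }
  rv <- arm_score / no_chemo
  if (is.null(digits)) rv else round_half_up(rv, digits)
}

#' @rdname relative_value
#' @param survey a `cs1_survey` data frame.
#' @return `survey_relative_values()` returns the survey with added columns
#'   `rel_first_line` and `rel_second_line`.
#' @export
survey_relative_values <- function(survey, digits = 3) {
  survey$rel_first_line <- relative_value(
    survey$vas_no_chemo, survey$vas_first_line, digits
  )
  survey$rel_second_line <- relative_value(
    survey$vas_no_chemo, survey$vas_second_line, digits
  )
  survey
}

#' Summarize an elicitation survey
#'
#' Aggregates the tabulated (3-decimal) relative values per arm: sample
#' size, mean, sample (n-1) standard deviation and a Student-t 95%
#' confidence interval for the mean. The toxicity ratio is the first-line
#' mean divided by the second-line mean, computed from the 3-decimal
#' tabulated means so that the shipped survey gives exactly 0.841/0.635.
#'
#' @param survey a `cs1_survey` data frame with at least 2 rows.
#' @param conf_level confidence level for the t interval.
#' @return an object of class `cs1_survey_summary`: a list with `n`, `arms`
#'   (data frame: `arm`, `n`, `mean`, `sd`, `ci_low`, `ci_high`),
#'   `toxicity_ratio` (full precision) and `conf_level`.
#' @export
#' @examples
#' summarize_survey(cs1_vas_survey())
summarize_survey <- function(survey, conf_level = 0.95) {
  survey <- as_cs1_survey(as.data.frame(survey))
  n <- nrow(survey)
  if (n < 2L) {
    stop("at least 2 respondents are needed to summarize a survey",
      call. = FALSE
    )
  }
  rv <- survey_relative_values(survey, digits = 3)
  one_arm <- function(arm, x) {
    m <- mean(x)
    s <- sd(x)
    half <- qt(1 - (1 - conf_level) / 2, df = n - 1L) * s / sqrt(n)
    data.frame(
      arm = arm, n = n, mean = m, sd = s,
      ci_low = m - half, ci_high = m + half,
      stringsAsFactors = FALSE
    )
  }
  arms <- rbind(
    one_arm("first_line", rv$rel_first_line),
    one_arm("second_line", rv$rel_second_line)
  )
  mean_first <- round_half_up(arms$mean[1L], 3)
  mean_second <- round_half_up(arms$mean[2L], 3)
  if (mean_second <= 0) stop("second-line mean must be positive", call. = FALSE)
  structure(
    list(
      n = n, arms = arms,
      toxicity_ratio = mean_first / mean_second,
      conf_level = conf_level
    ),
    class = "cs1_survey_summary"
  )
}

#' Derive the second-line toxicity multiplier
#'
#' The model's `tSecondChemo` parameter: how much more toxic one
#' second-line cycle is than one first-line cycle, estimated as the ratio
#' of the tabulated mean relative values (first-line / second-line) and
#' rounded half-up to `digits` decimals (default 1, giving the shipped
#' 1.3; `digits = NULL` returns full precision, 1.3244 for the packaged
#' survey).
#'
#' @param summary a `cs1_survey_summary`.
#' @param digits decimals to round to, or `NULL` for full precision.
#' @return the toxicity multiplier (scalar).
#' @export
#' @examples
#' derive_toxicity_ratio(summarize_survey(cs1_vas_survey())) # 1.3
derive_toxicity_ratio <- function(summary, digits = 1) {
  stopifnot(inherits(summary, "cs1_survey_summary"))
  if (is.null(digits)) summary$toxicity_ratio else round_half_up(summary$toxicity_ratio, digits)
}

#' @export
print.cs1_survey_summary <- function(x, ...) {
  cat(sprintf("VAS elicitation survey: %d respondents\n", x$n))
  for (i in seq_len(nrow(x$arms))) {
    a <- x$arms[i, ]
    cat(sprintf(
      "  %-12s mean %.3f, SD %.3f, %d%% CI %.3f-%.3f\n",
      a$arm, a$mean, a$sd, round(100 * x$conf_level), a$ci_low, a$ci_high
    ))
  }
  cat(sprintf(
    "  toxicity ratio (first/second line): %.4f (%.1f at 1 decimal)\n",
    x$toxicity_ratio, round_half_up(x$toxicity_ratio, 1)
  ))
  invisible(x)
}
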