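#' Configuration for the synthetic survey generator
#'
#' Describes a simulated VAS elicitation survey: each respondent gets a
#' no-chemotherapy anchor score drawn uniformly from integer `no_chemo_bounds`
#' (default 85-100, the typical anchor range of the packaged survey), and
#' per-arm relative values drawn from normal distributions truncated to
#' (0, 1\] with the given target means and spreads (defaults: the packaged
#' survey's 0.841/0.081 first line, 0.635/0.151 second line). Arm scores are
#' mapped back to integer VAS scores, matching how real respondents mark an
#' integer scale.
#'
#' @param n_respondents number of simulated respondents.
#' @param mean_first,sd_first target mean (in (0, 1\]) and spread (>= 0) of
#'   first-line relative values.
#' @param mean_second,sd_second likewise for second-line.
#' @param no_chemo_bounds integer anchor-score bounds within \[1, 100\].
#' @return an object of class `cs1_survey_config`.
#' @export
survey_config <- function(n_respondents = 24L,
                          mean_first = 0.841, sd_first = 0.081,
                          mean_second = 0.635, sd_second = 0.151,
                          no_chemo_bounds = c(85L, 100L)) {
  n_respondents <- as.integer(n_respondents)
  if (n_respondents < 1L) stop("need at least one respondent", call. = FALSE)
  for (m in c(mean_first, mean_second)) {
    if (!is.numeric(m) || m <= 0 || m > 1) {
      stop("target means must lie in (0, 1] (they are relative values)",
        call. = FALSE
      )
    }
  }
  if (sd_first < 0 || sd_second < 0) stop("spreads must be >= 0", call. = FALSE)
  b <- as.integer(no_chemo_bounds)
  if (length(b) != 2L || b[1L] > b[2L] || b[1L] < 1L || b[2L] > 100L) {
    stop("no_chemo_bounds must be increasing integers within [1, 100]",
      call. = FALSE
    )
  }
  structure(
    list(
      n_respondents = n_respondents,
      mean_first = mean_first, sd_first = sd_first,
      mean_second = mean_second, sd_second = sd_second,
      no_chemo_bounds = b
    ),
    class = "cs1_survey_config"
  )
}

# Normal truncated to (0, 1] by rejection; sd = 0 degenerates to the mean.
.rtrunc_unit <- function(n, mean, sd) {
  if (sd == 0) {
    return(rep(mean, n))
  }
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0 | out > 1)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0 | out[bad] > 1]
  }
  out
}

#' Generate a synthetic VAS survey
#'
#' Draws a reproducible simulated survey under `config` (see
#' [survey_config()]). The realized relative values differ from the latent
#' draws by at most the integer-score quantization (0.5 divided by the
#' anchor score), so arm summaries recover the configured means as the
#' sample grows.
#'
#' @param config a [survey_config()].
#' @param seed integer seed for reproducibility (the caller's RNG state is
#'   left untouched); `NULL` uses the current RNG state.
#' @return a `cs1_survey` data frame with `config$n_respondents` rows.
#' @export
#' @examples
#' s <- generate_survey(survey_config(n_respondents = 24), seed = 1)
#' summarize_survey(s)
generate_survey <- function(config = survey_config(), seed = NULL) {
  stopifnot(inherits(config, "cs1_survey_config"))
  with_seed(seed, {
    n <- config$n_respondents
    b <- config$no_chemo_bounds
    anchor <- sample(seq(b[1L], b[2L]), n, replace = TRUE)
    rel_first <- .rtrunc_unit(n, config$mean_first, config$sd_first)
    rel_second <- .rtrunc_unit(n, config$mean_second, config$sd_second)
    clamp <- function(x) pmax(0L, pmin(100L, as.integer(round(x))))
    as_cs1_survey(data.frame(
      respondent_id = seq_len(n),
      vas_no_chemo = anchor,
      vas_first_line = clamp(rel_first * anchor),
      vas_second_line = clamp(rel_second * anchor)
    ))
  })
}

#' Monte-Carlo microsimulation of a patient cohort
#'
#' Walks `n` virtual patients through a strategy, sampling each branching
#' event (risk group, relapse, post-salvage progression) independently
#' rather than enumerating path probabilities — so the simulation is
#' structurally independent of the rollback code and serves as its
#' stochastic oracle. Each patient accrues toxicity-weighted cycles along
#' the sampled path.
#'
#' @param strategy `"surveillance"` or `"risk_adapted"`.
#' @param params a valid [parameter_set()].
#' @param n number of simulated patients (>= 1).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return an object of class `cs1_cohort`: a list with `strategy`, `n`,
#'   `mean_exposure`, `se` (sample SD / sqrt(n)) and `path_counts`, a named
#'   integer vector over the strategy's terminal paths summing to `n`.
#' @export
#' @examples
#' simulate_cohort("surveillance", base_parameters(), n = 10000, seed = 1)
simulate_cohort <- function(strategy = c("surveillance", "risk_adapted"),
                            params = base_parameters(), n, seed = NULL) {
  strategy <- match.arg(strategy)
  assert_valid_parameters(params)
  n <- as.integer(n)
  if (n < 1L) stop("cohort size must be at least 1", call. = FALSE)
  with_seed(seed, {
    low <- runif(n) < params$pLowRisk
    p_relapse <- if (strategy == "surveillance") {
      ifelse(low, params$pRelapseLowrisk, params$pRelapseHighrisk)
    } else {
      ifelse(low, params$pRelapseLowrisk, params$pRelapsePostPrimChemo)
    }
    relapse <- runif(n) < p_relapse
    progress <- relapse & (runif(n) < params$pRelapsePostSalvChemo)
    upfront <- if (strategy == "surveillance") 0 else ifelse(low, 0, params$nPrimaryCycles)
    exposure <- upfront +
      ifelse(relapse, params$nSalvageCycles, 0) +
      ifelse(progress, params$nSecondLineCycles * params$tSecondChemo, 0)

    group <- ifelse(low, "low", "high")
    outcome <- ifelse(!relapse, "no_relapse",
      ifelse(progress, "salvage_second_line", "salvage_cr")
    )
    levels <- as.vector(outer(c("low", "high"), c(
      "no_relapse", "salvage_cr", "salvage_second_line"
    ), paste, sep = ":"))
    path <- factor(paste(group, outcome, sep = ":"), levels = levels)

    structure(
      list(
        strategy = strategy, n = n,
        mean_exposure = mean(exposure),
        se = sd(exposure) / sqrt(n),
        path_counts = table(path)
      ),
      class = "cs1_cohort"
    )
  })
}

#' @export
print.cs1_cohort <- function(x, ...) {
  cat(sprintf(
    "Simulated cohort (%s): n = %d, mean exposure %.4f cycles (SE %.4f)\n",
    x$strategy, x$n, x$mean_exposure, x$se
  ))
  counts <- x$path_counts[x$path_counts > 0]
  for (nm in names(counts)) cat(sprintf("  %-26s %d\n", nm, counts[[nm]]))
  invisible(x)
}
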