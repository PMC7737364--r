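# Shared sub-trees of the two strategy arms -----------------------------------

# Salvage chemotherapy after a detected relapse: 3 cycles of PEB, and if no
# complete response (probability pRelapsePostSalvChemo), 3 further cycles of
# second-line VIP at toxicity weight tSecondChemo each. Second-line
# chemotherapy is terminal with certain success.
.salvage_subtree <- function(extra = NULL) {
  second_line <- expr_product(
    expr_param("nSecondLineCycles"), expr_param("tSecondChemo")
  )
  payoff <- function(...) {
    terms <- c(if (!is.null(extra)) list(extra), list(...))
    if (length(terms) == 1L) terms[[1L]] else do.call(expr_sum, terms)
  }
  chance_node(
    branch(
      expr_param("pRelapsePostSalvChemo"),
      terminal_node(payoff(expr_param("nSalvageCycles"), second_line))
    ),
    branch(
      expr_complement(expr_param("pRelapsePostSalvChemo")),
      terminal_node(payoff(expr_param("nSalvageCycles")))
    )
  )
}

# Surveillance within one risk group: relapse triggers salvage, no relapse
# means no chemotherapy at all.
.surveillance_arm <- function(p_relapse) {
  chance_node(
    branch(expr_param(p_relapse), .salvage_subtree()),
    branch(expr_complement(expr_param(p_relapse)), terminal_node(0))
  )
}

#' Build the surveillance strategy tree
#'
#' All patients are observed after orchiectomy. The cohort splits into
#' low-risk (`pLowRisk`) and high-risk (`1 - pLowRisk`) groups; a relapse
#' during follow-up (`pRelapseLowrisk` / `pRelapseHighrisk`) is treated with
#' 3 salvage PEB cycles, and failure of salvage (`pRelapsePostSalvChemo`)
#' adds 3 second-line VIP cycles at weight `tSecondChemo` each. Patients who
#' never relapse receive no chemotherapy.
#'
#' @return a `cs1_tree` with strategy label `"surveillance"`.
#' @seealso [build_risk_adapted_tree()], [closed_form_exposure()]
#' @export
build_surveillance_tree <- function() {
  decision_tree("surveillance", chance_node(
    branch(expr_param("pLowRisk"), .surveillance_arm("pRelapseLowrisk")),
    branch(
      expr_complement(expr_param("pLowRisk")),
      .surveillance_arm("pRelapseHighrisk")
    )
  ))
}

#' Build the risk-adapted strategy tree
#'
#' Low-risk patients undergo surveillance exactly as in
#' [build_surveillance_tree()]. High-risk patients instead receive 1 cycle
#' of primary (adjuvant) PEB with certainty; a subsequent relapse
#' (`pRelapsePostPrimChemo`) is treated with the same salvage-then-
#' second-line cascade, accruing its toxicity on top of the primary cycle.
#'
#' @return a `cs1_tree` with strategy label `"risk_adapted"`.
#' @export
build_risk_adapted_tree <- function() {
  high_risk <- chance_node(
    branch(
      expr_param("pRelapsePostPrimChemo"),
      .salvage_subtree(extra = expr_param("nPrimaryCycles"))
    ),
    branch(
      expr_complement(expr_param("pRelapsePostPrimChemo")),
      terminal_node(expr_param("nPrimaryCycles"))
    )
  )
  decision_tree("risk_adapted", chance_node(
    branch(expr_param("pLowRisk"), .surveillance_arm("pRelapseLowrisk")),
    branch(expr_complement(expr_param("pLowRisk")), high_risk)
  ))
}

#' Path to a packaged strategy tree document
#'
#' The two strategy trees also ship as JSON documents (the schema of
#' [serialize_tree()]) so they can be inspected or loaded without running R
#' code; [read_tree()] on these files yields trees identical in value to the
#' builders.
#'
#' @param strategy `"surveillance"` or `"risk_adapted"`.
#' @return a file path.
#' @export
cs1_tree_file <- function(strategy = c("surveillance", "risk_adapted")) {
  strategy <- match.arg(strategy)
  system.file("extdata", paste0(strategy, ".json"),
    package = "cs1decision", mustWork = TRUE
  )
}

# Closed-form expected exposures --------------------------------------------
#
# Let R = nSalvageCycles + pRelapsePostSalvChemo * nSecondLineCycles *
# tSecondChemo be the expected toxicity of the salvage cascade. Then
#   surveillance  = [pLowRisk*pRelapseLowrisk +
#                    (1-pLowRisk)*pRelapseHighrisk] * R
#   risk_adapted  = pLowRisk*pRelapseLowrisk*R +
#                   (1-pLowRisk)*(nPrimaryCycles + pRelapsePostPrimChemo*R)
# These are pure arithmetic, vectorize over parameter fields, and serve as
# the analytic oracle for the tree engine.

.salvage_cascade_toxicity <- function(p) {
  p$nSalvageCycles +
    p$pRelapsePostSalvChemo * p$nSecondLineCycles * p$tSecondChemo
}

.closed_form <- function(strategy, p) {
  R <- .salvage_cascade_toxicity(p)
  if (strategy == "surveillance") {
    (p$pLowRisk * p$pRelapseLowrisk + (1 - p$pLowRisk) * p$pRelapseHighrisk) * R
  } else {
    p$pLowRisk * p$pRelapseLowrisk * R +
      (1 - p$pLowRisk) * (p$nPrimaryCycles + p$pRelapsePostPrimChemo * R)
  }
}

#' Closed-form expected chemotherapy exposure
#'
#' Algebraic reduction of the strategy trees (see Details), equal to
#' [rollback()] of the corresponding tree to within 1e-12. Used as an
#' independent oracle for the tree engine and as the fast evaluator inside
#' parameter sweeps.
#'
#' @details With \eqn{R = n_{salv} + p_{salv} \, n_{2nd} \, t_{2nd}} the
#' expected toxicity of the salvage cascade,
#' \deqn{E_{surv} = [p_{low} p_{rel,low} + (1-p_{low}) p_{rel,high}] R}
#' \deqn{E_{RA} = p_{low} p_{rel,low} R + (1-p_{low})(n_{prim} + p_{prim} R)}
#'
#' @param strategy `"surveillance"` or `"risk_adapted"`.
#' @param params a valid [parameter_set()].
#' @return expected toxicity-weighted cycles (scalar).
#' @export
#' @examples
#' closed_form_exposure("surveillance", base_parameters()) # 1.3419
closed_form_exposure <- function(strategy = c("surveillance", "risk_adapted"),
                                 params = base_parameters()) {
  strategy <- match.arg(strategy)
  assert_valid_parameters(params)
  .closed_form(strategy, params)
}

#' Compare the two management strategies
#'
#' Rolls back both strategy trees under one parameter set and reports the
#' expected exposures, their difference (surveillance minus risk-adapted)
#' and the preferred (lower-exposure) strategy; differences within 1e-12
#' are labelled `"indifferent"`.
#'
#' @param params a valid [parameter_set()].
#' @param engine `"rollback"` evaluates the trees (default); `"closed_form"`
#'   uses the algebraic expressions (identical within 1e-12, faster).
#' @return an object of class `cs1_comparison`: a list with `surveillance`,
#'   `risk_adapted`, `difference`, `preferred` and the `params` used.
#' @export
#' @examples
#' compare_strategies(base_parameters())
compare_strategies <- function(params = base_parameters(),
                               engine = c("rollback", "closed_form")) {
  engine <- match.arg(engine)
  assert_valid_parameters(params)
  if (engine == "rollback") {
    surv <- rollback(build_surveillance_tree(), params)
    ra <- rollback(build_risk_adapted_tree(), params)
  } else {
    surv <- .closed_form("surveillance", params)
    ra <- .closed_form("risk_adapted", params)
  }
  diff <- surv - ra
  structure(
    list(
      surveillance = surv, risk_adapted = ra, difference = diff,
      preferred = .pref_label(diff), params = params
    ),
    class = "cs1_comparison"
  )
}

#' @export
print.cs1_comparison <- function(x, ...) {
  cat("Expected toxicity-weighted chemotherapy exposure\n")
  cat(sprintf("  surveillance : %.4f cycles\n", x$surveillance))
  cat(sprintf("  risk-adapted : %.4f cycles\n", x$risk_adapted))
  cat(sprintf("  difference   : %.4f (surveillance - risk-adapted)\n", x$difference))
  cat(sprintf("  preferred    : %s\n", x$preferred))
  invisible(x)
}
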