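#' Decision-tree nodes
#'
#' A strategy is modeled as a finite, acyclic tree of chance nodes and
#' terminal nodes. A terminal node carries a payoff expression (toxicity-
#' weighted chemotherapy cycles accrued on that path); a chance node carries
#' an ordered list of branches, each a probability expression plus a child
#' node. Branch probabilities must sum to 1 (within 1e-12) for every valid
#' parameter set — this is asserted on every evaluation.
#'
#' The decision node itself is not materialized: each strategy is a separate
#' [decision_tree()] and strategies are compared externally (see
#' [compare_strategies()]), mirroring how the model weighs two fixed
#' protocols rather than optimizing within one tree.
#'
#' @param payoff a payoff expression (see [tree_expressions]); must evaluate
#'   to a finite non-negative number for any valid parameter set.
#' @param p a probability expression.
#' @param child a node.
#' @param ... for `chance_node()`, two or more [branch()] objects.
#' @param strategy strategy label; the shipped model uses `"surveillance"`
#'   and `"risk_adapted"`, arbitrary labels are allowed for user trees.
#' @param root the root node.
#' @return `terminal_node()` and `chance_node()` return nodes;
#'   `decision_tree()` returns a `cs1_tree`.
#' @name decision_tree_nodes
#' @seealso [rollback()], [serialize_tree()]
#' @examples
#' # 30% chance of payoff 10, else nothing; expectation 3
#' t <- decision_tree("toy", chance_node(
#'   branch(0.3, terminal_node(10)),
#'   branch(expr_complement(0.3), terminal_node(0))
#' ))
#' rollback(t, base_parameters())
NULL

#' @rdname decision_tree_nodes
#' @export
terminal_node <- function(payoff) {
  structure(list(type = "terminal", payoff = payoff),
    class = c("cs1_terminal", "cs1_node")
  )
}

#' @rdname decision_tree_nodes
#' @export
branch <- function(p, child) {
  if (!inherits(child, "cs1_node")) {
    stop("branch child must be a terminal_node() or chance_node()", call. = FALSE)
  }
  list(p = p, child = child)
}

#' @rdname decision_tree_nodes
#' @export
chance_node <- function(...) {
  branches <- list(...)
  if (length(branches) < 2L) {
    stop("a chance node needs at least two branches", call. = FALSE)
  }
  ok <- vapply(
    branches,
    function(b) is.list(b) && identical(names(b), c("p", "child")),
    logical(1L)
  )
  if (!all(ok)) stop("chance_node() arguments must be branch() objects", call. = FALSE)
  structure(list(type = "chance", branches = branches),
    class = c("cs1_chance", "cs1_node")
  )
}

#' @rdname decision_tree_nodes
#' @export
decision_tree <- function(strategy, root) {
  stopifnot(is.character(strategy), length(strategy) == 1L, nzchar(strategy))
  if (!inherits(root, "cs1_node")) {
    stop("root must be a terminal_node() or chance_node()", call. = FALSE)
  }
  structure(list(strategy = strategy, root = root), class = "cs1_tree")
}

#' Expected-value rollback of a decision tree
#'
#' Computes the probability-weighted sum of terminal payoffs by folding the
#' tree from the leaves upward — the standard evaluation of a decision tree.
#' At every chance node the branch probabilities are evaluated under
#' `params`, required to lie in \[0, 1\] and to sum to 1 within `tol`;
#' violations abort with the offending node's path.
#'
#' @param tree a [decision_tree()].
#' @param params a valid [parameter_set()].
#' @param tol absolute tolerance for the probability-mass check.
#' @return the expected payoff in toxicity-weighted chemotherapy cycles
#'   (a non-negative scalar).
#' @export
#' @examples
#' rollback(build_surveillance_tree(), base_parameters()) # 1.3419
rollback <- function(tree, params, tol = .cs1_tol) {
  if (!inherits(tree, "cs1_tree")) stop("not a decision tree", call. = FALSE)
  assert_valid_parameters(params)
  .roll <- function(node, path, depth) {
    if (depth > 1000L) {
      stop("tree deeper than 1000 levels at ", path,
        " - malformed (possibly cyclic) structure",
        call. = FALSE
      )
    }
    if (node$type == "terminal") {
      v <- eval_expr(node$payoff, params)
      if (!is.finite(v) || v < 0) {
        stop("terminal payoff at ", path, " evaluates to ", v,
          " (must be finite and non-negative)",
          call. = FALSE
        )
      }
      return(v)
    }
    probs <- vapply(
      node$branches,
      function(b) eval_expr(b$p, params), numeric(1L)
    )
    if (any(probs < -tol | probs > 1 + tol)) {
      stop("branch probability outside [0, 1] at ", path, call. = FALSE)
    }
    if (abs(sum(probs) - 1) > tol) {
      stop(sprintf(
        "branch probabilities at %s sum to %.15g, not 1", path, sum(probs)
      ), call. = FALSE)
    }
    kids <- vapply(seq_along(node$branches), function(i) {
      .roll(
        node$branches[[i]]$child,
        sprintf("%s/branches[%d]/child", path, i), depth + 1L
      )
    }, numeric(1L))
    sum(probs * kids)
  }
  .roll(tree$root, "root", 1L)
}

.count_nodes <- function(node) {
  if (node$type == "terminal") {
    return(c(chance = 0L, terminal = 1L))
  }
  Reduce(`+`, lapply(node$branches, function(b) .count_nodes(b$child))) +
    c(chance = 1L, terminal = 0L)
}

#' @export
print.cs1_tree <- function(x, ...) {
  n <- .count_nodes(x$root)
  cat(sprintf(
    "Decision tree '%s': %d chance node(s), %d terminal path(s)\n",
    x$strategy, n[["chance"]], n[["terminal"]]
  ))
  invisible(x)
}
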