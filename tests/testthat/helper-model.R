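# Shared generators for property-style tests.

# A random valid parameter set drawn from the full validity domain.
random_params <- function() {
  parameter_set(
    pLowRisk = runif(1),
    pRelapseLowrisk = runif(1),
    pRelapseHighrisk = runif(1),
    pRelapsePostPrimChemo = runif(1),
    pRelapsePostSalvChemo = runif(1),
    tSecondChemo = runif(1, 0.5, 2.5),
    nPrimaryCycles = sample(1:3, 1),
    nSalvageCycles = sample(1:4, 1),
    nSecondLineCycles = sample(1:4, 1)
  )
}

# A random small chance/terminal tree with literal split probabilities and
# payoffs mixing literals, parameter references and products.
random_tree <- function(max_depth = 3L) {
  random_payoff <- function() {
    switch(sample(3L, 1L),
      runif(1, 0, 10),
      expr_param(sample(c("nSalvageCycles", "nSecondLineCycles"), 1L)),
      expr_product(runif(1, 0, 3), expr_param("tSecondChemo"))
    )
  }
  random_node <- function(depth) {
    if (depth >= max_depth || runif(1) < 0.4) {
      return(terminal_node(random_payoff()))
    }
    p <- round(runif(1, 0.05, 0.95), 3)
    chance_node(
      branch(p, random_node(depth + 1L)),
      branch(expr_complement(p), random_node(depth + 1L))
    )
  }
  decision_tree("random", random_node(0L))
}

# Wrap every terminal payoff in a product with `factor`.
scale_payoffs <- function(tree, factor) {
  scale_node <- function(node) {
    if (node$type == "terminal") {
      return(terminal_node(expr_product(factor, node$payoff)))
    }
    do.call(chance_node, lapply(node$branches, function(b) {
      branch(b$p, scale_node(b$child))
    }))
  }
  decision_tree(tree$strategy, scale_node(tree$root))
}
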