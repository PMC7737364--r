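#' Serialize a decision tree to JSON
#'
#' Trees round-trip through a small JSON schema:
#' \preformatted{
#' {"strategy": str, "root": node}
#' node = {"type": "chance", "branches": [{"p": expr, "child": node}, ...]}
#'      | {"type": "terminal", "payoff": expr}
#' expr = number | {"param": name} | {"complement": expr}
#'      | {"product": [expr, expr]} | {"sum": [expr, ...]}
#' }
#' The packaged `surveillance.json` and `risk_adapted.json` under
#' `extdata/` are instances of this schema.
#'
#' @param tree a [decision_tree()].
#' @param pretty indent the JSON for readability.
#' @return `serialize_tree()` returns a JSON string; `write_tree()` writes it
#'   to `path` and returns `path` invisibly.
#' @seealso [deserialize_tree()]
#' @export
serialize_tree <- function(tree, pretty = TRUE) {
  if (!inherits(tree, "cs1_tree")) stop("not a decision tree", call. = FALSE)
  doc <- list(strategy = tree$strategy, root = .node_to_doc(tree$root))
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = pretty)
}

#' @rdname serialize_tree
#' @param path file path.
#' @export
write_tree <- function(tree, path, pretty = TRUE) {
  writeLines(serialize_tree(tree, pretty = pretty), path)
  invisible(path)
}

.node_to_doc <- function(node) {
  if (node$type == "terminal") {
    list(type = "terminal", payoff = node$payoff)
  } else {
    list(type = "chance", branches = lapply(node$branches, function(b) {
      list(p = b$p, child = .node_to_doc(b$child))
    }))
  }
}

#' Deserialize a decision tree from JSON
#'
#' Parses and validates a tree document against the schema described in
#' [serialize_tree()]; violations are reported with the path of the
#' offending node. As a cheap structural check, a chance node whose branch
#' probabilities are all numeric literals must have them sum to 1 within
#' 1e-12 (parameter-dependent probabilities are checked at [rollback()]
#' time instead).
#'
#' @param text a JSON string (or vector of lines).
#' @return a `cs1_tree` that evaluates identically to the serialized tree
#'   under any parameter set.
#' @export
deserialize_tree <- function(text) {
  text <- paste(text, collapse = "\n")
  if (!nzchar(trimws(text))) stop("empty tree document", call. = FALSE)
  doc <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) {
      stop("tree document is not valid JSON: ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  if (!is.list(doc) || is.null(doc$strategy) || is.null(doc$root)) {
    stop("tree document must have 'strategy' and 'root' fields", call. = FALSE)
  }
  if (!is.character(doc$strategy) || length(doc$strategy) != 1L) {
    stop("'strategy' must be a string", call. = FALSE)
  }
  errors <- character()
  root <- .node_from_doc(doc$root, "root", collect = function(msg) {
    errors <<- c(errors, msg)
  })
  if (length(errors) > 0L) {
    stop("invalid tree document:\n  ", paste(errors, collapse = "\n  "),
      call. = FALSE
    )
  }
  decision_tree(doc$strategy, root)
}

#' @rdname deserialize_tree
#' @param path file path to a JSON tree document.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  deserialize_tree(readLines(path, warn = FALSE))
}

.node_from_doc <- function(x, path, collect) {
  bad <- function(msg) {
    collect(sprintf("%s: %s", path, msg))
    terminal_node(0) # placeholder so parsing can continue
  }
  if (!is.list(x) || is.null(x$type)) {
    return(bad("node must be an object with a 'type' field"))
  }
  if (identical(x$type, "terminal")) {
    if (is.null(x$payoff)) {
      return(bad("terminal node lacks 'payoff'"))
    }
    payoff <- .expr_from_doc(x$payoff)
    problems <- validate_expr(payoff, paste0(path, "/payoff"))
    if (length(problems) > 0L) {
      for (p in problems) collect(p)
      return(terminal_node(0))
    }
    return(terminal_node(payoff))
  }
  if (identical(x$type, "chance")) {
    if (!is.list(x$branches) || length(x$branches) < 2L) {
      return(bad("chance node needs a 'branches' array of length >= 2"))
    }
    branches <- vector("list", length(x$branches))
    for (i in seq_along(x$branches)) {
      b <- x$branches[[i]]
      bpath <- sprintf("%s/branches[%d]", path, i)
      if (!is.list(b) || is.null(b$p) || is.null(b$child)) {
        collect(sprintf("%s: branch needs 'p' and 'child'", bpath))
        branches[[i]] <- branch(1, terminal_node(0))
        next
      }
      p <- .expr_from_doc(b$p)
      for (prob in validate_expr(p, paste0(bpath, "/p"))) collect(prob)
      child <- .node_from_doc(b$child, paste0(bpath, "/child"), collect)
      branches[[i]] <- branch(if (is.numeric(p) || is.list(p)) p else 1, child)
    }
    # literal-only mass check: catches typo'd probabilities at parse time
    lit <- vapply(branches, function(b) is.numeric(b$p), logical(1L))
    if (all(lit)) {
      mass <- sum(vapply(branches, function(b) b$p, numeric(1L)))
      if (abs(mass - 1) > .cs1_tol) {
        collect(sprintf(
          "%s: literal branch probabilities sum to %.15g, not 1", path, mass
        ))
      }
    }
    return(do.call(chance_node, branches))
  }
  bad(sprintf("unknown node type '%s'", format(x$type)))
}

# JSON -> internal expression. jsonlite(simplifyVector = FALSE) yields
# numbers as length-1 numerics and objects as named lists, which is already
# the internal form; only scalar unwrapping of singleton lists is needed.
.expr_from_doc <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  if (is.list(x) && length(x) == 1L && !is.null(names(x))) {
    key <- names(x)
    val <- x[[1L]]
    return(switch(key,
      param = list(param = if (is.character(val)) val else format(val)),
      complement = list(complement = .expr_from_doc(val)),
      product = list(product = lapply(val, .expr_from_doc)),
      sum = list(sum = lapply(val, .expr_from_doc)),
      x
    ))
  }
  x
}
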