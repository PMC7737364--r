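#' Parameter-bound arithmetic expressions
#'
#' Probabilities and payoffs in a decision tree are small symbolic
#' expressions over the model parameters, evaluated at rollback time. The
#' grammar is deliberately minimal so that serialized trees stay auditable:
#'
#' * a bare number,
#' * `expr_param(name)` — a parameter reference,
#' * `expr_complement(e)` — `1 - e` (for the "other" branch of a chance node),
#' * `expr_product(a, b)` — product of exactly two expressions,
#' * `expr_sum(...)` — sum of one or more expressions (payoffs accrued along
#'   a path, e.g. salvage plus second-line toxicity).
#'
#' @param name parameter field name (a string).
#' @param e,a,b sub-expressions.
#' @param ... sub-expressions to sum.
#' @return an expression object (plain list / numeric scalar) understood by
#'   [rollback()] and the JSON tree schema.
#' @name tree_expressions
#' @examples
#' # toxicity of the salvage-then-second-line path:
#' expr_sum(
#'   expr_param("nSalvageCycles"),
#'   expr_product(expr_param("nSecondLineCycles"), expr_param("tSecondChemo"))
#' )
NULL

#' @rdname tree_expressions
#' @export
expr_param <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  list(param = name)
}

#' @rdname tree_expressions
#' @export
expr_complement <- function(e) list(complement = e)

#' @rdname tree_expressions
#' @export
expr_product <- function(a, b) list(product = list(a, b))

#' @rdname tree_expressions
#' @export
expr_sum <- function(...) {
  terms <- list(...)
  if (length(terms) < 1L) stop("expr_sum() needs at least one term", call. = FALSE)
  list(sum = terms)
}

# Evaluate an expression against a parameter set (any named list of
# numerics). Scalar parameters give scalar results; the arithmetic also
# vectorizes if a field holds a vector, which the sweep code exploits.
eval_expr <- function(e, params) {
  if (is.numeric(e)) {
    if (length(e) != 1L) stop("numeric expression must be a scalar", call. = FALSE)
    return(e)
  }
  if (!is.list(e) || length(e) != 1L || is.null(names(e))) {
    stop("malformed expression (expected number or single-keyed list)",
      call. = FALSE
    )
  }
  switch(names(e),
    param = {
      v <- params[[e$param]]
      if (is.null(v)) stop("unknown parameter '", e$param, "'", call. = FALSE)
      v
    },
    complement = 1 - eval_expr(e$complement, params),
    product = {
      eval_expr(e$product[[1L]], params) * eval_expr(e$product[[2L]], params)
    },
    sum = Reduce(`+`, lapply(e$sum, eval_expr, params = params)),
    stop("unknown expression type '", names(e), "'", call. = FALSE)
  )
}

# Structural validation; returns a character vector of problems, each
# prefixed with the node path for error reporting.
validate_expr <- function(e, path = "expr") {
  if (is.numeric(e)) {
    if (length(e) != 1L || !is.finite(e)) {
      return(sprintf("%s: numeric expression must be a finite scalar", path))
    }
    return(character())
  }
  if (!is.list(e) || length(e) != 1L || is.null(names(e)) ||
    !names(e) %in% c("param", "complement", "product", "sum")) {
    return(sprintf(
      "%s: expected a number or one of param/complement/product/sum", path
    ))
  }
  switch(names(e),
    param = {
      if (!is.character(e$param) || length(e$param) != 1L || !nzchar(e$param)) {
        sprintf("%s: 'param' must name a parameter field", path)
      } else {
        character()
      }
    },
    complement = validate_expr(e$complement, paste0(path, "/complement")),
    product = {
      if (!is.list(e$product) || length(e$product) != 2L) {
        sprintf("%s: 'product' must hold exactly two expressions", path)
      } else {
        c(
          validate_expr(e$product[[1L]], paste0(path, "/product[1]")),
          validate_expr(e$product[[2L]], paste0(path, "/product[2]"))
        )
      }
    },
    sum = {
      if (!is.list(e$sum) || length(e$sum) < 1L) {
        sprintf("%s: 'sum' must hold at least one expression", path)
      } else {
        unlist(lapply(seq_along(e$sum), function(i) {
          validate_expr(e$sum[[i]], sprintf("%s/sum[%d]", path, i))
        }))
      }
    }
  )
}
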