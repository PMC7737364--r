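#' Sweep range for a model parameter
#'
#' Describes the interval and grid over which a parameter is varied in a
#' sensitivity analysis. When bounds are omitted the full validity domain is
#' used: \[0, 1\] for probabilities and \[1, 2\] for `tSecondChemo` (the
#' elicited toxicity multiplier's analysis range); narrower literature
#' ranges can be passed explicitly.
#'
#' @param parameter name of a [parameter_set()] field (one of the five
#'   probabilities or `tSecondChemo`).
#' @param low,high sweep bounds, `low < high`, within the parameter's
#'   validity domain.
#' @param n grid size (default 101 points, giving smooth region plots at
#'   negligible cost).
#' @return an object of class `cs1_range`.
#' @export
#' @examples
#' param_range("pRelapseHighrisk", 0.38, 0.73)
param_range <- function(parameter, low = NULL, high = NULL, n = 101L) {
  sweepable <- c(.cs1_prob_fields, "tSecondChemo")
  if (!is.character(parameter) || length(parameter) != 1L ||
    !parameter %in% sweepable) {
    stop("'parameter' must be one of: ", paste(sweepable, collapse = ", "),
      call. = FALSE
    )
  }
  domain <- if (parameter == "tSecondChemo") c(1e-9, Inf) else c(0, 1)
  default <- if (parameter == "tSecondChemo") c(1, 2) else c(0, 1)
  if (is.null(low)) low <- default[1L]
  if (is.null(high)) high <- default[2L]
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1L, length(high) == 1L)
  if (!(low < high)) stop("'low' must be strictly below 'high'", call. = FALSE)
  if (low < domain[1L] || high > domain[2L]) {
    stop(sprintf(
      "range [%g, %g] outside the validity domain of %s", low, high, parameter
    ), call. = FALSE)
  }
  n <- as.integer(n)
  if (n < 2L) stop("grid size 'n' must be at least 2", call. = FALSE)
  structure(list(parameter = parameter, low = low, high = high, n = n),
    class = "cs1_range"
  )
}

# Difference (surveillance - risk_adapted) with one or two fields replaced
# by vectors; relies on the closed form being plain vectorized arithmetic.
.difference_at <- function(base, values) {
  p <- as.list(unclass(base))
  for (nm in names(values)) p[[nm]] <- values[[nm]]
  .closed_form("surveillance", p) - .closed_form("risk_adapted", p)
}

.exposures_at <- function(base, values, engine) {
  if (engine == "closed_form") {
    p <- as.list(unclass(base))
    for (nm in names(values)) p[[nm]] <- values[[nm]]
    list(
      surveillance = .closed_form("surveillance", p),
      risk_adapted = .closed_form("risk_adapted", p)
    )
  } else {
    trees <- list(
      surveillance = build_surveillance_tree(),
      risk_adapted = build_risk_adapted_tree()
    )
    len <- length(values[[1L]])
    out <- lapply(trees, function(tree) {
      vapply(seq_len(len), function(i) {
        p <- as.list(unclass(base))
        for (nm in names(values)) p[[nm]] <- values[[nm]][i]
        rollback(tree, do.call(parameter_set, p))
      }, numeric(1L))
    })
    out
  }
}

#' One-way deterministic sensitivity analysis
#'
#' Evaluates both strategies at every point of a uniform grid over one
#' parameter, all other parameters held at `base`, and labels the preferred
#' (lower-exposure) strategy at each point.
#'
#' @param range a [param_range()] (or a parameter name, swept over its
#'   default range).
#' @param base a valid [parameter_set()].
#' @param engine `"closed_form"` (vectorized algebraic evaluation, default)
#'   or `"rollback"` (tree evaluation); the two agree within 1e-12.
#' @return a data frame of class `cs1_sweep` with columns `parameter`,
#'   `value`, `surveillance`, `risk_adapted`, `difference`, `preferred`.
#' @export
#' @examples
#' sw <- one_way_sweep(param_range("pRelapsePostPrimChemo"), base_parameters())
#' table(sw$preferred)
one_way_sweep <- function(range, base = base_parameters(),
                          engine = c("closed_form", "rollback")) {
  engine <- match.arg(engine)
  if (is.character(range)) range <- param_range(range)
  stopifnot(inherits(range, "cs1_range"))
  assert_valid_parameters(base)
  grid <- seq(range$low, range$high, length.out = range$n)
  values <- stats::setNames(list(grid), range$parameter)
  exp_ <- .exposures_at(base, values, engine)
  diff <- exp_$surveillance - exp_$risk_adapted
  out <- data.frame(
    parameter = range$parameter,
    value = grid,
    surveillance = exp_$surveillance,
    risk_adapted = exp_$risk_adapted,
    difference = diff,
    preferred = .pref_label(diff),
    stringsAsFactors = FALSE
  )
  attr(out, "base") <- base
  class(out) <- c("cs1_sweep", "data.frame")
  out
}

#' Threshold (break-even) analysis for one parameter
#'
#' Finds the parameter value at which the two strategies have equal expected
#' exposure, all other parameters fixed at `base`. The exposure difference
#' is affine in any single parameter, so the default solver computes the
#' root in closed form from the endpoint values (after verifying affinity at
#' the midpoint); `method = "bisection"` instead brackets the root with
#' [stats::uniroot()] as an independent cross-check. Thresholds are reported
#' at full precision with a 3-decimal display value.
#'
#' @param parameter name of the parameter to solve over.
#' @param base a valid [parameter_set()].
#' @param range a [param_range()]; defaults to the parameter's full domain.
#' @param method `"closed_form"` (default) or `"bisection"`.
#' @return an object of class `cs1_threshold`: a list with `parameter`,
#'   `threshold` (full precision, or `NA` if none in range),
#'   `threshold_display` (rounded half-up to 3 decimals), `preferred_below`,
#'   `preferred_above`, `method`, `flag` (reason when no threshold exists)
#'   and `range`.
#' @export
#' @examples
#' find_threshold("pRelapsePostPrimChemo") # 0.287
find_threshold <- function(parameter, base = base_parameters(),
                           range = param_range(parameter),
                           method = c("closed_form", "bisection")) {
  method <- match.arg(method)
  if (is.character(range)) range <- param_range(range)
  stopifnot(inherits(range, "cs1_range"))
  if (!identical(range$parameter, parameter)) {
    stop("'range' describes ", range$parameter, ", not ", parameter,
      call. = FALSE
    )
  }
  assert_valid_parameters(base)
  lo <- range$low
  hi <- range$high
  d <- function(x) .difference_at(base, stats::setNames(list(x), parameter))
  d_lo <- d(lo)
  d_hi <- d(hi)
  d_mid <- d((lo + hi) / 2)

  result <- function(threshold, flag = NA_character_,
                     below = NA_character_, above = NA_character_) {
    structure(
      list(
        parameter = parameter,
        threshold = threshold,
        threshold_display = if (is.na(threshold)) {
          NA_real_
        } else {
          round_half_up(threshold, 3)
        },
        preferred_below = below,
        preferred_above = above,
        method = method,
        flag = flag,
        range = c(low = lo, high = hi)
      ),
      class = "cs1_threshold"
    )
  }

  scale <- max(1, abs(d_lo), abs(d_hi))
  if (abs(d_hi - d_lo) <= .cs1_tol * scale) {
    # flat difference: either identically indifferent or never crossing
    if (abs(d_lo) <= .cs1_tol) {
      return(result(NA_real_,
        flag = "difference identically zero over the range (strategies indifferent)",
        below = "indifferent", above = "indifferent"
      ))
    }
    return(result(NA_real_,
      flag = "difference does not depend on this parameter over the range",
      below = .pref_label(d_lo), above = .pref_label(d_hi)
    ))
  }

  if (method == "closed_form") {
    curvature <- d_mid - (d_lo + d_hi) / 2
    if (abs(curvature) > 1e-9 * scale) {
      stop("exposure difference is not affine in ", parameter,
        "; use method = \"bisection\"",
        call. = FALSE
      )
    }
    root <- lo - d_lo * (hi - lo) / (d_hi - d_lo)
  } else {
    if (d_lo * d_hi > 0) {
      return(result(NA_real_,
        flag = "no sign change over the range",
        below = .pref_label(d_lo), above = .pref_label(d_hi)
      ))
    }
    root <- uniroot(d, c(lo, hi), tol = 1e-12)$root
  }

  if (root < lo - 1e-9 || root > hi + 1e-9) {
    return(result(NA_real_,
      flag = "threshold lies outside the swept range",
      below = .pref_label(d_lo), above = .pref_label(d_hi)
    ))
  }
  result(root, below = .pref_label(d_lo), above = .pref_label(d_hi))
}

#' @export
print.cs1_threshold <- function(x, ...) {
  cat(sprintf("Threshold analysis for %s\n", x$parameter))
  if (is.na(x$threshold)) {
    cat("  no threshold:", x$flag, "\n")
  } else {
    cat(sprintf(
      "  equal exposure at %s = %.3f (full precision %.10g)\n",
      x$parameter, x$threshold_display, x$threshold
    ))
    cat(sprintf(
      "  preferred below: %s; above: %s\n",
      x$preferred_below, x$preferred_above
    ))
  }
  invisible(x)
}

#' Two-way deterministic sensitivity analysis
#'
#' Evaluates the strategy difference on the full factorial grid of two
#' parameter ranges (all other parameters at `base`), classifies each cell
#' by preferred strategy, and extracts the preference boundary by linear
#' interpolation wherever the difference changes sign between adjacent
#' cells along the second parameter's axis.
#'
#' @param range_a,range_b [param_range()]s for two distinct parameters.
#' @param base a valid [parameter_set()].
#' @param engine see [one_way_sweep()].
#' @return an object of class `cs1_region`: a list with `param_a`,
#'   `param_b`, `grid_a`, `grid_b`, matrices `difference` and
#'   `risk_adapted_preferred` (rows index `grid_a`, columns `grid_b`;
#'   preference is `NA` at indifferent cells), and `boundary`, a data frame
#'   of break-even points `(a, b)`.
#' @export
#' @examples
#' reg <- two_way_sweep(
#'   param_range("pRelapsePostPrimChemo", 0, 0.3, n = 31),
#'   param_range("pRelapseHighrisk", 0.3, 0.8, n = 51)
#' )
#' mean(reg$risk_adapted_preferred, na.rm = TRUE)
two_way_sweep <- function(range_a, range_b, base = base_parameters(),
                          engine = c("closed_form", "rollback")) {
  engine <- match.arg(engine)
  if (is.character(range_a)) range_a <- param_range(range_a)
  if (is.character(range_b)) range_b <- param_range(range_b)
  stopifnot(inherits(range_a, "cs1_range"), inherits(range_b, "cs1_range"))
  if (identical(range_a$parameter, range_b$parameter)) {
    stop("the two swept parameters must be distinct", call. = FALSE)
  }
  assert_valid_parameters(base)
  ga <- seq(range_a$low, range_a$high, length.out = range_a$n)
  gb <- seq(range_b$low, range_b$high, length.out = range_b$n)
  values <- stats::setNames(
    list(rep(ga, times = length(gb)), rep(gb, each = length(ga))),
    c(range_a$parameter, range_b$parameter)
  )
  exp_ <- .exposures_at(base, values, engine)
  diff <- matrix(exp_$surveillance - exp_$risk_adapted,
    nrow = length(ga), ncol = length(gb)
  )
  preferred <- matrix(NA, nrow = length(ga), ncol = length(gb))
  preferred[diff > .cs1_tol] <- TRUE
  preferred[diff < -.cs1_tol] <- FALSE

  # boundary: scan each row (fixed a) for sign changes along b
  pts <- list()
  for (i in seq_along(ga)) {
    row <- diff[i, ]
    zero <- which(abs(row) <= .cs1_tol)
    for (j in zero) pts[[length(pts) + 1L]] <- c(ga[i], gb[j])
    cross <- which(row[-length(row)] * row[-1L] < 0)
    for (j in cross) {
      frac <- row[j] / (row[j] - row[j + 1L])
      pts[[length(pts) + 1L]] <- c(ga[i], gb[j] + frac * (gb[j + 1L] - gb[j]))
    }
  }
  boundary <- if (length(pts) > 0L) {
    m <- do.call(rbind, pts)
    data.frame(a = m[, 1L], b = m[, 2L])
  } else {
    data.frame(a = numeric(), b = numeric())
  }
  names(boundary) <- c(range_a$parameter, range_b$parameter)

  structure(
    list(
      param_a = range_a$parameter, param_b = range_b$parameter,
      grid_a = ga, grid_b = gb,
      difference = diff,
      risk_adapted_preferred = preferred,
      boundary = boundary,
      base = base
    ),
    class = "cs1_region"
  )
}

#' @export
print.cs1_region <- function(x, ...) {
  n <- length(x$difference)
  ra <- sum(x$risk_adapted_preferred, na.rm = TRUE)
  sv <- sum(!x$risk_adapted_preferred, na.rm = TRUE)
  cat(sprintf(
    "Two-way sensitivity analysis: %s x %s (%d x %d grid)\n",
    x$param_a, x$param_b, length(x$grid_a), length(x$grid_b)
  ))
  cat(sprintf(
    "  risk-adapted preferred in %d/%d cells, surveillance in %d, indifferent in %d\n",
    ra, n, sv, n - ra - sv
  ))
  invisible(x)
}

#' @describeIn two_way_sweep long-format view of a preference region, one
#'   row per grid cell with the preferred-strategy label.
#' @param x a `cs1_region`.
#' @param row.names,optional,... ignored (S3 signature).
#' @export
as.data.frame.cs1_region <- function(x, row.names = NULL, optional = FALSE, ...) {
  cells <- expand.grid(a = x$grid_a, b = x$grid_b, KEEP.OUT.ATTRS = FALSE)
  diff <- as.vector(x$difference)
  out <- data.frame(
    a = cells$a, b = cells$b,
    difference = diff,
    preferred = .pref_label(diff),
    stringsAsFactors = FALSE
  )
  names(out)[1:2] <- c(x$param_a, x$param_b)
  out
}
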