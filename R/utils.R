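# Absolute tolerance for probability-mass checks and strategy ties.
# All shipped inputs are short decimals, so 1e-12 separates genuine ties
# from floating-point noise.
.cs1_tol <- 1e-12

#' Round half away from zero
#'
#' Rounds with ties going away from zero (0.8125 -> 0.813 at 3 decimals),
#' the convention used when tabulating relative values and thresholds for
#' display. Base `round()` rounds half to even and would print 0.812.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(65 / 80, 3)  # 0.813
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards. seed = NULL uses (and
# advances) the current state.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L) # initialize RNG so there is a state to restore
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Preference label from a difference (surveillance minus risk-adapted
# exposure): positive means surveillance is the more toxic strategy, so
# risk-adapted is preferred.
.pref_label <- function(difference, tol = .cs1_tol) {
  ifelse(abs(difference) <= tol, "indifferent",
    ifelse(difference > 0, "risk_adapted", "surveillance")
  )
}
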