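#' Model parameters for the stage I pediatric testicular cancer decision model
#'
#' Bundles the probabilities, cycle counts and toxicity weight that drive both
#' strategy trees. Defaults are the literature point estimates used in the
#' base-case analysis:
#'
#' * `pRelapseLowrisk  = 0.15` (range 0.10-0.20): relapse rate of low-risk
#'   patients under surveillance.
#' * `pRelapseHighrisk = 0.60` (range 0.38-0.73): relapse rate of high-risk
#'   patients (e.g. with lymphovascular invasion) under surveillance.
#' * `pRelapsePostPrimChemo = 0.05` (range 0.01-0.10): relapse rate after one
#'   adjuvant cycle of PEB.
#' * `pRelapsePostSalvChemo = 0.05` (range 0.01-0.22): progression rate after
#'   three salvage cycles of PEB.
#' * `tSecondChemo = 1.3` (range 1.0-2.0): per-cycle toxicity of second-line
#'   VIP relative to PEB, elicited from a visual-analog-scale survey of
#'   urological oncologists (see [summarize_survey()]).
#' * `pLowRisk = 0.40`: proportion of low-risk patients. No literature point
#'   estimate exists for this proportion; 0.40 is the reconstructed default
#'   that reproduces the published surveillance base case of 1.3419
#'   toxicity-weighted cycles, and can be overridden freely.
#'
#' Cycle counts default to the modeled regimens: 1 adjuvant (primary) PEB
#' cycle, 3 salvage PEB cycles, 3 second-line VIP cycles. The payoff unit
#' throughout is toxicity-weighted chemotherapy cycles: salvage cycles count
#' 1 each, second-line cycles count `tSecondChemo` each.
#'
#' @param pLowRisk proportion of low-risk patients, in \[0, 1\].
#' @param pRelapseLowrisk relapse probability of the low-risk group under
#'   surveillance.
#' @param pRelapseHighrisk relapse probability of the high-risk group under
#'   surveillance.
#' @param pRelapsePostPrimChemo relapse probability after primary (adjuvant)
#'   chemotherapy.
#' @param pRelapsePostSalvChemo progression probability after salvage
#'   chemotherapy.
#' @param tSecondChemo per-cycle toxicity multiplier of second-line relative
#'   to first-line chemotherapy (> 0).
#' @param nPrimaryCycles,nSalvageCycles,nSecondLineCycles positive integer
#'   cycle counts of the three regimens.
#' @return an object of class `cs1_params` (a named list).
#' @seealso [validate_parameters()], [read_parameters()], [base_parameters()]
#' @export
#' @examples
#' parameter_set(pLowRisk = 0.25)
parameter_set <- function(pLowRisk = 0.40,
                          pRelapseLowrisk = 0.15,
                          pRelapseHighrisk = 0.60,
                          pRelapsePostPrimChemo = 0.05,
                          pRelapsePostSalvChemo = 0.05,
                          tSecondChemo = 1.3,
                          nPrimaryCycles = 1,
                          nSalvageCycles = 3,
                          nSecondLineCycles = 3) {
  fields <- list(
    pLowRisk = pLowRisk,
    pRelapseLowrisk = pRelapseLowrisk,
    pRelapseHighrisk = pRelapseHighrisk,
    pRelapsePostPrimChemo = pRelapsePostPrimChemo,
    pRelapsePostSalvChemo = pRelapsePostSalvChemo,
    tSecondChemo = tSecondChemo,
    nPrimaryCycles = nPrimaryCycles,
    nSalvageCycles = nSalvageCycles,
    nSecondLineCycles = nSecondLineCycles
  )
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (!is.numeric(v) || length(v) != 1L) {
      stop("parameter '", nm, "' must be a single number", call. = FALSE)
    }
    fields[[nm]] <- as.numeric(v)
  }
  structure(fields, class = "cs1_params")
}

#' Base-case parameters
#'
#' The shipped base case: all literature point estimates plus the
#' reconstructed `pLowRisk = 0.40` (see [parameter_set()]). Identical to the
#' packaged `base_params.yaml`.
#'
#' @return a `cs1_params` object.
#' @export
base_parameters <- function() parameter_set()

.cs1_prob_fields <- c(
  "pLowRisk", "pRelapseLowrisk", "pRelapseHighrisk",
  "pRelapsePostPrimChemo", "pRelapsePostSalvChemo"
)
.cs1_count_fields <- c("nPrimaryCycles", "nSalvageCycles", "nSecondLineCycles")

#' Read model parameters from a YAML or JSON file
#'
#' Values in the file override the supplied base set field-by-field; unknown
#' field names are an error. The file format is a flat mapping of parameter
#' name to number (see the packaged `base_params.yaml` for an example).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @param base parameters to start from; defaults to [base_parameters()].
#' @return a `cs1_params` object.
#' @export
read_parameters <- function(path, base = base_parameters()) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported parameter file extension '.", ext,
      "' (expected .yaml, .yml or .json)",
      call. = FALSE
    )
  )
  if (!is.list(vals) || is.null(names(vals)) || any(names(vals) == "")) {
    stop("parameter file must be a named mapping of parameter to value",
      call. = FALSE
    )
  }
  unknown <- setdiff(names(vals), names(base))
  if (length(unknown) > 0L) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  merged <- utils::modifyList(as.list(unclass(base)), vals)
  do.call(parameter_set, merged)
}

#' Validate a parameter set
#'
#' Checks every field against its validity domain: probabilities in \[0, 1\],
#' `tSecondChemo > 0`, cycle counts positive integers. Validation is the
#' result, not an exception: a report is always returned.
#'
#' @param params a `cs1_params` object (or a named list coercible to one).
#' @return an object of class `cs1_validation`: a list with elements `pass`
#'   (logical) and `fields` (data frame with columns `field`, `value`, `ok`,
#'   `message`).
#' @export
#' @examples
#' validate_parameters(base_parameters())$pass              # TRUE
#' validate_parameters(parameter_set(pRelapseHighrisk = 1.2))$pass # FALSE
validate_parameters <- function(params) {
  if (!inherits(params, "cs1_params")) {
    params <- do.call(parameter_set, as.list(params))
  }
  rows <- lapply(names(params), function(nm) {
    v <- params[[nm]]
    ok <- TRUE
    msg <- "ok"
    if (!is.finite(v)) {
      ok <- FALSE
      msg <- "must be a finite number"
    } else if (nm %in% .cs1_prob_fields) {
      if (v < 0 || v > 1) {
        ok <- FALSE
        msg <- sprintf("probability %g outside [0, 1]", v)
      }
    } else if (nm == "tSecondChemo") {
      if (v <= 0) {
        ok <- FALSE
        msg <- sprintf("toxicity multiplier %g must be > 0", v)
      }
    } else if (nm %in% .cs1_count_fields) {
      if (v < 1 || v != round(v)) {
        ok <- FALSE
        msg <- sprintf("cycle count %g must be a positive integer", v)
      }
    }
    data.frame(
      field = nm, value = v, ok = ok, message = msg,
      stringsAsFactors = FALSE
    )
  })
  fields <- do.call(rbind, rows)
  structure(list(pass = all(fields$ok), fields = fields),
    class = "cs1_validation"
  )
}

# Stop with the per-field messages when a parameter set is invalid.
assert_valid_parameters <- function(params) {
  report <- validate_parameters(params)
  if (!report$pass) {
    bad <- report$fields[!report$fields$ok, ]
    stop("invalid parameters: ",
      paste(sprintf("%s (%s)", bad$field, bad$message), collapse = "; "),
      call. = FALSE
    )
  }
  invisible(params)
}

#' @export
print.cs1_params <- function(x, ...) {
  cat("Decision-model parameters (toxicity-weighted cycle payoffs)\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.cs1_validation <- function(x, ...) {
  cat(if (x$pass) "PASS" else "FAIL", "- parameter validation\n")
  bad <- x$fields[!x$fields$ok, ]
  if (nrow(bad) > 0L) {
    for (i in seq_len(nrow(bad))) {
      cat(sprintf("  %s: %s\n", bad$field[i], bad$message[i]))
    }
  }
  invisible(x)
}
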