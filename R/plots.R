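#' Plot a one-way sensitivity sweep
#'
#' Expected exposure of both strategies against the swept parameter,
#' mirroring the usual one-way sensitivity panel (one line per strategy,
#' crossing at the preference threshold if any). Requires ggplot2.
#'
#' @param x a `cs1_sweep` from [one_way_sweep()].
#' @param ... ignored.
#' @return a ggplot object.
#' @export
plot.cs1_sweep <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting needs the ggplot2 package", call. = FALSE)
  }
  long <- rbind(
    data.frame(
      value = x$value, strategy = "surveillance",
      exposure = x$surveillance
    ),
    data.frame(
      value = x$value, strategy = "risk_adapted",
      exposure = x$risk_adapted
    )
  )
  ggplot2::ggplot(long, ggplot2::aes(value, exposure, colour = strategy)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = x$parameter[1L],
      y = "expected exposure (toxicity-weighted cycles)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a two-way preference region
#'
#' Fills the parameter plane by preferred strategy and overlays the
#' break-even boundary. Requires ggplot2.
#'
#' @param x a `cs1_region` from [two_way_sweep()].
#' @param ... ignored.
#' @return a ggplot object.
#' @export
plot.cs1_region <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting needs the ggplot2 package", call. = FALSE)
  }
  df <- as.data.frame(x)
  names(df)[1:2] <- c("a", "b")
  p <- ggplot2::ggplot(df, ggplot2::aes(a, b)) +
    ggplot2::geom_raster(ggplot2::aes(fill = preferred)) +
    ggplot2::labs(x = x$param_a, y = x$param_b, fill = "preferred") +
    ggplot2::theme_minimal()
  if (nrow(x$boundary) > 0L) {
    bdry <- x$boundary
    names(bdry) <- c("a", "b")
    p <- p + ggplot2::geom_line(data = bdry, linewidth = 0.7)
  }
  p
}
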