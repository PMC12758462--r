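#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.atlas_result <- function(x, ...) {
  top <- x$probabilities$probability[x$probabilities$range == x$selected_range]
  cat(sprintf("<atlas_result> %s trajectory, %d points\n",
              x$metadata$symptom, nrow(x$points)))
  cat(sprintf("severity: %s (%s), p=%.2f\n",
              as.character(x$severity), x$selected_range, top))
  if (length(x$flags) > 0) {
    cat("flags:", paste(x$flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a trajectory classification
#'
#' One row per inter-centile range with its score, probability and whether
#' it was selected.
#'
#' @param x An `atlas_result`.
#' @param ... Unused.
#' @return A six-row tibble: `range`, `lower`, `upper`, `severity`,
#'   `score`, `probability`, `selected`.
#' @export
tidy.atlas_result <- function(x, ...) {
  out <- x$probabilities
  out$selected <- out$range == x$selected_range
  out
}

#' One-row summary of a trajectory classification
#'
#' @param x An `atlas_result`.
#' @param ... Unused.
#' @return A one-row tibble: `severity`, `selected_range`, `probability`
#'   (of the selected range), `n_points`, `low_confidence`, `few_points`,
#'   `degenerate_floor`.
#' @export
glance.atlas_result <- function(x, ...) {
  tibble::tibble(
    severity = x$severity,
    selected_range = x$selected_range,
    probability = x$probabilities$probability[
      x$probabilities$range == x$selected_range],
    n_points = nrow(x$points),
    low_confidence = "low_confidence" %in% x$flags,
    few_points = "few_points" %in% x$flags,
    degenerate_floor = "degenerate_floor" %in% x$flags
  )
}

#' Plot the range probabilities of a classification
#'
#' @param object An `atlas_result`.
#' @param ... Unused.
#' @return A ggplot bar chart of the six range probabilities, coloured by
#'   severity stratum, with the selected range outlined.
#' @export
autoplot.atlas_result <- function(object, ...) {
  d <- tidy(object)
  d$range <- factor(d$range, levels = centile_ranges()$range)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$range, y = .data$probability,
                                  fill = .data$severity)) +
    ggplot2::geom_col(ggplot2::aes(colour = .data$selected), linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = NA),
                                 guide = "none") +
    ggplot2::labs(x = "Inter-centile range", y = "Probability",
                  title = sprintf("Whole-test severity: %s",
                                  as.character(object$severity))) +
    ggplot2::theme_minimal()
}
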