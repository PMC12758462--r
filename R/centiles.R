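#' Ordered reference centile labels
#'
#' The seven reference curves a symptom trajectory is scored against, in
#' fixed ascending order: the minimum and maximum envelopes plus the 5th,
#' 25th, 50th, 75th and 95th centiles of the healthy-reference Borg score
#' at each work rate.
#'
#' @return Character vector of the seven labels in ascending order.
#' @export
#' @examples
#' centile_labels()
centile_labels <- function() {
  c("min", "p5", "p25", "p50", "p75", "p95", "max")
}

#' Ordered severity categories
#'
#' Four-level ordered severity scale used both for whole-test (trajectory)
#' classification and for conventional peak-score classification.
#'
#' @return Character vector: mild < moderate < severe < very_severe.
#' @export
severity_levels <- function() {
  c("mild", "moderate", "severe", "very_severe")
}

severity_factor <- function(x) {
  factor(x, levels = severity_levels(), ordered = TRUE)
}

#' Adjacent inter-centile ranges
#'
#' The six bands between adjacent reference centile curves, in ascending
#' order, with the severity stratum each maps to: everything up to the 50th
#' centile is mild, 50th-75th moderate, 75th-95th severe, above the 95th
#' very severe.
#'
#' @return A tibble with columns `range` (e.g. `"p25-p50"`), `lower`,
#'   `upper` (centile labels) and `severity` (ordered factor).
#' @export
#' @examples
#' centile_ranges()
centile_ranges <- function() {
  .centile_ranges
}

.centile_ranges <- local({
  labs <- c("min", "p5", "p25", "p50", "p75", "p95", "max")
  tibble::tibble(
    range = paste(labs[-7], labs[-1], sep = "-"),
    lower = labs[-7],
    upper = labs[-1],
    severity = factor(
      c("mild", "mild", "mild", "moderate", "severe", "very_severe"),
      levels = c("mild", "moderate", "severe", "very_severe"), ordered = TRUE
    )
  )
})

#' Build a reference centile set
#'
#' Bundles a work-rate grid of reference Borg values (one column per centile
#' curve) with the metadata identifying which population it describes. The
#' grid rows must be ascending in work rate, every value must lie on the
#' 0-10 Borg scale, values must be non-decreasing across the centile columns
#' at each work rate and non-decreasing in work rate within each column.
#'
#' @param grid Data frame with columns `work_rate` plus the seven centile
#'   columns `min`, `p5`, `p25`, `p50`, `p75`, `p95`, `max`.
#' @param symptom `"dyspnea"` or `"leg_effort"`.
#' @param sex `"M"` or `"F"`.
#' @param age_band Inclusive age range in years, length-2 numeric.
#' @param source Free-text provenance of the table.
#' @return An `atlas_centiles` object: the grid as a tibble with the
#'   metadata stored as attributes.
#' @seealso [validate_centiles()], [evaluate_centile()], [read_centiles()]
#' @export
#' @examples
#' grid <- data.frame(
#'   work_rate = c(0, 50, 100),
#'   min = c(0, 0, 1), p5 = c(0, 0.5, 2), p25 = c(0, 1, 3),
#'   p50 = c(0, 2, 4), p75 = c(0, 3, 6), p95 = c(0, 4, 8),
#'   max = c(0, 5, 10)
#' )
#' atlas_centiles(grid, symptom = "dyspnea", sex = "M", age_band = c(40, 85))
atlas_centiles <- function(grid, symptom = c("dyspnea", "leg_effort"),
                           sex = c("M", "F"), age_band = c(19, 85),
                           source = "unspecified") {
  symptom <- match.arg(symptom)
  sex <- match.arg(sex)
  grid <- tibble::as_tibble(grid)
  needed <- c("work_rate", centile_labels())
  missing_cols <- setdiff(needed, names(grid))
  if (length(missing_cols) > 0) {
    stop("centile grid is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  grid <- grid[needed]
  out <- structure(
    grid,
    class = c("atlas_centiles", class(grid)),
    symptom = symptom,
    sex = sex,
    age_band = as.numeric(age_band),
    source = source
  )
  violations <- validate_centiles(out)
  if (length(violations) > 0) {
    stop("invalid centile set:\n  ", paste(violations, collapse = "\n  "),
         call. = FALSE)
  }
  out
}

#' Validate a centile set
#'
#' Checks every structural invariant of a centile grid and returns the
#' violations as messages rather than raising, so a malformed table can be
#' reported in full. An empty character vector means the set is valid.
#'
#' @param x An `atlas_centiles` object, or any data frame with a
#'   `work_rate` column and the seven centile columns.
#' @return Character vector of violation descriptions (empty if valid); each
#'   names the offending grid row and/or column.
#' @export
validate_centiles <- function(x) {
  v <- character()
  labs <- centile_labels()
  if (!all(c("work_rate", labs) %in% names(x))) {
    return(paste("missing columns:",
                 paste(setdiff(c("work_rate", labs), names(x)), collapse = ", ")))
  }
  wr <- x$work_rate
  if (length(wr) < 2) {
    v <- c(v, "grid: fewer than 2 work-rate points")
  }
  if (anyNA(wr) || any(wr < 0)) {
    v <- c(v, "grid: work rates must be non-negative and non-missing")
  }
  if (length(wr) >= 2 && any(diff(wr) <= 0)) {
    bad <- which(diff(wr) <= 0) + 1
    v <- c(v, paste0("grid row ", bad, ": work rates not strictly ascending"))
  }
  m <- as.matrix(as.data.frame(x)[labs])
  if (anyNA(m)) {
    v <- c(v, "grid: missing Borg values")
    return(v)
  }
  rng <- which(m < 0 | m > 10, arr.ind = TRUE)
  if (nrow(rng) > 0) {
    v <- c(v, paste0("range: row ", rng[, 1], ", column ", labs[rng[, 2]],
                     ": Borg value outside [0, 10]"))
  }
  # non-decreasing across labels within a row
  rowbad <- which(m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE] < 0,
                  arr.ind = TRUE)
  if (nrow(rowbad) > 0) {
    v <- c(v, paste0("column order: row ", rowbad[, 1], ": ",
                     labs[rowbad[, 2] + 1], " < ", labs[rowbad[, 2]]))
  }
  # non-decreasing in work rate within a column
  if (nrow(m) >= 2) {
    colbad <- which(m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE] < 0,
                    arr.ind = TRUE)
    if (nrow(colbad) > 0) {
      v <- c(v, paste0("work-rate order: column ", labs[colbad[, 2]],
                       ", row ", colbad[, 1] + 1,
                       ": value decreases with work rate"))
    }
  }
  v
}

#' Evaluate a centile curve at arbitrary work rates
#'
#' Returns the reference Borg value of one centile curve at the queried work
#' rates: exact at grid points, linearly interpolated between them, and held
#' constant at the nearest grid value beyond either end of the table.
#' Because all seven curves share the same knots, linear interpolation
#' preserves their ordering at every query point.
#'
#' @param centiles An `atlas_centiles` object.
#' @param label One of [centile_labels()].
#' @param work_rate Numeric vector of work rates in watts (>= 0).
#' @return Numeric vector of Borg values in \[0, 10\].
#' @export
#' @examples
#' cs <- generate_centiles()
#' evaluate_centile(cs, "p50", c(40, 85, 1e4))
evaluate_centile <- function(centiles, label, work_rate) {
  if (length(label) != 1 || !label %in% centile_labels()) {
    stop("unknown centile label: ", paste(label, collapse = ", "),
         "; expected one of ", paste(centile_labels(), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(work_rate >= 0))
  stats::approx(centiles$work_rate, centiles[[label]], xout = work_rate,
                method = "linear", rule = 2)$y
}

#' Width of the informative centile band
#'
#' The spread between the 95th and 5th reference centiles at a work rate.
#' A spread of zero marks the early low-load region where the reference
#' curves coincide (healthy subjects all report ~0) and observed points
#' carry no information about which inter-centile range fits best; the
#' classifier down-weights such "inertial" points.
#'
#' @inheritParams evaluate_centile
#' @return Numeric vector of non-negative Borg spreads.
#' @export
centile_spread <- function(centiles, work_rate) {
  evaluate_centile(centiles, "p95", work_rate) -
    evaluate_centile(centiles, "p5", work_rate)
}

#' List the inter-centile ranges of a centile set
#'
#' @param centiles An `atlas_centiles` object.
#' @return The six adjacent ranges as a tibble (see [centile_ranges()]).
#' @export
list_ranges <- function(centiles) {
  stopifnot(inherits(centiles, "atlas_centiles"))
  centile_ranges()
}

#' @export
print.atlas_centiles <- function(x, ...) {
  cat(sprintf(
    "<atlas_centiles> %s, sex %s, ages %g-%g, %d work rates (%g-%g W)\n",
    attr(x, "symptom"), attr(x, "sex"),
    attr(x, "age_band")[1], attr(x, "age_band")[2],
    nrow(x), min(x$work_rate), max(x$work_rate)
  ))
  cat("source:", attr(x, "source"), "\n")
  print(tibble::as_tibble(unclass(x)), ...)
  invisible(x)
}

#' Plot reference centiles with an optional observed trajectory
#'
#' Draws the seven reference curves against work rate, shades the severity
#' strata, and overlays one subject's observed scores if given — the
#' standard way these classifications are read.
#'
#' @param centiles An `atlas_centiles` object.
#' @param points Optional data frame of observed points with columns
#'   `work_rate` and `score`.
#' @return A ggplot object.
#' @export
plot_centiles <- function(centiles, points = NULL) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(unclass(centiles)),
    cols = dplyr::all_of(centile_labels()),
    names_to = "centile", values_to = "borg"
  )
  long$centile <- factor(long$centile, levels = centile_labels())
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$work_rate, y = .data$borg)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$centile,
                                    linetype = .data$centile),
                       colour = "grey40") +
    ggplot2::labs(
      x = "Work rate (W)", y = "Borg CR10 score",
      title = sprintf("Reference centiles: %s (%s, %g-%g y)",
                      attr(centiles, "symptom"), attr(centiles, "sex"),
                      attr(centiles, "age_band")[1], attr(centiles, "age_band")[2]),
      linetype = "centile"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(
      data = tibble::as_tibble(points),
      ggplot2::aes(x = .data$work_rate, y = .data$score),
      colour = "firebrick", size = 2
    ) +
      ggplot2::geom_line(
        data = tibble::as_tibble(points),
        ggplot2::aes(x = .data$work_rate, y = .data$score),
        colour = "firebrick"
      )
  }
  p
}
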