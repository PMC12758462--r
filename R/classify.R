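#' @importFrom rlang .data
NULL

# Validate an observed-points data frame: columns work_rate, score;
# >= 1 row, strictly increasing work rates, Borg scores in [0, 10].
check_points <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(c("work_rate", "score") %in% names(data))) {
    stop("trajectory data must have columns `work_rate` and `score`",
         call. = FALSE)
  }
  if (nrow(data) < 1) {
    stop("trajectory must contain at least one point", call. = FALSE)
  }
  if (anyNA(data$work_rate) || anyNA(data$score)) {
    stop("trajectory contains missing values", call. = FALSE)
  }
  if (nrow(data) >= 2 && any(diff(data$work_rate) <= 0)) {
    stop("trajectory work rates must be strictly increasing", call. = FALSE)
  }
  if (any(data$score < 0 | data$score > 10)) {
    stop("Borg scores must lie in [0, 10]", call. = FALSE)
  }
  data
}

check_symptom_match <- function(symptom, centiles) {
  if (!is.null(symptom) && !identical(symptom, attr(centiles, "symptom"))) {
    stop("trajectory symptom (", symptom, ") does not match centile set (",
         attr(centiles, "symptom"), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-point weights for trajectory scoring
#'
#' Points recorded where the 5th-95th reference centile spread is below
#' `config$inertial_spread` (the early low-load region where the reference
#' curves coincide or sit within a single Borg category of each other) are
#' "inertial": their position between centiles carries no information about
#' which band fits best. They receive `config$inertial_weight`, all other
#' points weight 1, and the weights are rescaled to sum to the number of
#' points.
#'
#' @param data Data frame of observed points with columns `work_rate`
#'   (watts, strictly increasing) and `score` (Borg 0-10).
#' @param centiles An `atlas_centiles` object for the same symptom.
#' @param config An [atlas_config()].
#' @param symptom Optional symptom name; if supplied it must match the
#'   centile set's metadata.
#' @return The input as a tibble with columns `spread` and `weight` added;
#'   weights sum to `nrow(data)`.
#' @export
compute_weights <- function(data, centiles, config = atlas_config(),
                            symptom = NULL) {
  data <- check_points(data)
  check_symptom_match(symptom, centiles)
  spread <- centile_spread(centiles, data$work_rate)
  inertial <- spread == 0 | spread < config$inertial_spread
  raw <- ifelse(inertial, config$inertial_weight, 1)
  data$spread <- spread
  data$weight <- raw * nrow(data) / sum(raw)
  data
}

#' Reciprocal-exponential-loss fit of a trajectory to each centile curve
#'
#' For each of the seven reference curves, each observed point contributes
#' `exp(-alpha * d)` where `d` is its absolute Borg deviation from the
#' curve, capped at `clamp_dev`. The per-curve fit score is the weighted
#' mean of these contributions, floored at `min_loss`. Being a reciprocal
#' loss, a better fit yields a *greater* score: the score is 1 exactly when
#' every deviation is zero and decays exponentially as the trajectory moves
#' away from the curve.
#'
#' @inheritParams compute_weights
#' @return A tibble with columns `centile` and `rel` (fit score in
#'   \[`min_loss`, 1\]).
#' @export
#' @examples
#' cs <- generate_centiles()
#' traj <- generate_trajectory(cs, "p50-p75", noise_sd = 0, seed = 1)
#' rel_scores(traj, cs)
rel_scores <- function(data, centiles, config = atlas_config(),
                       symptom = NULL) {
  data <- compute_weights(data, centiles, config, symptom = symptom)
  rel <- vapply(centile_labels(), function(lab) {
    d <- pmin(abs(data$score - evaluate_centile(centiles, lab, data$work_rate)),
              config$clamp_dev)
    max(config$min_loss,
        sum(data$weight * exp(-config$alpha * d)) / sum(data$weight))
  }, numeric(1))
  tibble::tibble(centile = centile_labels(), rel = unname(rel))
}

#' Score each inter-centile range
#'
#' A range's score is the product of the fit scores of its two bordering
#' centile curves — e.g. the 25th-50th range scores `rel(p25) * rel(p50)` —
#' so a band is rewarded when the trajectory sits close to both of its
#' borders.
#'
#' @inheritParams compute_weights
#' @return [centile_ranges()] with a `score` column, each score in
#'   \[`min_loss`^2, 1\].
#' @export
range_scores <- function(data, centiles, config = atlas_config(),
                         symptom = NULL) {
  rel <- rel_scores(data, centiles, config, symptom = symptom)
  r <- stats::setNames(rel$rel, rel$centile)
  out <- centile_ranges()
  out$score <- unname(r[out$lower] * r[out$upper])
  out
}

#' Normalize range scores into probabilities
#'
#' Divides the six range scores by their sum so they read as the percent
#' probability that each inter-centile range is the most representative of
#' the observed trajectory; the probabilities sum to one.
#'
#' @param scores Output of [range_scores()] (or any data frame with `range`
#'   and positive `score` columns).
#' @return The input with a `probability` column added (sums to 1).
#' @export
normalize_scores <- function(scores) {
  scores <- tibble::as_tibble(scores)
  stopifnot("score" %in% names(scores))
  total <- sum(scores$score)
  if (!is.finite(total) || total <= 0) {
    stop("range scores must be positive and finite; check min_loss",
         call. = FALSE)
  }
  scores$probability <- scores$score / total
  scores
}

# boundary index after range i for each usable threshold label
threshold_boundaries <- c(p5 = 1, p25 = 2, p50 = 3, p75 = 4, p95 = 5)

#' Select the most representative inter-centile range
#'
#' A generalized binary search over the six range probabilities. Working
#' through `config$threshold_order` (default: the severity-stratum
#' boundaries p50, p75, p95), each threshold splits the currently surviving
#' ranges into those entirely below it and those at or above it; the side
#' carrying the larger probability mass survives (ties per
#' `config$tie_rule`). Comparing summed masses rather than single ranges
#' prevents bias against strata spanning fewer ranges (mild spans three
#' bands, the others one). When one severity stratum remains, its
#' highest-probability range is returned.
#'
#' @param probabilities Output of [normalize_scores()], or a numeric vector
#'   of six probabilities in ascending range order.
#' @param config An [atlas_config()].
#' @return A single range id, e.g. `"p50-p75"`.
#' @export
select_range <- function(probabilities, config = atlas_config()) {
  ranges <- centile_ranges()
  if (is.data.frame(probabilities)) {
    stopifnot(all(c("range", "probability") %in% names(probabilities)))
    p <- probabilities$probability[match(ranges$range, probabilities$range)]
  } else {
    p <- as.numeric(probabilities)
  }
  stopifnot(length(p) == 6, all(p >= 0))
  if (abs(sum(p) - 1) > 1e-9) {
    stop("probabilities must sum to 1", call. = FALSE)
  }
  surviving <- seq_len(6L)
  for (lab in config$threshold_order) {
    b <- threshold_boundaries[[lab]]
    below <- surviving[surviving <= b]
    above <- surviving[surviving > b]
    if (length(below) == 0 || length(above) == 0) next
    mass_below <- sum(p[below])
    mass_above <- sum(p[above])
    surviving <- if (mass_above > mass_below) {
      above
    } else if (mass_below > mass_above) {
      below
    } else if (config$tie_rule == "higher") above else below
  }
  best <- surviving[p[surviving] == max(p[surviving])]
  idx <- if (config$tie_rule == "higher") max(best) else min(best)
  ranges$range[idx]
}

#' Map an inter-centile range to its severity category
#'
#' Whole-test severity strata: anything up to the 50th centile is mild,
#' 50th-75th moderate, 75th-95th severe, and above the 95th very severe.
#'
#' @param range Character vector of range ids (see [centile_ranges()]).
#' @return Ordered factor of severity categories.
#' @export
#' @examples
#' severity_from_range(c("p75-p95", "min-p5"))
severity_from_range <- function(range) {
  ranges <- centile_ranges()
  idx <- match(range, ranges$range)
  if (anyNA(idx)) {
    stop("unknown inter-centile range: ",
         paste(unique(range[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  ranges$severity[idx]
}

#' Classify a peak Borg score
#'
#' The conventional single-point classification of the score reported at
#' maximal exercise: 0-2 mild, 3-4 moderate, 5-6 severe, 7 or more very
#' severe. Non-integer scores are binned by the same interval bounds
#' (e.g. 2.5 is moderate).
#'
#' @param score Numeric vector of Borg scores in \[0, 10\].
#' @return Ordered factor of severity categories.
#' @export
#' @examples
#' classify_peak(c(2, 2.5, 5, 7))
classify_peak <- function(score) {
  if (anyNA(score) || any(score < 0 | score > 10)) {
    stop("peak Borg scores must lie in [0, 10]", call. = FALSE)
  }
  cut(score, breaks = c(-Inf, 2, 4, 6, Inf), labels = severity_levels(),
      ordered_result = TRUE)
}

#' Classify a symptom trajectory against reference centiles
#'
#' The full pipeline: weight the observed points, compute each reference
#' curve's reciprocal-exponential-loss fit, score and normalize the six
#' inter-centile ranges, select the most representative range by
#' generalized binary search, and map it to the four-level severity scale.
#'
#' Diagnostic flags: `few_points` when the trajectory has fewer than 3
#' points; `low_confidence` when the winning range's probability is below
#' 0.35 (a heuristic diagnostic, not part of the selection rule);
#' `degenerate_floor` when any centile's fit score hit the `min_loss`
#' floor (the trajectory is far from that curve everywhere).
#'
#' @inheritParams compute_weights
#' @param sex,age Optional subject metadata; if supplied, `sex` must equal
#'   the centile set's sex and `age` must fall inside its age band.
#' @return An `atlas_result` object with components `probabilities` (tibble
#'   of ranges, scores, probabilities), `rel` (per-centile fit scores),
#'   `points` (weighted input), `selected_range`, `severity`, `flags`, and
#'   the `config` used. Has [generics::tidy()], [generics::glance()],
#'   `autoplot()` and `print()` methods.
#' @export
#' @examples
#' cs <- generate_centiles()
#' traj <- generate_trajectory(cs, "p50-p75", seed = 7)
#' fit <- atlas_classify(traj, cs)
#' fit
#' generics::tidy(fit)
atlas_classify <- function(data, centiles, config = atlas_config(),
                           symptom = NULL, sex = NULL, age = NULL) {
  check_symptom_match(symptom, centiles)
  if (!is.null(sex) && !identical(sex, attr(centiles, "sex"))) {
    stop("subject sex (", sex, ") does not match centile set (",
         attr(centiles, "sex"), ")", call. = FALSE)
  }
  band <- attr(centiles, "age_band")
  if (!is.null(age) && (age < band[1] || age > band[2])) {
    stop("subject age ", age, " outside centile set age band [",
         band[1], ", ", band[2], "]", call. = FALSE)
  }
  points <- compute_weights(data, centiles, config, symptom = symptom)
  rel <- rel_scores(points[c("work_rate", "score")], centiles, config)
  r <- stats::setNames(rel$rel, rel$centile)
  probs <- centile_ranges()
  probs$score <- unname(r[probs$lower] * r[probs$upper])
  probs <- normalize_scores(probs)
  selected <- select_range(probs, config)
  severity <- severity_from_range(selected)
  top_p <- probs$probability[probs$range == selected]
  flags <- c(
    if (nrow(points) < 3) "few_points",
    if (top_p < 0.35) "low_confidence",
    if (any(rel$rel <= config$min_loss)) "degenerate_floor"
  )
  structure(
    list(
      probabilities = probs,
      rel = rel,
      points = points,
      selected_range = selected,
      severity = severity,
      flags = flags %||% character(),
      config = config,
      metadata = list(symptom = attr(centiles, "symptom"),
                      sex = attr(centiles, "sex"),
                      age_band = band)
    ),
    class = "atlas_result"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
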