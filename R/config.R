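#' Classifier configuration
#'
#' Tuning constants of the trajectory classifier. None are learned from
#' data; all are fixed, documented choices that can be overridden per run.
#'
#' @param alpha Loss steepness per Borg unit of deviation (> 0). Larger
#'   values make the fit score decay faster with distance from a centile
#'   curve, i.e. reduce the algorithm's leniency toward neighbouring ranges.
#' @param min_loss Floor applied to each centile's aggregated fit score
#'   (0 < min_loss < 1), guaranteeing strictly positive range scores and a
#'   well-defined normalization even for trajectories far from every curve.
#' @param clamp_dev Maximum absolute deviation, in Borg units, entering the
#'   exponential loss (0 < clamp_dev <= 10). Caps the influence of a single
#'   wild outlier.
#' @param inertial_weight Weight in (0, 1\] given to "inertial" points —
#'   observations at work rates where the 5th-95th centile spread is below
#'   `inertial_spread`, so the reference curves are too close for the point
#'   to discriminate between ranges.
#' @param inertial_spread Borg spread (>= 0) below which a point counts as
#'   inertial. The default of 1 is the width of one Borg category: when the
#'   entire 5th-95th reference band spans less than one category, a rating
#'   made in whole or half categories cannot resolve position between
#'   curves. Set to 0 to down-weight only points where the curves coincide
#'   exactly.
#' @param tie_rule `"higher"` (default; never understates burden) or
#'   `"lower"`: which side wins exact ties in the range selector.
#' @param threshold_order Centile labels used, in order, as split points of
#'   the generalized binary search. The default `c("p50", "p75", "p95")`
#'   mirrors the severity-stratum boundaries, so the search is not biased
#'   against strata that span fewer inter-centile ranges.
#' @return An `atlas_config` list.
#' @export
#' @examples
#' atlas_config(alpha = 2)
atlas_config <- function(alpha = 1,
                         min_loss = 1e-4,
                         clamp_dev = 5,
                         inertial_weight = 0.25,
                         inertial_spread = 1,
                         tie_rule = c("higher", "lower"),
                         threshold_order = c("p50", "p75", "p95")) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(
    is.numeric(alpha), length(alpha) == 1, alpha > 0,
    is.numeric(min_loss), length(min_loss) == 1, min_loss > 0, min_loss < 1,
    is.numeric(clamp_dev), length(clamp_dev) == 1,
    clamp_dev > 0, clamp_dev <= 10,
    is.numeric(inertial_weight), length(inertial_weight) == 1,
    inertial_weight > 0, inertial_weight <= 1,
    is.numeric(inertial_spread), length(inertial_spread) == 1,
    inertial_spread >= 0,
    all(threshold_order %in% setdiff(centile_labels(), c("min", "max")))
  )
  structure(
    list(
      alpha = alpha, min_loss = min_loss, clamp_dev = clamp_dev,
      inertial_weight = inertial_weight, inertial_spread = inertial_spread,
      tie_rule = tie_rule,
      threshold_order = threshold_order
    ),
    class = "atlas_config"
  )
}

#' Read a classifier configuration file
#'
#' YAML or JSON (by extension) with any subset of the [atlas_config()]
#' keys; unspecified keys keep their defaults, unknown keys are an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `atlas_config` list.
#' @export
read_config <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(atlas_config))
  extra <- setdiff(names(obj), known)
  if (length(extra) > 0) {
    stop("unknown config keys in ", path, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  do.call(atlas_config, obj)
}

#' @export
print.atlas_config <- function(x, ...) {
  cat("<atlas_config>\n")
  cat(sprintf("  alpha: %g per Borg unit\n", x$alpha))
  cat(sprintf("  min_loss: %g   clamp_dev: %g Borg\n", x$min_loss, x$clamp_dev))
  cat(sprintf("  inertial_weight: %g (spread < %g)   tie_rule: %s\n",
              x$inertial_weight, x$inertial_spread, x$tie_rule))
  cat(sprintf("  threshold_order: %s\n", paste(x$threshold_order, collapse = " ")))
  invisible(x)
}

format_config <- function(cfg) {
  sprintf("alpha=%g min_loss=%g clamp_dev=%g inertial_weight=%g inertial_spread=%g tie_rule=%s thresholds=%s",
          cfg$alpha, cfg$min_loss, cfg$clamp_dev, cfg$inertial_weight,
          cfg$inertial_spread, cfg$tie_rule,
          paste(cfg$threshold_order, collapse = ","))
}
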