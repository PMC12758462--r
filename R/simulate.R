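#' Parameters of the synthetic study generator
#'
#' Describes the incremental exercise protocol (stepwise 1-2 min stages of
#' 10-20 W on a cycle ergometer), the shape of the synthetic reference
#' centile curves, and the trajectory noise model. The centile curves rise
#' as a power function of work rate above a per-centile onset — Borg
#' ratings follow a psychophysical power law — with onsets staggered so
#' that the minimum, 5th and 25th centiles stay at 0 through the low-load
#' region (as real leg-effort references do up to ~80 W).
#'
#' @param increment_w Work-rate increment per stage, 10-20 W.
#' @param stage_min Stage duration in minutes (1 or 2; metadata only).
#' @param peak_work_rate_w Default highest stage reached by a simulated
#'   subject, watts.
#' @param grid_max_w Upper end of the reference table's work-rate grid,
#'   watts; the table extends beyond typical patient peaks.
#' @param grid_step_w Grid spacing of the reference table, watts.
#' @param exponent Power-law exponent of the centile curves (> 1:
#'   accelerating symptom growth).
#' @param onsets Named numeric vector: work rate (W) at which each centile
#'   curve leaves 0, in centile order; must be non-increasing.
#' @param terminals Named numeric vector: each curve's Borg value at
#'   `grid_max_w`, in centile order; must be non-decreasing (an error
#'   otherwise) and within \[0, 10\].
#' @param noise_sd Gaussian noise sd added to the latent symptom curve,
#'   Borg units.
#' @param n_events Number of sudden persistent symptom jumps per
#'   trajectory.
#' @param event_size Size of each jump, Borg units.
#' @param round_half Round observed scores to the nearest 0.5 (usual Borg
#'   CR10 practice).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(increment_w = 10,
                           stage_min = 2,
                           peak_work_rate_w = 120,
                           grid_max_w = 160,
                           grid_step_w = 10,
                           exponent = 1.8,
                           onsets = c(min = 110, p5 = 95, p25 = 80,
                                      p50 = 40, p75 = 20, p95 = 10, max = 0),
                           terminals = c(min = 2, p5 = 3, p25 = 4.5,
                                         p50 = 6, p75 = 8, p95 = 9.5,
                                         max = 10),
                           noise_sd = 0.3,
                           n_events = 0,
                           event_size = 1.5,
                           round_half = TRUE) {
  stopifnot(
    increment_w >= 10, increment_w <= 20,
    peak_work_rate_w > 0, grid_max_w >= peak_work_rate_w, grid_step_w > 0,
    exponent > 0, noise_sd >= 0, n_events >= 0, event_size >= 0,
    identical(names(onsets), centile_labels()),
    identical(names(terminals), centile_labels()),
    all(onsets >= 0), all(onsets < grid_max_w),
    all(terminals >= 0), all(terminals <= 10),
    !is.unsorted(rev(onsets))
  )
  if (is.unsorted(terminals)) {
    stop("terminal Borg values must be non-decreasing across centiles",
         call. = FALSE)
  }
  structure(
    list(increment_w = increment_w, stage_min = stage_min,
         peak_work_rate_w = peak_work_rate_w, grid_max_w = grid_max_w,
         grid_step_w = grid_step_w, exponent = exponent, onsets = onsets,
         terminals = terminals, noise_sd = noise_sd, n_events = n_events,
         event_size = event_size, round_half = round_half),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic reference centile table
#'
#' Builds the seven centile curves on the spec's work-rate grid:
#' `terminal * ((w - onset) / (grid_max - onset))^exponent` above each
#' curve's onset, 0 below it. Because onsets fall and terminals rise with
#' centile order, the curves are ordered at every work rate and
#' non-decreasing in work rate, so the table always validates. The
#' generation is deterministic.
#'
#' @param spec A [synthetic_spec()].
#' @param symptom,sex,age_band Metadata for the resulting table.
#' @return An `atlas_centiles` object with `source = "synthetic"`.
#' @export
#' @examples
#' cs <- generate_centiles()
#' validate_centiles(cs)
generate_centiles <- function(spec = synthetic_spec(),
                              symptom = "dyspnea", sex = "M",
                              age_band = c(40, 85)) {
  wr <- seq(0, spec$grid_max_w, by = spec$grid_step_w)
  cols <- lapply(centile_labels(), function(lab) {
    onset <- spec$onsets[[lab]]
    term <- spec$terminals[[lab]]
    x <- pmax(0, wr - onset) / (spec$grid_max_w - onset)
    pmin(10, term * x^spec$exponent)
  })
  grid <- tibble::as_tibble(
    c(list(work_rate = wr), stats::setNames(cols, centile_labels()))
  )
  atlas_centiles(grid, symptom = symptom, sex = sex, age_band = age_band,
                 source = "synthetic")
}

# midpoint of an inter-centile range at given work rates; where the range
# has zero width this is the shared curve value
range_midpoint <- function(centiles, range, work_rate) {
  ranges <- centile_ranges()
  idx <- match(range, ranges$range)
  if (is.na(idx)) stop("unknown range: ", range, call. = FALSE)
  (evaluate_centile(centiles, ranges$lower[idx], work_rate) +
      evaluate_centile(centiles, ranges$upper[idx], work_rate)) / 2
}

#' Generate one ground-truth-labelled symptom trajectory
#'
#' Stage work rates follow the protocol (one point per `increment_w` up to
#' `peak_work_rate`). The latent symptom curve is the midpoint of the
#' target inter-centile range at each work rate (the shared curve value
#' where the range has zero width); observations add Gaussian noise and
#' optional sudden persistent jumps, are clipped to \[0, 10\] and rounded
#' to the nearest half point. Deterministic for a given seed.
#'
#' @param centiles Reference `atlas_centiles` to generate against.
#' @param target Target range id (see [centile_ranges()]).
#' @param spec A [synthetic_spec()]; supplies defaults for the remaining
#'   arguments.
#' @param noise_sd,n_events,peak_work_rate Optional overrides of the spec.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return A tibble of points (`work_rate`, `score`) with attributes
#'   `target` (range id) and `severity` (ground-truth category).
#' @export
#' @examples
#' cs <- generate_centiles()
#' generate_trajectory(cs, "p75-p95", seed = 1)
generate_trajectory <- function(centiles, target, spec = synthetic_spec(),
                                noise_sd = NULL, n_events = NULL,
                                peak_work_rate = NULL, seed = NULL) {
  noise_sd <- noise_sd %||% spec$noise_sd
  n_events <- n_events %||% spec$n_events
  peak_work_rate <- peak_work_rate %||% spec$peak_work_rate_w
  gen <- function() {
    wr <- seq(spec$increment_w, peak_work_rate, by = spec$increment_w)
    out <- tibble::tibble(
      work_rate = wr,
      score = simulate_scores(centiles, target, wr, noise_sd, n_events,
                              spec$event_size, spec$round_half)
    )
    attr(out, "target") <- target
    attr(out, "severity") <- severity_from_range(target)
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# draw one observed score vector from the trajectory noise model; uses the
# current RNG stream
simulate_scores <- function(centiles, target, wr, noise_sd, n_events,
                            event_size, round_half) {
  score <- range_midpoint(centiles, target, wr) +
    stats::rnorm(length(wr), 0, noise_sd)
  if (n_events > 0) {
    for (at in sample.int(length(wr), min(n_events, length(wr)))) {
      score[at:length(wr)] <- score[at:length(wr)] + event_size
    }
  }
  score <- pmin(10, pmax(0, score))
  if (round_half) score <- round(score * 2) / 2
  score
}

#' Generate a synthetic patient cohort with stage data
#'
#' Draws each subject a ground-truth severity from `mix`, a target
#' inter-centile range within that stratum per symptom, demographic
#' metadata, and three two-level impairment labels (GOLD stage,
#' mechanical constraint, low peak VO2) whose probability of being adverse
#' rises with true severity at a rate set by `coupling` (0 = independent,
#' 1 = near-deterministic). More severe subjects reach fewer stages, so
#' their peak work rates — and hence peak Borg scores, taken from the last
#' stage — are lower: the phenomenon that makes peak-score classification
#' understate the burden of impaired patients. Deterministic for a given
#' seed.
#'
#' @param n Number of subjects (>= 1).
#' @param mix Named severity proportions (must sum to 1).
#' @param coupling Group-severity coupling in \[0, 1\].
#' @param spec A [synthetic_spec()].
#' @param centiles Reference table; generated from `spec` if `NULL`.
#' @param seed Integer seed, or `NULL`.
#' @return A list: `cohort` (one row per subject: id, sex, age, group
#'   labels, peak scores, ground-truth targets and severities), `stages`
#'   (long stage table, [read_stage_csv()] schema), `centiles`.
#' @export
generate_cohort <- function(n,
                            mix = c(mild = 0.35, moderate = 0.25,
                                    severe = 0.25, very_severe = 0.15),
                            coupling = 0.6,
                            spec = synthetic_spec(),
                            centiles = NULL,
                            seed = NULL) {
  stopifnot(n >= 1, coupling >= 0, coupling <= 1)
  if (!identical(names(mix), severity_levels()) ||
      abs(sum(mix) - 1) > 1e-8 || any(mix < 0)) {
    stop("mix must be named proportions over ",
         paste(severity_levels(), collapse = " < "), " summing to 1",
         call. = FALSE)
  }
  if (is.null(centiles)) centiles <- generate_centiles(spec)
  ranges <- centile_ranges()
  base_stages <- floor(spec$peak_work_rate_w / spec$increment_w)

  # map severity rank to its candidate range indices in centile_ranges()
  stratum_ranges <- list(`1` = 1:3, `2` = 4L, `3` = 5L, `4` = 6L)
  pick_range <- function(kk) {
    vapply(kk, function(k) {
      cand <- stratum_ranges[[as.character(k)]]
      if (length(cand) == 1) cand else sample(cand, 1)
    }, integer(1))
  }

  gen <- function() {
    k <- sample.int(4, n, replace = TRUE, prob = mix)
    flip <- stats::runif(n) < 0.25
    k_leg <- ifelse(flip,
                    pmax(1, pmin(4, k + sample(c(-1, 1), n, replace = TRUE))),
                    k)
    idx_dys <- pick_range(k)
    idx_leg <- pick_range(k_leg)
    n_stages <- pmax(4, base_stages - 2 * (k - 1) +
                       sample(-1:1, n, replace = TRUE))
    sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.55, 0.45))
    age <- round(pmin(85, pmax(40, stats::rnorm(n, 65, 9))))
    p_adv <- pmin(1, pmax(0, 0.5 + coupling * (k - 2.5) / 3))
    draw2 <- function(levels) {
      ifelse(stats::runif(n) < p_adv, levels[2], levels[1])
    }
    gold_stage <- draw2(c("I_II", "III_IV"))
    mech <- draw2(c("no", "yes"))
    lowvo2 <- draw2(c("no", "yes"))

    ids <- sprintf("S%04d", seq_len(n))
    dys <- vector("list", n)
    leg <- vector("list", n)
    for (i in seq_len(n)) {
      wr <- seq_len(n_stages[i]) * spec$increment_w
      dys[[i]] <- simulate_scores(centiles, ranges$range[idx_dys[i]], wr,
                                  spec$noise_sd, spec$n_events,
                                  spec$event_size, spec$round_half)
      leg[[i]] <- simulate_scores(centiles, ranges$range[idx_leg[i]], wr,
                                  spec$noise_sd, spec$n_events,
                                  spec$event_size, spec$round_half)
    }
    cohort <- tibble::tibble(
      subject_id = ids, sex = sex, age = age,
      gold_stage = gold_stage, mechanical_constraint = mech,
      low_peak_vo2 = lowvo2,
      peak_dyspnea = vapply(dys, function(s) s[length(s)], numeric(1)),
      peak_leg_effort = vapply(leg, function(s) s[length(s)], numeric(1)),
      true_severity_dyspnea = severity_factor(severity_levels()[k]),
      true_severity_leg_effort = severity_factor(severity_levels()[k_leg]),
      true_range_dyspnea = ranges$range[idx_dys],
      true_range_leg_effort = ranges$range[idx_leg]
    )
    stages <- tibble::tibble(
      subject_id = rep(ids, n_stages),
      stage = unlist(lapply(n_stages, seq_len), use.names = FALSE),
      work_rate_w = unlist(lapply(n_stages, function(m) {
        seq_len(m) * spec$increment_w
      }), use.names = FALSE),
      dyspnea_borg = unlist(dys, use.names = FALSE),
      leg_effort_borg = unlist(leg, use.names = FALSE)
    )
    list(cohort = cohort, stages = stages, centiles = centiles)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
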