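test_that("inertial points are down-weighted and weights sum to n", {
  cs <- coincident_centiles()
  cfg <- atlas_config(inertial_weight = 0.25, inertial_spread = 0)
  # first two points in the exactly-coincident region, last two outside
  pts <- data.frame(work_rate = c(10, 30, 70, 100), score = c(0, 0, 1, 2))
  w <- compute_weights(pts, cs, cfg)
  expect_equal(w$weight, c(0.25, 0.25, 1, 1) * 4 / 2.5)
  expect_equal(sum(w$weight), 4)

  # no low-spread points at all: every weight is 1
  w2 <- compute_weights(data.frame(work_rate = c(40, 80), score = c(3, 4)),
                        wide_centiles(), atlas_config())
  expect_equal(w2$weight, c(1, 1))

  # all points inertial: rescaling makes every weight 1 again
  w3 <- compute_weights(data.frame(work_rate = c(10, 20, 30),
                                   score = c(0, 0, 0.5)),
                        cs, cfg)
  expect_equal(w3$weight, c(1, 1, 1))

  expect_error(
    compute_weights(pts, cs, cfg, symptom = "dyspnea"),
    "does not match"
  )
})

test_that("REL matches hand-evaluated exponential loss", {
  cs <- wide_centiles()  # p50 runs linearly from 2 at 0 W to 4 at 100 W
  cfg <- atlas_config(alpha = 1)

  # trajectory exactly on the curve scores 1 for that centile
  on <- data.frame(work_rate = c(25, 50, 75),
                   score = evaluate_centile(cs, "p50", c(25, 50, 75)))
  r <- rel_scores(on, cs, cfg)
  expect_equal(r$rel[r$centile == "p50"], 1)

  # single point one Borg unit off: exp(-1)
  one <- data.frame(work_rate = 50, score = evaluate_centile(cs, "p50", 50) + 1)
  r1 <- rel_scores(one, cs, cfg)
  expect_equal(r1$rel[r1$centile == "p50"], exp(-1))

  # two equal-weight points at deviations 0 and ln 2: (1 + 1/2) / 2
  two <- data.frame(
    work_rate = c(25, 75),
    score = evaluate_centile(cs, "p50", c(25, 75)) + c(0, log(2))
  )
  r2 <- rel_scores(two, cs, cfg)
  expect_equal(r2$rel[r2$centile == "p50"], 0.75)

  expect_error(rel_scores(data.frame(work_rate = numeric(),
                                     score = numeric()), cs, cfg),
               "at least one point")
})

test_that("REL is bounded, calibrated at zero deviation, and decreasing", {
  cs <- wide_centiles()
  cfg <- atlas_config()
  withr::with_seed(42, {
    for (i in 1:25) {
      wr <- sort(sample(5:95, 5))
      base <- evaluate_centile(cs, "p50", wr)
      off <- runif(5, 0, 2)
      r0 <- rel_scores(data.frame(work_rate = wr, score = base + off),
                       cs, cfg)
      expect_true(all(r0$rel >= cfg$min_loss & r0$rel <= 1))
      rel50 <- r0$rel[r0$centile == "p50"]
      expect_identical(rel50 == 1, all(off == 0))
      # shifting every deviation up (still below the clamp) lowers the fit
      r1 <- rel_scores(data.frame(work_rate = wr, score = base + off + 0.5),
                       cs, cfg)
      expect_lt(r1$rel[r1$centile == "p50"], rel50)
    }
  })
  # clamp caps the influence of a wild outlier
  cl <- atlas_config(clamp_dev = 2)
  far <- data.frame(work_rate = 50, score = evaluate_centile(cs, "min", 50) + 8)
  rf <- rel_scores(far, cs, cl)
  expect_equal(rf$rel[rf$centile == "min"], exp(-2))
})

test_that("range scores are border-REL products", {
  cs <- wide_centiles()
  cfg <- atlas_config()
  pts <- generate_trajectory(generate_centiles(), "p50-p75", seed = 3)
  # consistency with rel_scores on an arbitrary trajectory
  tr <- data.frame(work_rate = c(20, 50, 80), score = c(3, 4, 6))
  rel <- rel_scores(tr, cs, cfg)
  r <- setNames(rel$rel, rel$centile)
  sc <- range_scores(tr, cs, cfg)
  expect_equal(sc$score, unname(r[sc$lower] * r[sc$upper]))
  expect_true(all(sc$score >= cfg$min_loss^2 & sc$score <= 1))

  # trajectory pinned to p50: both adjacent ranges carry the largest scores
  on <- data.frame(work_rate = c(25, 50, 75),
                   score = evaluate_centile(cs, "p50", c(25, 50, 75)))
  sc2 <- range_scores(on, cs, cfg)
  top2 <- sc2$range[order(sc2$score, decreasing = TRUE)][1:2]
  expect_setequal(top2, c("p25-p50", "p50-p75"))
})

test_that("normalization yields a unit-sum probability vector", {
  sc <- centile_ranges()
  sc$score <- rep(2, 6)
  expect_equal(normalize_scores(sc)$probability, rep(1 / 6, 6))
  withr::with_seed(1, {
    for (i in 1:50) {
      sc$score <- runif(6, 1e-8, 1)
      p <- normalize_scores(sc)$probability
      expect_lt(abs(sum(p) - 1), 1e-9)
      expect_true(all(p > 0))
    }
  })
  sc$score <- rep(0, 6)
  expect_error(normalize_scores(sc), "positive")
})

test_that("the range selector walks thresholds by probability mass", {
  cfg <- atlas_config()
  p <- c(0, 0, 0, 0, 1, 0)
  expect_equal(select_range(p, cfg), "p75-p95")

  # mass below p50 0.30, on the moderate band 0.40, above p75 0.30:
  # above wins at p50 (0.70 > 0.30), below wins at p75 (0.40 > 0.30)
  p2 <- c(0.1, 0.1, 0.1, 0.4, 0.2, 0.1)
  expect_equal(select_range(p2, cfg), "p50-p75")

  # uniform probabilities tie at every threshold; "higher" climbs to the top
  p3 <- rep(1 / 6, 6)
  expect_equal(select_range(p3, cfg), "p95-max")
  expect_equal(select_range(p3, atlas_config(tie_rule = "lower")), "min-p5")
})

test_that("the selector agrees with the recursive oracle on random vectors", {
  cfg_hi <- atlas_config(tie_rule = "higher")
  cfg_lo <- atlas_config(tie_rule = "lower")
  withr::with_seed(2024, {
    for (i in 1:300) {
      p <- random_probability_vector()
      expect_identical(select_range(p, cfg_hi), oracle_select(p, tie = "higher"))
      expect_identical(select_range(p, cfg_lo), oracle_select(p, tie = "lower"))
    }
  })
})

test_that("severity strata follow the centile-range definitions", {
  expect_equal(as.character(severity_from_range("p75-p95")), "severe")
  expect_equal(as.character(severity_from_range("p95-max")), "very_severe")
  expect_equal(as.character(severity_from_range("p50-p75")), "moderate")
  expect_equal(
    as.character(severity_from_range(c("min-p5", "p5-p25", "p25-p50"))),
    rep("mild", 3)
  )
  expect_error(severity_from_range("p50-p95"), "unknown")
})

test_that("peak-score classification reproduces the conventional bins", {
  expect_equal(
    as.character(classify_peak(0:10)),
    c(rep("mild", 3), rep("moderate", 2), rep("severe", 2),
      rep("very_severe", 4))
  )
  expect_equal(as.character(classify_peak(2.5)), "moderate")
  expect_error(classify_peak(11), "\\[0, 10\\]")
  expect_error(classify_peak(-1), "\\[0, 10\\]")
})

test_that("the full pipeline classifies band-following trajectories", {
  cs <- generate_centiles()
  wr <- seq(10, 120, 10)

  # between the 50th and 75th centiles throughout: moderate burden
  mid <- (evaluate_centile(cs, "p50", wr) + evaluate_centile(cs, "p75", wr)) / 2
  fit <- atlas_classify(data.frame(work_rate = wr, score = mid), cs)
  expect_equal(as.character(fit$severity), "moderate")
  expect_equal(fit$selected_range, "p50-p75")

  # strictly above the 95th centile at every point: very severe
  hi <- pmin(10, (evaluate_centile(cs, "p95", wr) +
                    evaluate_centile(cs, "max", wr)) / 2 + 0.25)
  fit2 <- atlas_classify(data.frame(work_rate = wr, score = hi), cs)
  expect_equal(as.character(fit2$severity), "very_severe")

  # probabilities always sum to one
  expect_lt(abs(sum(fit$probabilities$probability) - 1), 1e-9)
})

test_that("flags mark sparse, uncertain and floor-bound classifications", {
  cs <- generate_centiles()
  one <- data.frame(work_rate = 60, score = evaluate_centile(cs, "p50", 60))
  fit <- atlas_classify(one, cs)
  expect_true("few_points" %in% fit$flags)
  expect_true(as.character(fit$severity) %in% c("mild", "moderate"))

  # a ceiling-pinned trajectory under a steep loss: the clamped deviation
  # of 5 Borg units gives exp(-alpha * 5) below the floor once alpha > ~1.8
  wr <- seq(10, 120, 10)
  fit2 <- atlas_classify(data.frame(work_rate = wr, score = rep(10, 12)), cs,
                         atlas_config(alpha = 3))
  expect_true("degenerate_floor" %in% fit2$flags)
  expect_equal(as.character(fit2$severity), "very_severe")
})

test_that("metadata mismatches are rejected", {
  cs <- generate_centiles(symptom = "dyspnea", sex = "M", age_band = c(40, 85))
  pts <- data.frame(work_rate = c(20, 40), score = c(1, 2))
  expect_error(atlas_classify(pts, cs, symptom = "leg_effort"),
               "does not match")
  expect_error(atlas_classify(pts, cs, sex = "F"), "does not match")
  expect_error(atlas_classify(pts, cs, age = 30), "age band")
  expect_silent(atlas_classify(pts, cs, symptom = "dyspnea", sex = "M",
                               age = 60))
})

test_that("classification is deterministic and tidier methods are coherent", {
  cs <- generate_centiles()
  tr <- generate_trajectory(cs, "p75-p95", seed = 5)
  f1 <- atlas_classify(tr, cs)
  f2 <- atlas_classify(tr, cs)
  expect_identical(f1$probabilities, f2$probabilities)
  expect_identical(f1$severity, f2$severity)

  td <- tidy(f1)
  expect_equal(nrow(td), 6)
  expect_equal(sum(td$selected), 1)
  expect_equal(td$range[td$selected], f1$selected_range)
  g <- glance(f1)
  expect_equal(g$severity, f1$severity)
  expect_equal(g$n_points, nrow(tr))
  expect_s3_class(ggplot2::autoplot(f1), "ggplot")
})
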