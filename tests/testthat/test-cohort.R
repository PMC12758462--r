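test_that("severity cross-tabulation counts subjects and keeps marginals", {
  d <- tibble::tibble(
    subject_id = c("a", "b", "c", "d"),
    m1 = c("mild", "severe", "moderate", "very_severe"),
    m2 = c("mild", "severe", "moderate", "very_severe")
  )
  tab <- crosstab_severity(d, "m1", "m2")
  expect_equal(dim(tab), c(4L, 4L))
  expect_equal(sum(tab), 4)
  expect_equal(sum(diag(tab)), 4)  # full agreement sits on the diagonal

  d2 <- tibble::tibble(subject_id = c("a", "b"),
                       m1 = c("mild", "severe"),
                       m2 = c("severe", "mild"))
  tab2 <- crosstab_severity(d2, "m1", "m2")
  expect_equal(diag(tab2), setNames(rep(0L, 4), severity_levels()))
  expect_equal(tab2["mild", "severe"], 1L)
  expect_equal(tab2["severe", "mild"], 1L)
  expect_equal(as.vector(rowSums(tab2)), c(1, 0, 1, 0))

  d3 <- d
  d3$m2[2] <- NA
  expect_error(crosstab_severity(d3, "m1", "m2"), "b")
})

test_that("McNemar switches between exact and corrected forms as specified", {
  # balanced discordance: exact p is 1
  t1 <- matrix(c(10, 5, 5, 10), 2, 2)
  r1 <- mcnemar_test(t1)
  expect_equal(r1$method, "exact")
  expect_equal(r1$p_value, 1)

  # b = 9, c = 1: two-sided binomial tail 2 * (C(10,9) + C(10,10)) / 2^10
  t2 <- matrix(c(10, 1, 9, 10), 2, 2)
  r2 <- mcnemar_test(t2)
  expect_equal(r2$method, "exact")
  expect_equal(r2$p_value, 22 / 1024)
  # cross-check against the exact binomial test
  expect_equal(r2$p_value, binom.test(9, 10, 0.5)$p.value)

  # 25 or more discordant pairs: continuity-corrected statistic
  t3 <- matrix(c(30, 10, 20, 40), 2, 2)
  r3 <- mcnemar_test(t3)
  expect_equal(r3$method, "corrected")
  expect_equal(r3$statistic, (abs(20 - 10) - 1)^2 / 30)
  # cross-check against the standard implementation
  ref <- stats::mcnemar.test(t3, correct = TRUE)
  expect_equal(r3$statistic, unname(ref$statistic))
  expect_equal(r3$p_value, ref$p.value)

  # no discordant pairs: degenerate, p = 1
  t4 <- matrix(c(7, 0, 0, 3), 2, 2)
  r4 <- mcnemar_test(t4)
  expect_equal(r4$method, "degenerate")
  expect_equal(r4$p_value, 1)

  expect_error(mcnemar_test(matrix(1, 3, 3)), "2 x 2")
})

test_that("exact and corrected McNemar p agree near the switchover", {
  # in the discriminating regime the continuity-corrected approximation
  # tracks the exact binomial closely across the n = 25 switch
  for (n in 23:27) {
    for (b in 0:n) {
      c <- n - b
      exact <- min(1, 2 * pbinom(min(b, c), n, 0.5))
      corrected <- pchisq((abs(b - c) - 1)^2 / n, 1, lower.tail = FALSE)
      if (corrected < 0.2) {
        expect_lt(abs(exact - corrected), 0.02)
      }
    }
  }
})

test_that("Pearson chi-squared matches the 2x2 closed form", {
  r0 <- chi_squared_test(matrix(10, 2, 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  m <- matrix(c(20, 10, 10, 20), 2, 2)
  r <- chi_squared_test(m)
  expect_equal(r$statistic, 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30))
  expect_equal(r$df, 1)

  # row permutation leaves the statistic unchanged
  expect_equal(chi_squared_test(m[c(2, 1), ])$statistic, r$statistic)

  withr::with_seed(9, {
    for (i in 1:100) {
      t <- matrix(rpois(4, 20) + 1, 2, 2)
      a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
      n <- sum(t)
      closed <- n * (a * d - b * c)^2 /
        (sum(t[1, ]) * sum(t[2, ]) * sum(t[, 1]) * sum(t[, 2]))
      expect_equal(chi_squared_test(t)$statistic, closed, tolerance = 1e-9)
    }
  })

  expect_error(chi_squared_test(matrix(c(1, 2, 0, 0), 2, 2)), "degenerate")
  expect_error(chi_squared_test(matrix(1:3, 3, 1)), "at least 2 x 2")
})

test_that("severity dichotomization cuts at severe-or-worse by default", {
  x <- dichotomize_severity(c("mild", "moderate", "severe", "very_severe"))
  expect_equal(as.character(x),
               c("below", "below", "at_or_above", "at_or_above"))
  y <- dichotomize_severity(c("mild", "moderate"), cut = "moderate")
  expect_equal(as.character(y), c("below", "at_or_above"))
})

test_that("discrimination report contrasts methods on a coupled cohort", {
  withr::with_seed(31, {
    n <- 160
    sev <- sample(severity_levels(), n, replace = TRUE)
    rank <- match(sev, severity_levels())
    # a grouping tightly coupled to the trajectory-based category, and a
    # second classification that is pure noise
    grp <- ifelse(runif(n) < 0.15 + 0.22 * (rank - 1), "III_IV", "I_II")
    noise <- sample(severity_levels(), n, replace = TRUE)
    d <- tibble::tibble(subject_id = as.character(seq_len(n)),
                        atlas_severity = sev, peak_severity = noise,
                        gold_stage = grp)
    rep <- discrimination_report(d, "gold_stage")
    tests <- tidy(rep)
    expect_lt(tests$p_value[tests$method == "atlas"], 0.05)
    expect_true(tests$discriminates[tests$method == "atlas"])
    expect_true(tests$monotone[tests$method == "atlas"])
    # both methods tabulate the same cohort
    expect_equal(sum(rep$tables$atlas), n)
    expect_equal(sum(rep$tables$peak), n)
    expect_equal(sum(rep$shares$n[rep$shares$method == "atlas"]), n)
  })
})

test_that("a constant grouping is reported as non-discriminating", {
  d <- tibble::tibble(subject_id = c("a", "b", "c", "d"),
                      atlas_severity = c("mild", "moderate", "severe",
                                         "very_severe"),
                      peak_severity = c("mild", "mild", "mild", "mild"),
                      gold_stage = rep("I_II", 4))
  rep <- discrimination_report(d, "gold_stage")
  expect_true(all(is.na(tidy(rep)$p_value)))
  expect_false(any(tidy(rep)$discriminates))
})

test_that("the limiting symptom follows the higher peak score", {
  expect_equal(limiting_symptom(c(5, 3, 4), c(4, 6, 4)),
               c("dyspnea", "leg_effort", "both"))
})
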