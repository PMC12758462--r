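# Shared fixtures and independent oracles for the test suite.

# Small hand-made centile set with wide, everywhere-positive spread so that
# no point is inertial and hand-computed deviations drive the fit scores.
wide_centiles <- function() {
  atlas_centiles(
    data.frame(
      work_rate = c(0, 100),
      min = c(0, 0), p5 = c(0, 1), p25 = c(1, 2), p50 = c(2, 4),
      p75 = c(3, 6), p95 = c(4, 8), max = c(5, 10)
    ),
    symptom = "dyspnea", sex = "M", age_band = c(40, 85),
    source = "synthetic test fixture"
  )
}

# Centile set whose curves all coincide at 0 up to 40 W (zero spread), then
# fan out; exercises the inertial-point weighting.
coincident_centiles <- function() {
  atlas_centiles(
    data.frame(
      work_rate = c(0, 40, 100),
      min = c(0, 0, 0), p5 = c(0, 0, 0.5), p25 = c(0, 0, 1),
      p50 = c(0, 0, 2), p75 = c(0, 0, 3), p95 = c(0, 0, 4.5),
      max = c(0, 0, 6)
    ),
    symptom = "leg_effort", sex = "F", age_band = c(19, 85),
    source = "synthetic test fixture"
  )
}

# Independent recursive implementation of the generalized-binary-search
# selection rule, used as the oracle for select_range().
oracle_select <- function(p, thresholds = c("p50", "p75", "p95"),
                          tie = "higher") {
  boundary <- c(p5 = 1, p25 = 2, p50 = 3, p75 = 4, p95 = 5)
  recurse <- function(surv, th) {
    if (length(th) == 0) {
      cand <- surv[p[surv] == max(p[surv])]
      return(if (tie == "higher") max(cand) else min(cand))
    }
    b <- boundary[[th[1]]]
    lo <- surv[surv <= b]
    hi <- surv[surv > b]
    if (length(lo) == 0 || length(hi) == 0) return(recurse(surv, th[-1]))
    sl <- sum(p[lo])
    sh <- sum(p[hi])
    keep <- if (sh > sl) hi else if (sl > sh) lo else {
      if (tie == "higher") hi else lo
    }
    recurse(keep, th[-1])
  }
  centile_ranges()$range[recurse(seq_len(6), thresholds)]
}

random_probability_vector <- function() {
  x <- stats::runif(6)
  x / sum(x)
}
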