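#' Classify every trajectory in a stage table
#'
#' Runs the trajectory classifier on each (subject, symptom) pair of a
#' long-format stage table. Rows with a missing score for a symptom are
#' omitted from that symptom's trajectory only.
#'
#' @param stages Stage data frame with columns `subject_id`, `stage`,
#'   `work_rate_w`, `dyspnea_borg`, `leg_effort_borg` (see
#'   [read_stage_csv()]).
#' @param centiles A single `atlas_centiles` object applied to both
#'   symptoms, or a named list with elements `dyspnea` and `leg_effort`.
#' @param config An [atlas_config()].
#' @return A tibble with one row per subject and symptom: `subject_id`,
#'   `symptom`, `severity`, `selected_range`, `probability`, `n_points`,
#'   `flags` (comma-separated).
#' @export
classify_cohort <- function(stages, centiles, config = atlas_config()) {
  trajs <- stage_trajectories(stages)
  get_set <- function(symptom) {
    if (inherits(centiles, "atlas_centiles")) return(centiles)
    centiles[[symptom]]
  }
  purrr::map_dfr(trajs, function(tr) {
    fit <- atlas_classify(tr$points, get_set(tr$symptom), config)
    g <- glance(fit)
    tibble::tibble(
      subject_id = tr$subject_id,
      symptom = tr$symptom,
      severity = g$severity,
      selected_range = g$selected_range,
      probability = g$probability,
      n_points = g$n_points,
      flags = paste(fit$flags, collapse = ",")
    )
  })
}

#' Cross-tabulate severity classifications
#'
#' Counts of subjects in each pair of severity categories under two
#' classification methods (e.g. whole-test trajectory vs peak score). All
#' four levels are kept even when empty, so the table is always 4 x 4 and
#' its marginals equal the method-wise category counts.
#'
#' @param data Data frame with one row per subject.
#' @param a,b Names of the two columns holding severity categories.
#' @return A base contingency `table` (rows = `a`, columns = `b`).
#' @export
crosstab_severity <- function(data, a, b) {
  data <- tibble::as_tibble(data)
  for (col in c(a, b)) {
    if (!col %in% names(data)) {
      stop("column not found: ", col, call. = FALSE)
    }
    if (anyNA(data[[col]])) {
      bad <- if ("subject_id" %in% names(data)) {
        paste(data$subject_id[is.na(data[[col]])], collapse = ", ")
      } else {
        paste(which(is.na(data[[col]])), collapse = ", ")
      }
      stop("missing classifications in ", col, " for: ", bad, call. = FALSE)
    }
  }
  table(severity_factor(as.character(data[[a]])),
        severity_factor(as.character(data[[b]])),
        dnn = c(a, b))
}

#' Dichotomize severity at a cut level
#'
#' @param severity Vector of severity categories.
#' @param cut Lowest level counted as the adverse side; default `"severe"`
#'   (i.e. severe-or-worse vs below).
#' @return Factor with levels `"below"` and `"at_or_above"`.
#' @export
dichotomize_severity <- function(severity, cut = "severe") {
  sev <- severity_factor(as.character(severity))
  cut <- match.arg(cut, severity_levels())
  factor(ifelse(as.integer(sev) >= match(cut, severity_levels()),
                "at_or_above", "below"),
         levels = c("below", "at_or_above"))
}

#' McNemar's test for paired classification disagreement
#'
#' Tests whether two paired dichotomous classifications disagree
#' systematically. With fewer than 25 discordant pairs an exact two-sided
#' binomial test (success probability 1/2) is used; otherwise the
#' continuity-corrected statistic `(|b - c| - 1)^2 / (b + c)` referred to a
#' chi-squared distribution with 1 df. With no discordant pairs the test is
#' degenerate and p = 1.
#'
#' @param table A 2 x 2 paired contingency table (e.g. severe-or-worse
#'   under each of two methods); the off-diagonal cells are the discordant
#'   counts b and c.
#' @return A one-row tibble: `b`, `c`, `method` (`"exact"`, `"corrected"`
#'   or `"degenerate"`), `statistic` (NA for the exact test), `p_value`.
#' @export
#' @examples
#' mcnemar_test(matrix(c(30, 9, 1, 20), 2, 2))
mcnemar_test <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2)) || any(m < 0)) {
    stop("mcnemar_test requires a 2 x 2 table of non-negative counts",
         call. = FALSE)
  }
  b <- m[1, 2]
  c <- m[2, 1]
  n <- b + c
  if (n == 0) {
    return(tibble::tibble(b = b, c = c, method = "degenerate",
                          statistic = NA_real_, p_value = 1))
  }
  if (n < 25) {
    p <- min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
    return(tibble::tibble(b = b, c = c, method = "exact",
                          statistic = NA_real_, p_value = p))
  }
  stat <- (abs(b - c) - 1)^2 / n
  tibble::tibble(b = b, c = c, method = "corrected", statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' McNemar disagreement between two severity classifications
#'
#' Convenience wrapper: dichotomizes both severity columns at `cut`
#' (default severe-or-worse), builds the paired 2 x 2 table and runs
#' [mcnemar_test()].
#'
#' @inheritParams crosstab_severity
#' @inheritParams dichotomize_severity
#' @return As [mcnemar_test()], with the table attached as attribute
#'   `"table"`.
#' @export
mcnemar_disagreement <- function(data, a, b, cut = "severe") {
  da <- dichotomize_severity(data[[a]], cut)
  db <- dichotomize_severity(data[[b]], cut)
  tab <- table(da, db, dnn = c(a, b))
  out <- mcnemar_test(tab)
  attr(out, "table") <- tab
  out
}

#' Pearson chi-squared test of a contingency table
#'
#' Standard uncorrected Pearson test of independence, `sum((O - E)^2 / E)`
#' on `(r - 1)(c - 1)` degrees of freedom.
#'
#' @param table Contingency table (matrix or `table`) of non-negative
#'   counts, at least 2 x 2, with no zero row or column marginal.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_squared_test(matrix(c(20, 10, 10, 20), 2, 2))
chi_squared_test <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: zero row or column marginal", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value))
}

#' Compare how two methods discriminate a patient grouping
#'
#' For each classification method (whole-test trajectory and peak score),
#' cross-tabulates the four severity categories against a two-level patient
#' grouping (e.g. GOLD stage I-II vs III-IV, mechanical constraint yes/no,
#' low peak VO2 yes/no), runs the chi-squared test, and reports the share
#' of the adverse group within each severity category together with whether
#' that share rises monotonically with severity — the signature of a
#' classification that tracks disease impairment.
#'
#' @param data Data frame with one row per subject.
#' @param grouping Name of the two-level grouping column.
#' @param methods Named character vector mapping method names to severity
#'   column names.
#' @param adverse The group level counted as adverse; defaults to
#'   `"III_IV"` or `"yes"` when present, otherwise the last level.
#' @return An `atlas_discrimination` object: `tests` (per-method tibble
#'   with `statistic`, `df`, `p_value`, `monotone`, `discriminates`),
#'   `shares` (per method x severity adverse-group shares), `tables`
#'   (named list of 4 x 2 tables). Has `tidy()` and `print()` methods.
#' @export
discrimination_report <- function(data, grouping,
                                  methods = c(atlas = "atlas_severity",
                                              peak = "peak_severity"),
                                  adverse = NULL) {
  data <- tibble::as_tibble(data)
  if (!grouping %in% names(data)) {
    stop("grouping column not found: ", grouping, call. = FALSE)
  }
  if (anyNA(data[[grouping]])) {
    stop("grouping label missing for some subjects", call. = FALSE)
  }
  grp <- factor(as.character(data[[grouping]]))
  if (is.null(adverse)) {
    known <- intersect(c("III_IV", "yes"), levels(grp))
    adverse <- if (length(known) > 0) known[1] else levels(grp)[nlevels(grp)]
  }

  one_method <- function(col) {
    sev <- severity_factor(as.character(data[[col]]))
    tab <- table(sev, grp, dnn = c(col, grouping))
    # empty severity rows carry no information; drop them from the test only
    test <- tryCatch(chi_squared_test(tab[rowSums(tab) > 0, , drop = FALSE]),
                     error = function(e) {
      tibble::tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
    })
    n_sev <- rowSums(tab)
    adv_n <- if (adverse %in% colnames(tab)) tab[, adverse] else rep(0, nrow(tab))
    share <- ifelse(n_sev > 0, adv_n / n_sev, NA_real_)
    observed <- share[n_sev > 0]
    monotone <- length(observed) > 0 && !is.unsorted(observed)
    list(
      table = tab,
      test = test,
      shares = tibble::tibble(severity = severity_factor(rownames(tab)),
                              n = as.integer(n_sev),
                              adverse_n = as.integer(adv_n),
                              adverse_share = as.numeric(share)),
      monotone = monotone
    )
  }

  res <- lapply(methods, one_method)
  tests <- purrr::imap_dfr(res, function(r, nm) {
    dplyr::mutate(r$test, method = nm, monotone = r$monotone,
                  discriminates = !is.na(r$test$p_value) & r$test$p_value < 0.05,
                  .before = 1)
  })
  shares <- purrr::imap_dfr(res, function(r, nm) {
    dplyr::mutate(r$shares, method = nm, .before = 1)
  })
  structure(
    list(grouping = grouping, adverse = adverse, tests = tests,
         shares = shares, tables = lapply(res, `[[`, "table"),
         n = nrow(data)),
    class = "atlas_discrimination"
  )
}

#' @export
print.atlas_discrimination <- function(x, ...) {
  cat(sprintf("<atlas_discrimination> grouping: %s (adverse: %s), n = %d\n",
              x$grouping, x$adverse, x$n))
  print(as.data.frame(x$tests), row.names = FALSE)
  invisible(x)
}

#' @rdname discrimination_report
#' @param x An `atlas_discrimination` object.
#' @param ... Unused.
#' @export
tidy.atlas_discrimination <- function(x, ...) {
  x$tests
}

#' Main limiting symptom from peak scores
#'
#' The symptom with the higher peak Borg rating; equal ratings give
#' `"both"` (conventionally excluded from two-way comparisons).
#'
#' @param peak_dyspnea,peak_leg_effort Numeric vectors of peak Borg scores.
#' @return Character vector: `"dyspnea"`, `"leg_effort"` or `"both"`.
#' @export
limiting_symptom <- function(peak_dyspnea, peak_leg_effort) {
  dplyr::case_when(
    peak_dyspnea > peak_leg_effort ~ "dyspnea",
    peak_leg_effort > peak_dyspnea ~ "leg_effort",
    TRUE ~ "both"
  )
}

#' Full cohort comparison of trajectory vs peak-score classification
#'
#' Classifies every subject's trajectories, joins the conventional
#' peak-score categories, and produces the three cohort-level analyses:
#' the 4 x 4 cross-tabulation of the two methods per symptom, McNemar's
#' test of their disagreement (dichotomized at severe-or-worse), and the
#' chi-squared discrimination of a patient grouping by each method's
#' dyspnea categories.
#'
#' @param cohort Data frame with one row per subject: `subject_id`,
#'   `peak_dyspnea`, `peak_leg_effort` and any grouping columns.
#' @param stages Stage data frame (see [classify_cohort()]).
#' @param centiles Centile set(s), as in [classify_cohort()].
#' @param config An [atlas_config()].
#' @param grouping Grouping column name for the discrimination analysis,
#'   or `NULL` to skip it.
#' @param symptom Symptom used for the discrimination analysis.
#' @return A list: `subjects` (cohort with per-symptom trajectory and peak
#'   severities), `crosstabs` (per symptom), `mcnemar` (per symptom),
#'   `discrimination` (or `NULL`).
#' @export
cohort_analysis <- function(cohort, stages, centiles,
                            config = atlas_config(), grouping = NULL,
                            symptom = "dyspnea") {
  cohort <- tibble::as_tibble(cohort)
  atlas <- classify_cohort(stages, centiles, config)
  wide <- tidyr::pivot_wider(
    atlas[c("subject_id", "symptom", "severity")],
    names_from = "symptom", values_from = "severity",
    names_glue = "atlas_{symptom}"
  )
  subjects <- dplyr::left_join(cohort, wide, by = "subject_id")
  subjects$peak_sev_dyspnea <- classify_peak(subjects$peak_dyspnea)
  subjects$peak_sev_leg_effort <- classify_peak(subjects$peak_leg_effort)
  subjects$limiting <- limiting_symptom(subjects$peak_dyspnea,
                                        subjects$peak_leg_effort)

  crosstabs <- list()
  mcnemar <- list()
  for (sym in intersect(c("dyspnea", "leg_effort"),
                        sub("^atlas_", "", grep("^atlas_", names(subjects),
                                                value = TRUE)))) {
    a <- paste0("atlas_", sym)
    b <- paste0("peak_sev_", sym)
    crosstabs[[sym]] <- crosstab_severity(subjects, a, b)
    mcnemar[[sym]] <- mcnemar_disagreement(subjects, a, b)
  }

  discrimination <- NULL
  if (!is.null(grouping)) {
    discrimination <- discrimination_report(
      subjects, grouping,
      methods = stats::setNames(
        c(paste0("atlas_", symptom), paste0("peak_sev_", symptom)),
        c("atlas", "peak"))
    )
  }
  list(subjects = subjects, crosstabs = crosstabs, mcnemar = mcnemar,
       discrimination = discrimination)
}
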