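stage_header <- c("subject_id", "stage", "work_rate_w",
                  "dyspnea_borg", "leg_effort_borg")

#' Read a stage CSV
#'
#' Reads per-stage symptom recordings. The header must be exactly
#' `subject_id,stage,work_rate_w,dyspnea_borg,leg_effort_borg` (UTF-8,
#' `.` decimal). Either Borg column may be blank on a row — the rating was
#' not collected for that symptom at that stage. All validation problems
#' are collected and reported together with their line numbers.
#'
#' @param path Path to the CSV file.
#' @return A tibble of stage rows (one per subject and stage).
#' @seealso [stage_trajectories()] to split into per-symptom trajectories.
#' @export
read_stage_csv <- function(path) {
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  if (!identical(trimws(header), stage_header)) {
    stop("malformed stage CSV header in ", path, "; expected exactly: ",
         paste(stage_header, collapse = ","), call. = FALSE)
  }
  d <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      stage = readr::col_integer(),
      work_rate_w = readr::col_double(),
      dyspnea_borg = readr::col_double(),
      leg_effort_borg = readr::col_double()
    ),
    progress = FALSE
  )
  line <- seq_len(nrow(d)) + 1L  # header is line 1
  problems <- character()
  bad <- is.na(d$work_rate_w) | d$work_rate_w < 0
  if (any(bad)) {
    problems <- c(problems, paste0("line ", line[bad],
                                   ": work_rate_w missing or negative"))
  }
  for (col in c("dyspnea_borg", "leg_effort_borg")) {
    bad <- !is.na(d[[col]]) & (d[[col]] < 0 | d[[col]] > 10)
    if (any(bad)) {
      problems <- c(problems, paste0("line ", line[bad], ": ", col,
                                     " outside [0, 10]"))
    }
  }
  ord <- unlist(lapply(split(seq_len(nrow(d)), d$subject_id), function(ix) {
    ix[c(FALSE, diff(d$work_rate_w[ix]) <= 0 |
           diff(d$stage[ix]) <= 0)]
  }), use.names = FALSE)
  if (length(ord) > 0) {
    problems <- c(problems,
                  paste0("line ", line[sort(ord)],
                         ": stage/work rate not strictly increasing within subject"))
  }
  if (length(problems) > 0) {
    stop("invalid stage CSV ", path, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  d
}

#' Write a stage table to CSV
#'
#' Inverse of [read_stage_csv()].
#'
#' @param stages Stage tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stage_csv <- function(stages, path) {
  readr::write_csv(stages[stage_header], path, progress = FALSE)
  invisible(path)
}

#' Split a stage table into per-subject, per-symptom trajectories
#'
#' Rows with a missing score for a symptom are dropped from that symptom's
#' trajectory only; subjects with no scored rows for a symptom contribute
#' no trajectory for it.
#'
#' @param stages Stage tibble (see [read_stage_csv()]).
#' @return A list of trajectories, each a list with `subject_id`,
#'   `symptom` and `points` (tibble of `work_rate`, `score`).
#' @export
stage_trajectories <- function(stages) {
  stages <- tibble::as_tibble(stages)
  missing_cols <- setdiff(stage_header, names(stages))
  if (length(missing_cols) > 0) {
    stop("stage table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cols <- c(dyspnea = "dyspnea_borg", leg_effort = "leg_effort_borg")
  out <- list()
  for (id in unique(stages$subject_id)) {
    sub <- stages[stages$subject_id == id, ]
    for (sym in names(cols)) {
      keep <- !is.na(sub[[cols[[sym]]]])
      if (!any(keep)) next
      out[[length(out) + 1]] <- list(
        subject_id = id,
        symptom = sym,
        points = tibble::tibble(work_rate = sub$work_rate_w[keep],
                                score = sub[[cols[[sym]]]][keep])
      )
    }
  }
  out
}

#' Write a classification result to JSON
#'
#' Records the six range probabilities (6 decimal places), the selected
#' range, the severity category, the diagnostic flags and the per-centile
#' fit scores.
#'
#' @param result An `atlas_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path) {
  stopifnot(inherits(result, "atlas_result"))
  obj <- list(
    symptom = result$metadata$symptom,
    probabilities = stats::setNames(
      as.list(round(result$probabilities$probability, 6)),
      result$probabilities$range),
    selected_range = result$selected_range,
    severity = as.character(result$severity),
    flags = as.list(result$flags),
    rel = stats::setNames(as.list(result$rel$rel), result$rel$centile)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
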