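#' Read a centile table from JSON
#'
#' The on-disk schema is a single JSON object with keys `symptom`, `sex`,
#' `age_band` (\[lo, hi\] in years), `work_rates` (ascending array),
#' `centiles` (object mapping `"min"`, `"p5"`, `"p25"`, `"p50"`, `"p75"`,
#' `"p95"`, `"max"` to arrays of the same length as `work_rates`) and
#' `source`. The schema is strict: missing or unknown centile keys are
#' rejected, and the resulting set must pass [validate_centiles()].
#'
#' @param path Path to a centile JSON file.
#' @return An `atlas_centiles` object.
#' @export
read_centiles <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("symptom", "sex", "age_band", "work_rates", "centiles")
  missing_keys <- setdiff(needed, names(obj))
  if (length(missing_keys) > 0) {
    stop("centile file ", path, " is missing keys: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(obj$centiles), centile_labels())
  if (length(extra) > 0) {
    stop("centile file ", path, " has unknown centile keys: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(centile_labels(), names(obj$centiles))
  if (length(miss) > 0) {
    stop("centile file ", path, " is missing centile keys: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  lens <- vapply(obj$centiles, length, integer(1))
  if (any(lens != length(obj$work_rates))) {
    stop("centile file ", path,
         ": centile arrays must match work_rates in length", call. = FALSE)
  }
  grid <- tibble::as_tibble(c(list(work_rate = as.numeric(obj$work_rates)),
                              lapply(obj$centiles[centile_labels()], as.numeric)))
  atlas_centiles(
    grid,
    symptom = obj$symptom, sex = obj$sex,
    age_band = as.numeric(obj$age_band),
    source = if (is.null(obj$source)) "unspecified" else obj$source
  )
}

#' Write a centile table to JSON
#'
#' Inverse of [read_centiles()]; a write-then-read round trip reproduces
#' the in-memory object exactly.
#'
#' @param centiles An `atlas_centiles` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_centiles <- function(centiles, path) {
  stopifnot(inherits(centiles, "atlas_centiles"))
  obj <- list(
    symptom = attr(centiles, "symptom"),
    sex = attr(centiles, "sex"),
    age_band = attr(centiles, "age_band"),
    work_rates = centiles$work_rate,
    centiles = lapply(stats::setNames(centile_labels(), centile_labels()),
                      function(l) centiles[[l]]),
    source = attr(centiles, "source")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
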