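#' Read and validate a long-format visit-score table
#'
#' The on-disk format is CSV (or TSV, by file extension) with one row per
#' patient, occasion, rater and item:
#' `patient_id, occasion_label, occasion_order, weeks_elapsed, rater,
#' item_id, item_class, scale, value`. `scale` is `"points_0_4"` (integers
#' 0-4) or `"vas_0_100"` (real, mm); `item_class` is `"anamnestic"` or
#' `"clinical"`; `rater` is `"assessor"` or `"clinician"`. Validation rejects
#' malformed rows with row-level diagnostics.
#'
#' @param path Path to a CSV/TSV file.
#' @return A validated tibble of visit scores.
#' @export
read_visit_scores <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("No such file: %s", path), class = "tdcontrol_error_input")
  }
  reader <- if (grepl("\\.tsv$", path, ignore.case = TRUE))
    readr::read_tsv else readr::read_csv
  scores <- reader(path, show_col_types = FALSE, progress = FALSE)
  validate_visit_scores(scores)
}

#' @rdname read_visit_scores
#' @param scores A data frame to validate in place.
#' @export
validate_visit_scores <- function(scores) {
  check_score_frame(scores)
  if (nrow(scores) == 0L) {
    abort("The score table is empty (no patients).",
          class = "tdcontrol_error_validation")
  }
  scores$value <- parse_ascii_minus(scores$value)
  problems <- character()

  bad <- which(!scores$rater %in% c("assessor", "clinician"))
  if (length(bad)) problems <- c(problems, row_msg(bad, "unknown rater"))
  bad <- which(!scores$item_class %in% c("anamnestic", "clinical"))
  if (length(bad)) problems <- c(problems, row_msg(bad, "unknown item_class"))
  bad <- which(!scores$scale %in% c("points_0_4", "vas_0_100"))
  if (length(bad)) problems <- c(problems, row_msg(bad, "unknown scale"))
  bad <- which(!is.finite(scores$value))
  if (length(bad)) problems <- c(problems, row_msg(bad, "missing or non-numeric value"))

  pts <- scores$scale == "points_0_4" & is.finite(scores$value)
  bad <- which(pts & (scores$value < 0 | scores$value > 4 |
                        scores$value != round(scores$value)))
  if (length(bad)) {
    problems <- c(problems, row_msg(bad, "0-4 item value outside {0,1,2,3,4}"))
  }
  vas <- scores$scale == "vas_0_100" & is.finite(scores$value)
  bad <- which(vas & (scores$value < 0 | scores$value > 100))
  if (length(bad)) problems <- c(problems, row_msg(bad, "VAS value outside [0, 100]"))

  key <- paste(scores$patient_id, scores$occasion_order, scores$item_id,
               scores$rater, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) problems <- c(problems, row_msg(dup, "duplicate (patient, occasion, item, rater)"))

  ord <- scores |>
    dplyr::distinct(.data$patient_id, .data$occasion_order, .data$weeks_elapsed) |>
    dplyr::arrange(.data$patient_id, .data$occasion_order) |>
    dplyr::summarise(ok = !is.unsorted(.data$weeks_elapsed),
                     .by = "patient_id")
  if (any(!ord$ok)) {
    problems <- c(problems,
                  sprintf("weeks_elapsed not increasing with occasion_order for patient(s) %s",
                          paste(ord$patient_id[!ord$ok], collapse = ", ")))
  }

  if (length(problems)) {
    abort(c("Invalid visit-score table:", stats::setNames(problems, rep("x", length(problems)))),
          class = "tdcontrol_error_validation")
  }
  tibble::as_tibble(scores)
}

row_msg <- function(rows, what) {
  shown <- head(rows, 5)
  sprintf("%s at row(s) %s%s", what, paste(shown, collapse = ", "),
          if (length(rows) > 5) sprintf(" (+%d more)", length(rows) - 5) else "")
}

# inputs may carry a Unicode minus sign; outputs are always ASCII
parse_ascii_minus <- function(x) {
  if (is.character(x)) {
    x <- as.numeric(gsub("−", "-", x))
  }
  x
}

#' @rdname read_visit_scores
#' @param x A visit-score tibble to write.
#' @export
write_visit_scores <- function(x, path) {
  check_score_frame(x)
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(x, path, progress = FALSE)
  } else {
    readr::write_csv(x, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a run configuration from a YAML file
#'
#' Recognised top-level keys: `cutoffs` (arguments of [cutoff_config()]),
#' `thresholds` (arguments of [sdd_thresholds()]), `mode`, `policy`,
#' `precision`, `seed`, and `simulation` (arguments of
#' [simulation_config()]). Missing keys fall back to package defaults;
#' values are validated by the respective constructors at load time.
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @return A list with elements `cutoffs`, `thresholds`, `mode`, `policy`,
#'   `precision`, `seed`, `simulation`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  cutoffs <- do.call(cutoff_config, raw$cutoffs %||% list())
  thresholds <- do.call(sdd_thresholds, raw$thresholds %||% list())
  sim_args <- raw$simulation %||% list()
  if (!is.null(raw$seed) && is.null(sim_args$seed)) sim_args$seed <- raw$seed
  list(
    cutoffs = cutoffs,
    thresholds = thresholds,
    mode = raw$mode %||% "s-A",
    policy = raw$policy %||% "zero",
    precision = raw$precision %||% 3,
    seed = raw$seed %||% 1L,
    simulation = do.call(simulation_config, sim_args)
  )
}
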