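#' Per-visit TDC report for one patient
#'
#' Produces the reporting view of a patient's timeline: per-occasion overall,
#' anamnestic-subset and clinical-subset TDCs, rounded the way the original
#' score tables are — each Contrast rounded to `precision` decimals first,
#' then the subset means rounded to the same precision — plus the reference
#' ledger. Three decimals keep rounding error negligible when values are
#' transformed back to factors.
#'
#' @param scores Long-format visit scores (one or more patients).
#' @param patient_id Patient to report; may be omitted when `scores` holds a
#'   single patient.
#' @param mode,policy,thresholds See [assemble_reference_timeline()].
#' @param precision Decimals for reported values (default 3).
#' @return A list of class `tdc_patient_report`: `patient_id`, `tdc` (tibble
#'   with rounded `tdc`, `tdc_anamnestic`, `tdc_clinical` per occasion),
#'   `references` (the ledger), `precision`.
#' @export
#' @examples
#' path <- system.file("extdata", "worked_example_scores.csv", package = "tdcontrol")
#' report_patient(read_visit_scores(path))
report_patient <- function(scores, patient_id = NULL,
                           mode = c("s-A", "c-A", "NA"),
                           policy = c("zero", "baseline_relative"),
                           thresholds = sdd_thresholds(),
                           precision = 3) {
  check_score_frame(scores)
  if (!is.null(patient_id)) {
    scores <- scores[scores$patient_id == patient_id, , drop = FALSE]
    if (nrow(scores) == 0L) {
      abort(sprintf("Patient %s not found.", patient_id),
            class = "tdcontrol_error_input")
    }
  }
  tl <- assemble_reference_timeline(scores, mode = mode, policy = policy,
                                    thresholds = thresholds)
  ctr <- tl$contrasts
  ctr$contrast_rounded <- round_tdc(ctr$contrast, precision)
  rep_tbl <- ctr |>
    dplyr::summarise(
      n_items = dplyr::n(),
      tdc = round_tdc(mean(.data$contrast_rounded), precision),
      tdc_anamnestic = if (any(.data$item_class == "anamnestic"))
        round_tdc(mean(.data$contrast_rounded[.data$item_class == "anamnestic"]),
                  precision) else NA_real_,
      tdc_clinical = if (any(.data$item_class == "clinical"))
        round_tdc(mean(.data$contrast_rounded[.data$item_class == "clinical"]),
                  precision) else NA_real_,
      .by = c("occasion_label", "occasion_order", "weeks_elapsed", "rater")
    ) |>
    dplyr::arrange(.data$occasion_order)

  structure(
    list(patient_id = tl$patient_id, tdc = rep_tbl,
         references = tl$references, contrasts = ctr, precision = precision),
    class = "tdc_patient_report"
  )
}

#' @export
print.tdc_patient_report <- function(x, ...) {
  cat(sprintf("Patient %s: %d reference items (%d basic, %d added)\n",
              x$patient_id, nrow(x$references),
              sum(x$references$kind == "basic"),
              sum(x$references$kind == "added")))
  df <- as.data.frame(x$tdc[, c("occasion_label", "weeks_elapsed", "rater",
                                "n_items", "tdc", "tdc_anamnestic",
                                "tdc_clinical")])
  fmt <- function(v) ifelse(is.na(v), "", sprintf(paste0("%.", x$precision, "f"), v))
  df$tdc <- fmt(df$tdc)
  df$tdc_anamnestic <- fmt(df$tdc_anamnestic)
  df$tdc_clinical <- fmt(df$tdc_clinical)
  print(df, row.names = FALSE)
  invisible(x)
}
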