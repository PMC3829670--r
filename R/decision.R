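#' Decision cut-offs and therapy duration limits
#'
#' Two TDC cut-offs control treatment duration. The responsiveness cut-off
#' (default −0.212, a 35% decrease of a single pain score) decides, once the
#' therapy-specific minimum duration has elapsed, whether a patient responds
#' at all: a TDC above it ends treatment as unresponsive. The success cut-off
#' (default −0.379, a 55% decrease, derived from the maximal-severity
#' calibration profile, see [cutoff_from_profile()]) marks attainment of
#' functional status: treatment ends as potentially successful after the
#' required number of successive visits at or below it, spaced within the
#' confirmation interval, provided the anamnestic discrepancy rule does not
#' object. Boundary semantics follow the printed rules exactly: success is
#' inclusive (TDC ≤ cut-off) and non-responsiveness strictly above
#' (TDC > cut-off).
#'
#' @param responsiveness_cutoff TDC above which a patient is insufficiently
#'   responsive (negative).
#' @param success_cutoff TDC at or below which functional status is attained
#'   (more negative than `responsiveness_cutoff`).
#' @param consecutive_successes Number of successive qualifying visits needed
#'   to end treatment as potentially successful.
#' @param confirmation_interval Length-2 numeric: admissible spacing in weeks
#'   between those successive visits.
#' @param min_visits,max_visits Therapy-specific visit limits.
#' @param min_weeks,max_weeks Therapy-specific duration limits in weeks.
#' @return An object of class `cutoff_config`.
#' @export
cutoff_config <- function(responsiveness_cutoff = -0.212,
                          success_cutoff = -0.379,
                          consecutive_successes = 2,
                          confirmation_interval = c(3, 6),
                          min_visits = 3, max_visits = 15,
                          min_weeks = 6, max_weeks = 30) {
  if (!(success_cutoff < responsiveness_cutoff && responsiveness_cutoff < 0)) {
    abort("Require success_cutoff < responsiveness_cutoff < 0.",
          class = "tdcontrol_error_input")
  }
  if (length(confirmation_interval) != 2L ||
      any(confirmation_interval <= 0) ||
      confirmation_interval[1] > confirmation_interval[2]) {
    abort("`confirmation_interval` must be positive c(min, max) weeks.",
          class = "tdcontrol_error_input")
  }
  if (min_visits <= 0 || min_weeks <= 0 ||
      min_visits > max_visits || min_weeks > max_weeks) {
    abort("Therapy limits must be positive with min <= max.",
          class = "tdcontrol_error_input")
  }
  structure(
    list(responsiveness_cutoff = responsiveness_cutoff,
         success_cutoff = success_cutoff,
         consecutive_successes = consecutive_successes,
         confirmation_interval = confirmation_interval,
         min_visits = min_visits, max_visits = max_visits,
         min_weeks = min_weeks, max_weeks = max_weeks),
    class = "cutoff_config"
  )
}

#' The anamnestic discrepancy rule
#'
#' Patients express daily oral functioning through the anamnestic items,
#' clinicians through the clinical test items; patients tend to report less
#' improvement. The patient's opinion is given priority: when the overall TDC
#' indicates success (≤ success cut-off) but the anamnestic-subset TDC still
#' indicates insufficient effect (> responsiveness cut-off), the occasion's
#' classification is overruled to unfinished/unsuccessful. The rule can only
#' flip successful to unsuccessful, never the reverse.
#'
#' @param tdc_overall Overall TDC at the occasion.
#' @param tdc_anamnestic Anamnestic-subset TDC at the same occasion, from the
#'   same reference timeline; `NA` if no anamnestic reference item exists
#'   (the rule is then inapplicable and returns `FALSE` with a warning).
#' @param cfg A [cutoff_config()].
#' @return Logical: `TRUE` if the classification is overruled.
#' @export
#' @examples
#' discrepancy_rule(-0.674, -0.685, cutoff_config())  # FALSE: patient agrees
#' discrepancy_rule(-0.40, -0.10, cutoff_config())    # TRUE: overruled
discrepancy_rule <- function(tdc_overall, tdc_anamnestic, cfg = cutoff_config()) {
  if (is.na(tdc_anamnestic)) {
    warn("No anamnestic reference items; discrepancy rule is inapplicable.",
         .frequency = "once", .frequency_id = "tdcontrol_discrepancy_na")
    return(FALSE)
  }
  tdc_overall <= cfg$success_cutoff &&
    tdc_anamnestic > cfg$responsiveness_cutoff
}

#' Evaluate a treatment visit: continue or end
#'
#' Applies the visit-by-visit stopping logic to a patient's chronological
#' history of treatment-visit TDC values:
#' \enumerate{
#'   \item if the latest TDC exceeds the responsiveness cut-off after the
#'     therapy-specific minimum duration, treatment ends as unresponsive;
#'   \item if the latest `consecutive_successes` visits are all at or below
#'     the success cut-off, consecutively spaced within the confirmation
#'     interval, and the discrepancy rule does not object at the latest
#'     visit, treatment ends as potentially successful;
#'   \item otherwise treatment continues, unless the maximal duration or
#'     visit count is reached, in which case the patient is referred to the
#'     blinded assessor.
#' }
#'
#' @param history Data frame with one row per treatment visit so far, in
#'   chronological order: columns `tdc`, `tdc_anamnestic`, `weeks_elapsed`.
#' @param cfg A [cutoff_config()].
#' @return One of `"continue"`, `"end_unresponsive"`,
#'   `"end_potentially_successful"`, `"end_max_duration"`.
#' @export
evaluate_treatment_visit <- function(history, cfg = cutoff_config()) {
  if (!is.data.frame(history) || nrow(history) == 0L ||
      !all(c("tdc", "weeks_elapsed") %in% names(history))) {
    abort("`history` must be a non-empty data frame with columns tdc, weeks_elapsed.",
          class = "tdcontrol_error_input")
  }
  wk <- history$weeks_elapsed
  if (is.unsorted(wk, strictly = FALSE)) {
    abort("`history` must be chronological.", class = "tdcontrol_error_input")
  }
  n <- nrow(history)
  latest <- history[n, ]

  if (latest$weeks_elapsed >= cfg$min_weeks &&
      latest$tdc > cfg$responsiveness_cutoff) {
    return("end_unresponsive")
  }

  k <- cfg$consecutive_successes
  if (n >= k) {
    last_k <- history[(n - k + 1L):n, ]
    gaps <- diff(last_k$weeks_elapsed)
    anam <- if ("tdc_anamnestic" %in% names(latest)) latest$tdc_anamnestic else NA_real_
    if (all(last_k$tdc <= cfg$success_cutoff) &&
        all(gaps >= cfg$confirmation_interval[1] &
            gaps <= cfg$confirmation_interval[2]) &&
        !discrepancy_rule(latest$tdc, anam, cfg)) {
      return("end_potentially_successful")
    }
  }

  if (latest$weeks_elapsed >= cfg$max_weeks || n >= cfg$max_visits) {
    return("end_max_duration")
  }
  "continue"
}

#' Classify treatment outcome at a post-treatment occasion
#'
#' At the end measurement (EM) and follow-up occasions the blinded assessor's
#' TDC decides the outcome: successful iff TDC ≤ success cut-off and the
#' anamnestic discrepancy rule does not overrule it. A clinician's
#' unfavourable pre-end measurement does not block success: if the
#' assessor's TDC meets the criterion the short-term outcome is successful
#' and the patient continues to follow-up.
#'
#' @param tdc_value Overall TDC at the occasion (assessor data).
#' @param tdc_anamnestic Anamnestic-subset TDC at the occasion.
#' @param cfg A [cutoff_config()].
#' @return A list with `classification` ("successful"/"unsuccessful") and
#'   `discrepancy` (logical).
#' @export
#' @examples
#' classify_post_treatment(-0.674, -0.685)          # successful
#' classify_post_treatment(-0.379, -0.50)           # boundary is inclusive
classify_post_treatment <- function(tdc_value, tdc_anamnestic,
                                    cfg = cutoff_config()) {
  overruled <- discrepancy_rule(tdc_value, tdc_anamnestic, cfg)
  ok <- tdc_value <= cfg$success_cutoff && !overruled
  list(classification = if (ok) "successful" else "unsuccessful",
       discrepancy = overruled)
}

#' Follow-up evaluation to the last measurement
#'
#' Patients whose treatment is unsuccessful in the short term (at EM) have no
#' follow-up — their treatment is stepped up or changed — so their last
#' measurement (LM) equals EM. Patients successful at EM are re-evaluated at
#' 6 and 12 months; the first unsuccessful occasion terminates follow-up and
#' becomes LM, otherwise LM is the final follow-up occasion.
#'
#' @param em A list as returned by [classify_post_treatment()] for EM, plus
#'   elements `occasion_label` and `tdc_value`.
#' @param followups Data frame of follow-up occasions in chronological order:
#'   columns `occasion_label`, `tdc`, `tdc_anamnestic`.
#' @param cfg A [cutoff_config()].
#' @return A list: `lm_occasion`, `lm_tdc`, `lm_class`, `lm_discrepancy`,
#'   `followup_complete` (FALSE when a patient successful at EM lacks
#'   follow-up scores; such patients are excluded from LM summaries).
#' @export
run_followup <- function(em, followups, cfg = cutoff_config()) {
  if (em$classification == "unsuccessful") {
    return(list(lm_occasion = em$occasion_label, lm_tdc = em$tdc_value,
                lm_class = "unsuccessful", lm_discrepancy = em$discrepancy,
                followup_complete = TRUE))
  }
  if (is.null(followups) || nrow(followups) == 0L) {
    return(list(lm_occasion = NA_character_, lm_tdc = NA_real_,
                lm_class = NA_character_, lm_discrepancy = NA,
                followup_complete = FALSE))
  }
  for (j in seq_len(nrow(followups))) {
    cl <- classify_post_treatment(followups$tdc[j],
                                  followups$tdc_anamnestic[j], cfg)
    if (cl$classification == "unsuccessful" || j == nrow(followups)) {
      return(list(lm_occasion = followups$occasion_label[j],
                  lm_tdc = followups$tdc[j],
                  lm_class = cl$classification,
                  lm_discrepancy = cl$discrepancy,
                  followup_complete = TRUE))
    }
  }
}

#' Run the full decision procedure for one patient
#'
#' Consumes a patient's per-occasion TDC table (from
#' [assemble_reference_timeline()] or [compute_tdc()]) and produces the
#' decision trace: the terminal treatment action, the classification at the
#' pre-end measurement (PEM, clinician's last treatment visit), the end
#' measurement (EM, blinded assessor) and the last measurement (LM, after
#' follow-up), plus duration and visit counts.
#'
#' @param tdc_tbl One patient's TDC table: columns `patient_id`,
#'   `occasion_label`, `occasion_order`, `weeks_elapsed`, `rater`, `tdc`,
#'   `tdc_anamnestic`.
#' @param cfg A [cutoff_config()].
#' @return A one-row tibble (an outcome record).
#' @export
decide_patient <- function(tdc_tbl, cfg = cutoff_config()) {
  pid <- unique(tdc_tbl$patient_id)
  if (length(pid) != 1L) {
    abort("`tdc_tbl` must contain exactly one patient.",
          class = "tdcontrol_error_input")
  }
  tdc_tbl <- tdc_tbl[order(tdc_tbl$occasion_order), , drop = FALSE]
  tx <- tdc_tbl[tdc_tbl$rater == "clinician", , drop = FALSE]
  post <- tdc_tbl[tdc_tbl$rater == "assessor" &
                    tdc_tbl$occasion_order > min(tdc_tbl$occasion_order), ,
                  drop = FALSE]

  action <- "continue"
  n_visits <- 0L
  for (v in seq_len(nrow(tx))) {
    action <- evaluate_treatment_visit(tx[seq_len(v), , drop = FALSE], cfg)
    n_visits <- v
    if (action != "continue") break
  }
  if (action == "continue" && nrow(tx) > 0L) {
    # data ran out before a stopping rule fired; refer to the assessor
    action <- "end_of_data"
  }

  if (nrow(tx) > 0L) {
    pem <- tx[n_visits, ]
    pem_disc <- discrepancy_rule(pem$tdc, pem$tdc_anamnestic, cfg)
    pem_class <- if (pem$tdc <= cfg$success_cutoff && !pem_disc)
      "successful" else "unsuccessful"
    duration_weeks <- pem$weeks_elapsed
  } else {
    pem <- NULL
    pem_disc <- NA
    pem_class <- NA_character_
    duration_weeks <- NA_real_
  }

  if (nrow(post) == 0L) {
    abort(sprintf("Patient %s has no post-treatment assessor occasion.", pid),
          class = "tdcontrol_error_input")
  }
  em_row <- post[1L, ]
  em_cl <- classify_post_treatment(em_row$tdc, em_row$tdc_anamnestic, cfg)
  em <- c(em_cl, list(occasion_label = em_row$occasion_label,
                      tdc_value = em_row$tdc))
  fu <- post[-1L, , drop = FALSE]
  lm <- run_followup(em, fu, cfg)

  tibble::tibble(
    patient_id = pid,
    terminal_action = action,
    n_visits = n_visits,
    duration_weeks = duration_weeks,
    pem_tdc = if (is.null(pem)) NA_real_ else pem$tdc,
    pem_class = pem_class,
    pem_discrepancy = pem_disc,
    em_occasion = em_row$occasion_label,
    em_tdc = em_row$tdc,
    em_class = em_cl$classification,
    em_discrepancy = em_cl$discrepancy,
    lm_occasion = lm$lm_occasion,
    lm_tdc = lm$lm_tdc,
    lm_class = lm$lm_class,
    lm_discrepancy = lm$lm_discrepancy,
    followup_complete = lm$followup_complete
  )
}

#' Success rate of a cohort at an evaluation occasion
#'
#' @param outcomes Outcome records, one row per patient (see
#'   [decide_patient()] or [run_trial()]).
#' @param occasion `"PEM"`, `"EM"` or `"LM"`.
#' @return A one-row tibble: `occasion`, `n`, `n_successful`,
#'   `n_unsuccessful`, `n_discrepancy`, `success_pct`. Patients with an
#'   incomplete follow-up are excluded from LM summaries.
#' @export
#' @examples
#' df <- tibble::tibble(em_class = rep(c("successful", "unsuccessful"), c(89, 29)),
#'                      em_discrepancy = FALSE, followup_complete = TRUE)
#' success_rate(df, "EM")  # 75.4% of 118
success_rate <- function(outcomes, occasion = c("EM", "LM", "PEM")) {
  occasion <- match.arg(occasion)
  col <- switch(occasion, PEM = "pem_class", EM = "em_class", LM = "lm_class")
  disc <- switch(occasion, PEM = "pem_discrepancy", EM = "em_discrepancy",
                 LM = "lm_discrepancy")
  cls <- outcomes[[col]]
  dsc <- outcomes[[disc]]
  if (occasion == "LM") {
    keep <- !is.na(cls)
    cls <- cls[keep]
    dsc <- dsc[keep]
  }
  if (length(cls) == 0L) {
    abort("No patients to summarise.", class = "tdcontrol_error_input")
  }
  tibble::tibble(
    occasion = occasion,
    n = length(cls),
    n_successful = sum(cls == "successful"),
    n_unsuccessful = sum(cls == "unsuccessful"),
    n_discrepancy = sum(dsc, na.rm = TRUE),
    success_pct = 100 * sum(cls == "successful") / length(cls)
  )
}
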