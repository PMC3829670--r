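#' Smallest-detectable-difference thresholds for reference-item selection
#'
#' Reference items are only worth monitoring when their maximally possible
#' decrease towards zero exceeds the smallest detectable difference (SDD) of a
#' single score, so chance test-retest fluctuation cannot masquerade as
#' relative change. On the adjectival 0-4 point scales the short-term SDD is
#' 1.9 units (basic reference items therefore need a baseline of at least 2)
#' and the long-term SDD is 2.2 units (items added later need to reach 3 or
#' 4 from a baseline of 0 or 1). The long-term SDD of the 0-100 mm pain VAS
#' is 49 mm.
#'
#' @param sdd_short_points Short-term SDD of a single 0-4 score, in scale
#'   units.
#' @param sdd_long_points Long-term SDD of a single 0-4 score.
#' @param sdd_long_vas Long-term SDD of a single 0-100 mm VAS score.
#' @param vas_reference_min Minimum baseline VAS (mm) for the predominant-pain
#'   item to become a basic reference. All enrolled patients present with
#'   pain, so any positive baseline qualifies by default.
#' @return An object of class `sdd_thresholds`.
#' @export
sdd_thresholds <- function(sdd_short_points = 1.9,
                           sdd_long_points = 2.2,
                           sdd_long_vas = 49,
                           vas_reference_min = 0) {
  if (sdd_short_points <= 0 || sdd_long_points <= 0 || sdd_long_vas <= 0) {
    abort("SDD thresholds must be positive.", class = "tdcontrol_error_input")
  }
  if (sdd_short_points >= sdd_long_points) {
    abort("The short-term SDD must be below the long-term SDD on the 0-4 scale.",
          class = "tdcontrol_error_input")
  }
  structure(
    list(
      sdd_short_points = sdd_short_points,
      sdd_long_points = sdd_long_points,
      sdd_long_vas = sdd_long_vas,
      vas_reference_min = vas_reference_min,
      # smallest integer score whose full decrease to zero exceeds each SDD
      basic_min_score = ceiling(sdd_short_points),
      added_min_score = ceiling(sdd_long_points)
    ),
    class = "sdd_thresholds"
  )
}

# columns every long-format visit-score table must carry
score_columns <- c("patient_id", "occasion_label", "occasion_order",
                   "weeks_elapsed", "rater", "item_id", "item_class",
                   "scale", "value")

check_score_frame <- function(scores, arg = "scores") {
  if (!is.data.frame(scores)) {
    abort(sprintf("`%s` must be a data frame of visit scores.", arg),
          class = "tdcontrol_error_input")
  }
  missing <- setdiff(score_columns, names(scores))
  if (length(missing)) {
    abort(sprintf("`%s` is missing columns: %s.", arg,
                  paste(missing, collapse = ", ")),
          class = "tdcontrol_error_input")
  }
  invisible(scores)
}

#' Select basic reference items from a baseline examination
#'
#' Every 0-4 item whose baseline score reaches at least 2 units (its maximal
#' decrease towards zero then exceeds the short-term SDD of 1.9 units) becomes
#' a basic reference item, with the baseline score as its reference score.
#' The VAS item for intensity of the predominant pain is also a basic
#' reference whenever its baseline exceeds `vas_reference_min` (0 mm by
#' default, since enrolled patients present with pain).
#'
#' @param baseline Data frame of baseline scores for one patient: one row per
#'   item with at least `item_id`, `item_class`, `scale`, `value`.
#' @param thresholds An [sdd_thresholds()] object.
#' @return A tibble of reference items: `item_id`, `item_class`, `scale`,
#'   `kind` ("basic"), `baseline_score`, `reference_score`,
#'   `reference_occasion` (0 for baseline), `added_by` (NA for basic items).
#' @export
select_basic_references <- function(baseline, thresholds = sdd_thresholds()) {
  if (!is.data.frame(baseline) ||
      !all(c("item_id", "item_class", "scale", "value") %in% names(baseline))) {
    abort("`baseline` needs columns item_id, item_class, scale, value.",
          class = "tdcontrol_error_input")
  }
  if (anyDuplicated(baseline$item_id)) {
    abort("`baseline` must contain exactly one score per item.",
          class = "tdcontrol_error_input")
  }
  check_scores(baseline$value, "baseline$value")
  is_ref <- ifelse(baseline$scale == "vas_0_100",
                   baseline$value > thresholds$vas_reference_min,
                   baseline$value >= thresholds$basic_min_score)
  refs <- baseline[is_ref, c("item_id", "item_class", "scale", "value")]
  tibble::tibble(
    item_id = refs$item_id,
    item_class = refs$item_class,
    scale = refs$scale,
    kind = rep("basic", nrow(refs)),
    baseline_score = refs$value,
    reference_score = refs$value,
    reference_occasion = rep(0L, nrow(refs)),
    added_by = rep(NA_character_, nrow(refs))
  )
}

#' Detect reference items added at a later visit
#'
#' A 0-4 item that was not yet a reference becomes an added reference when its
#' score rises from a baseline of 0 or 1 to 3 or 4: the potential decrease of
#' at least 3 units then exceeds the long-term SDD of 2.2 units. The score at
#' the visit of addition becomes the item's reference score for subsequent
#' visits. Items that are already references are never re-added, and the VAS
#' item can only ever be a basic reference.
#'
#' @param refs Current reference tibble (as from [select_basic_references()]).
#' @param visit Data frame of this visit's scores (same shape as `baseline`).
#' @param baseline Data frame of baseline scores.
#' @param occasion_order Integer order of the visit (for the ledger).
#' @param added_by Rater responsible for the addition ("clinician" or
#'   "assessor").
#' @param thresholds An [sdd_thresholds()] object.
#' @return A tibble of newly added reference items (possibly zero rows), same
#'   columns as [select_basic_references()].
#' @export
detect_added_references <- function(refs, visit, baseline,
                                    occasion_order = NA_integer_,
                                    added_by = "clinician",
                                    thresholds = sdd_thresholds()) {
  base_val <- setNames(baseline$value, baseline$item_id)
  cand <- visit[
    !(visit$item_id %in% refs$item_id) &
      visit$scale == "points_0_4" &
      visit$value >= thresholds$added_min_score, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_reference_tibble())
  b <- base_val[cand$item_id]
  keep <- !is.na(b) & b < thresholds$basic_min_score
  cand <- cand[keep, , drop = FALSE]
  tibble::tibble(
    item_id = cand$item_id,
    item_class = cand$item_class,
    scale = cand$scale,
    kind = rep("added", nrow(cand)),
    baseline_score = unname(base_val[cand$item_id]),
    reference_score = cand$value,
    reference_occasion = rep(as.integer(occasion_order), nrow(cand)),
    added_by = rep(added_by, nrow(cand))
  )
}

empty_reference_tibble <- function() {
  tibble::tibble(
    item_id = character(), item_class = character(), scale = character(),
    kind = character(), baseline_score = numeric(), reference_score = numeric(),
    reference_occasion = integer(), added_by = character()
  )
}

#' Initial Contrast of a reference item at its reference visit
#'
#' At the visit where an item becomes a reference its Contrast can be set in
#' two ways. Under the `"baseline_relative"` policy an added item's initial
#' Contrast is computed against its pre-treatment baseline, giving a positive
#' value between +0.5 (1 to 3) and +1 (0 to 3 or 4) that flags the worsening;
#' under the `"zero"` policy the initial Contrast is 0, treating added items
#' exactly like basic ones (whose Contrast at baseline is 0 under either
#' policy). The zero policy removes most of the between-mode bias in
#' post-treatment TDC values and is the default.
#'
#' @param refs Reference tibble rows (see [select_basic_references()]).
#' @param policy `"zero"` or `"baseline_relative"`.
#' @return Numeric vector of initial Contrast values, one per row of `refs`.
#' @export
#' @examples
#' added <- tibble::tibble(kind = "added", baseline_score = 1, reference_score = 3)
#' initial_contrast(added, policy = "baseline_relative")  # +0.5
#' initial_contrast(added, policy = "zero")               # 0
initial_contrast <- function(refs, policy = c("zero", "baseline_relative")) {
  policy <- match.arg(policy)
  out <- numeric(nrow(refs))
  if (policy == "baseline_relative") {
    is_added <- refs$kind == "added"
    out[is_added] <- contrast(refs$baseline_score[is_added],
                              refs$reference_score[is_added])
  }
  out
}

#' Assemble a patient's reference timeline and per-occasion Contrasts
#'
#' Walks one patient's visit scores in chronological order, maintaining the
#' evolving reference set and computing the Contrast of every active
#' reference item at every occasion, under a mode of adding reference items
#' and an initial-Contrast policy. Once an item is a reference its Contrast
#' keeps contributing at every subsequent occasion, even if its score wanes
#' to zero.
#'
#' Modes:
#' \describe{
#'   \item{`"s-A"`}{Separate addition. Treatment-visit TDCs use the
#'     clinician's additions, but the post-treatment TDCs treat the treatment
#'     period as a black box: clinician additions are discarded and only
#'     additions detected in the blinded assessor's post-treatment data count,
#'     with the reference taken relative to baseline. This keeps post-treatment
#'     outcomes free of clinician-bound bias and of differences in visit
#'     frequency or treatment duration. The standard mode.}
#'   \item{`"c-A"`}{Continued addition: clinician additions persist into the
#'     post-treatment occasions with their treatment-period reference scores,
#'     and assessor additions accumulate on top.}
#'   \item{`"NA"`}{No additions: only basic reference items, at every
#'     occasion.}
#' }
#'
#' @param scores Long-format visit scores for a single patient (see
#'   [read_visit_scores()] for the column contract). The baseline occasion is
#'   the row set with the smallest `occasion_order`; treatment visits carry
#'   `rater = "clinician"` and post-treatment occasions `rater = "assessor"`.
#' @param mode Addition mode: `"s-A"`, `"c-A"` or `"NA"`.
#' @param policy Initial-Contrast policy, see [initial_contrast()].
#' @param thresholds An [sdd_thresholds()] object.
#' @return A list of class `tdc_timeline` with elements `patient_id`,
#'   `mode`, `policy`, `references` (the reference ledger, including
#'   provenance of additions), `contrasts` (one row per active reference item
#'   per occasion) and `tdc` (one row per occasion with `tdc`,
#'   `tdc_anamnestic`, `tdc_clinical` and item counts).
#' @export
assemble_reference_timeline <- function(scores,
                                        mode = c("s-A", "c-A", "NA"),
                                        policy = c("zero", "baseline_relative"),
                                        thresholds = sdd_thresholds()) {
  mode <- match.arg(mode)
  policy <- match.arg(policy)
  check_score_frame(scores)
  pid <- unique(scores$patient_id)
  if (length(pid) != 1L) {
    abort("`scores` must contain exactly one patient; see compute_tdc() for cohorts.",
          class = "tdcontrol_error_input")
  }

  occ <- unique(scores[, c("occasion_label", "occasion_order", "weeks_elapsed", "rater")])
  occ <- occ[order(occ$occasion_order), , drop = FALSE]
  if (anyDuplicated(occ$occasion_order)) {
    abort("Conflicting occasion metadata: one occasion_order maps to several labels/raters.",
          class = "tdcontrol_error_input")
  }
  if (is.unsorted(occ$weeks_elapsed, strictly = FALSE)) {
    abort("`weeks_elapsed` must be non-decreasing with `occasion_order`.",
          class = "tdcontrol_error_input")
  }

  base_order <- occ$occasion_order[1L]
  baseline <- scores[scores$occasion_order == base_order, , drop = FALSE]
  basic <- select_basic_references(baseline, thresholds)
  if (nrow(basic) == 0L) {
    abort(sprintf("Patient %s has no reference items at baseline (no pronounced signs).",
                  pid),
          class = "tdcontrol_error_no_references")
  }

  # ledgers: clinician view (treatment phase) and assessor view (post phase)
  clin_refs <- basic
  post_refs <- basic   # grows with assessor additions; for c-A also clinician ones
  clin_handover_done <- FALSE

  contrast_rows <- vector("list", nrow(occ))
  for (k in seq_len(nrow(occ))) {
    ok <- occ$occasion_order[k]
    visit <- scores[scores$occasion_order == ok, , drop = FALSE]
    is_baseline <- k == 1L
    is_treatment <- !is_baseline && occ$rater[k] == "clinician"
    is_post <- !is_baseline && occ$rater[k] == "assessor"

    if (is_treatment && mode != "NA") {
      adds <- detect_added_references(clin_refs, visit, baseline,
                                      occasion_order = ok,
                                      added_by = "clinician",
                                      thresholds = thresholds)
      clin_refs <- dplyr::bind_rows(clin_refs, adds)
    }
    if (is_post && mode == "c-A" && !clin_handover_done) {
      # clinician additions persist post-treatment with their treatment reference
      post_refs <- clin_refs
      clin_handover_done <- TRUE
    }
    if (is_post && mode != "NA") {
      adds <- detect_added_references(post_refs, visit, baseline,
                                      occasion_order = ok,
                                      added_by = "assessor",
                                      thresholds = thresholds)
      post_refs <- dplyr::bind_rows(post_refs, adds)
    }

    active <- if (is_treatment) {
      if (mode == "NA") basic else clin_refs
    } else if (is_post) {
      if (mode == "NA") basic else post_refs
    } else {
      basic
    }

    val <- setNames(visit$value, visit$item_id)
    v <- val[active$item_id]
    if (anyNA(v)) {
      abort(sprintf("Patient %s, occasion %s: reference item(s) %s have no score.",
                    pid, occ$occasion_label[k],
                    paste(active$item_id[is.na(v)], collapse = ", ")),
            class = "tdcontrol_error_input")
    }
    at_ref_visit <- active$reference_occasion == ok |
      (is_baseline & active$kind == "basic")
    ci <- contrast(active$reference_score, unname(v))
    ci[at_ref_visit] <- initial_contrast(active[at_ref_visit, , drop = FALSE],
                                         policy = policy)
    contrast_rows[[k]] <- tibble::tibble(
      occasion_label = occ$occasion_label[k],
      occasion_order = ok,
      weeks_elapsed = occ$weeks_elapsed[k],
      rater = occ$rater[k],
      item_id = active$item_id,
      item_class = active$item_class,
      kind = active$kind,
      reference_score = active$reference_score,
      score = unname(v),
      contrast = ci
    )
  }

  contrasts <- dplyr::bind_rows(contrast_rows)
  tdc_tbl <- contrasts |>
    dplyr::group_by(.data$occasion_label, .data$occasion_order,
                    .data$weeks_elapsed, .data$rater) |>
    dplyr::summarise(
      n_items = dplyr::n(),
      tdc = mean(.data$contrast),
      n_anamnestic = sum(.data$item_class == "anamnestic"),
      tdc_anamnestic = if (any(.data$item_class == "anamnestic"))
        mean(.data$contrast[.data$item_class == "anamnestic"]) else NA_real_,
      n_clinical = sum(.data$item_class == "clinical"),
      tdc_clinical = if (any(.data$item_class == "clinical"))
        mean(.data$contrast[.data$item_class == "clinical"]) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$occasion_order) |>
    dplyr::mutate(patient_id = pid, .before = 1)

  references <- dplyr::bind_rows(
    basic,
    if (mode != "NA") clin_refs[clin_refs$kind == "added", , drop = FALSE],
    if (mode != "NA") post_refs[post_refs$kind == "added" &
                                  post_refs$added_by == "assessor", , drop = FALSE]
  )
  references <- references[!duplicated(references[c("item_id", "added_by")]), , drop = FALSE]

  structure(
    list(patient_id = pid, mode = mode, policy = policy,
         references = tibble::as_tibble(references),
         contrasts = contrasts, tdc = tdc_tbl),
    class = "tdc_timeline"
  )
}

#' @export
print.tdc_timeline <- function(x, ...) {
  cat(sprintf("<tdc_timeline> patient %s  (mode %s, policy %s)\n",
              x$patient_id, x$mode, x$policy))
  cat(sprintf("  %d reference items (%d basic, %d added)\n",
              nrow(x$references), sum(x$references$kind == "basic"),
              sum(x$references$kind == "added")))
  print(x$tdc, ...)
  invisible(x)
}

#' Per-occasion TDC values for a cohort
#'
#' Applies [assemble_reference_timeline()] to every patient in a long-format
#' visit-score table and binds the per-occasion TDC rows.
#'
#' @inheritParams assemble_reference_timeline
#' @param scores Long-format visit scores for one or more patients.
#' @return A tibble with one row per patient per occasion: `patient_id`,
#'   occasion metadata, `n_items`, `tdc`, `tdc_anamnestic`, `tdc_clinical`
#'   and subset counts.
#' @export
compute_tdc <- function(scores, mode = c("s-A", "c-A", "NA"),
                        policy = c("zero", "baseline_relative"),
                        thresholds = sdd_thresholds()) {
  mode <- match.arg(mode)
  policy <- match.arg(policy)
  check_score_frame(scores)
  scores |>
    dplyr::group_split(.data$patient_id) |>
    purrr::map(\(p) assemble_reference_timeline(p, mode = mode, policy = policy,
                                                thresholds = thresholds)$tdc) |>
    dplyr::bind_rows()
}
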