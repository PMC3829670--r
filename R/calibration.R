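#' Baseline severity profile of a patient's reference items
#'
#' A severity profile counts how many 0-4 reference items score 2, 3 and 4 at
#' baseline. The summed score is the primary severity ranking criterion and
#' the number of reference items the secondary one; the maximal profile in a
#' sample calibrates the success cut-off (see [cutoff_from_profile()]).
#'
#' @param counts Named numeric vector mapping score values to item counts,
#'   e.g. `c("2" = 7, "3" = 10, "4" = 15)`.
#' @return An object of class `severity_profile` with elements `counts`,
#'   `summed_score`, `n_items`, `mean_level_pct` (mean score as a percentage
#'   of the scale maximum 4).
#' @export
#' @examples
#' severity_profile(c("2" = 7, "3" = 10, "4" = 15))  # summed score 104, 32 items
severity_profile <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- setNames(counts$count, counts$score)
  }
  v <- suppressWarnings(as.numeric(names(counts)))
  if (length(counts) == 0L || anyNA(v) || any(counts < 0) ||
      !is.numeric(counts)) {
    abort("`counts` must be a named vector mapping score values to item counts.",
          class = "tdcontrol_error_input")
  }
  counts <- counts[counts > 0]
  v <- as.numeric(names(counts))
  n_items <- sum(counts)
  if (n_items == 0) {
    abort("The profile has no items.", class = "tdcontrol_error_input")
  }
  summed <- sum(v * counts)
  structure(
    list(counts = counts,
         summed_score = summed,
         n_items = n_items,
         mean_level_pct = 100 * (summed / n_items) / 4),
    class = "severity_profile"
  )
}

#' @export
print.severity_profile <- function(x, ...) {
  cat(sprintf("<severity_profile> %s; summed score %g over %g items (mean level %.0f%%)\n",
              paste(sprintf("%s x '%s'", x$counts, names(x$counts)), collapse = ", "),
              x$summed_score, x$n_items, x$mean_level_pct))
  invisible(x)
}

#' Derive the success cut-off from a maximal-severity profile and a ULFS
#'
#' The success cut-off of TDC is tuned so that the patient with overall
#' maximal signs and symptoms just attains the upper limit of functional
#' status (ULFS): the cut-off is the mean Contrast between each of that
#' patient's baseline reference scores and the ULFS level,
#' \eqn{\sum_v n_v \, C(v, ULFS) / n}. Because end levels are proportional to
#' baseline, the same overall treatment factor \eqn{T} brings every patient
#' with smaller baselines below the ULFS (see [functional_status_check()]).
#' Computation is full precision; apply [round_tdc()] for reporting and
#' [cutoff_rounded_to_percent()] for the shipped decision cut-off.
#'
#' @param profile A [severity_profile()] (or a named count vector accepted by
#'   it).
#' @param ulfs Upper limit of functional status, in 0-4 scale units; must lie
#'   strictly below every score value in the profile.
#' @return A one-row tibble: `cutoff` (TDC units), `factor_recip`
#'   (\eqn{1/T = (1 + TDC)/(1 - TDC)}), `factor_T`, `pct_decrease` (the
#'   percentage decrease of a single score that the cut-off corresponds to),
#'   `summed_score`, `n_items`.
#' @export
#' @examples
#' cutoff_from_profile(c("2" = 7, "3" = 10, "4" = 15), ulfs = 1.40)
cutoff_from_profile <- function(profile, ulfs) {
  if (!inherits(profile, "severity_profile")) profile <- severity_profile(profile)
  if (!is.numeric(ulfs) || length(ulfs) != 1L || ulfs <= 0) {
    abort("`ulfs` must be a single positive score level.",
          class = "tdcontrol_error_input")
  }
  v <- as.numeric(names(profile$counts))
  if (ulfs >= min(v)) {
    abort("ULFS must lie below every profile score value (those items are already functional).",
          class = "tdcontrol_error_input")
  }
  co <- sum(profile$counts * contrast(v, ulfs)) / profile$n_items
  recip <- contrast_to_factor(co)
  tibble::tibble(
    cutoff = co,
    factor_recip = recip,
    factor_T = 1 / recip,
    pct_decrease = (1 - recip) * 100,
    summed_score = profile$summed_score,
    n_items = profile$n_items
  )
}

#' Round a calibrated cut-off through the percent-decrease chain
#'
#' The shipped decision cut-off is not the raw calibration value but the
#' result of rounding its single-score percent decrease to a whole percent
#' and transforming back: the calibration value −0.378 corresponds to a
#' 54.9% decrease, rounded to 55%, giving the decision cut-off −0.379.
#'
#' @param cutoff Calibrated cut-off in TDC units (negative).
#' @return The decision cut-off, rounded to 3 decimals.
#' @export
#' @examples
#' cutoff_rounded_to_percent(cutoff_from_profile(c("2" = 7, "3" = 10, "4" = 15), 1.4)$cutoff)
cutoff_rounded_to_percent <- function(cutoff) {
  pct <- round((1 - contrast_to_factor(cutoff)) * 100)
  round_tdc(factor_to_contrast(1 - pct / 100))
}

#' Rank patients by baseline severity
#'
#' Orders severity profiles by summed baseline score (primary criterion) and
#' number of reference items (secondary, for ties), both descending. The top
#' profile is the maximal-severity patient used for calibration.
#'
#' @param profiles Data frame with columns `patient_id`, `summed_score`,
#'   `n_items` (one row per patient), or a list of [severity_profile()]
#'   objects named by patient.
#' @return The input as a tibble, ordered most severe first, with a `rank`
#'   column.
#' @export
rank_patients_by_severity <- function(profiles) {
  if (!is.data.frame(profiles)) {
    profiles <- tibble::tibble(
      patient_id = names(profiles) %||% as.character(seq_along(profiles)),
      summed_score = purrr::map_dbl(profiles, "summed_score"),
      n_items = purrr::map_dbl(profiles, "n_items")
    )
  }
  if (nrow(profiles) == 0L) {
    abort("`profiles` is empty.", class = "tdcontrol_error_input")
  }
  out <- dplyr::arrange(tibble::as_tibble(profiles),
                        dplyr::desc(.data$summed_score),
                        dplyr::desc(.data$n_items))
  out$rank <- seq_len(nrow(out))
  out
}

#' Severity profiles of a cohort's baseline reference items
#'
#' Convenience builder: selects each patient's basic 0-4 reference items from
#' a long-format baseline table and returns one profile row per patient.
#'
#' @param scores Long-format visit scores (baseline rows are used).
#' @param thresholds An [sdd_thresholds()] object.
#' @return A tibble: `patient_id`, `summed_score`, `n_items`.
#' @export
severity_profiles_from_scores <- function(scores, thresholds = sdd_thresholds()) {
  check_score_frame(scores)
  scores |>
    dplyr::filter(.data$occasion_order == min(.data$occasion_order),
                  .by = "patient_id") |>
    dplyr::filter(.data$scale == "points_0_4",
                  .data$value >= thresholds$basic_min_score) |>
    dplyr::summarise(summed_score = sum(.data$value),
                     n_items = dplyr::n(),
                     .by = "patient_id")
}

#' Weighted-percentile estimate of the upper limit of functional status
#'
#' The ULFS can be estimated in retrospect as a high percentile (default
#' 95th) of the post-treatment score distribution of successfully treated
#' patients. Items differ in their chance of being a reference item, so each
#' observation is weighted by its item's reference chance before the
#' percentile is taken. The percentile convention is the step function: the
#' smallest score whose cumulative weight reaches the target fraction of the
#' total weight (no interpolation), appropriate for discrete 0-4 scores.
#'
#' @param post_scores Data frame with columns `item_id` and `score`
#'   (post-treatment 0-4 scores, one row per observation).
#' @param reference_chance Named numeric vector (or data frame `item_id`,
#'   `chance`) of per-item reference probabilities in (0, 1].
#' @param pct Percentile, in percent (default 95).
#' @return A one-row tibble: `value` (score units), `percentile`,
#'   `total_weight`, `n_obs`.
#' @export
weighted_percentile_ulfs <- function(post_scores, reference_chance, pct = 95) {
  if (!is.data.frame(post_scores) ||
      !all(c("item_id", "score") %in% names(post_scores)) ||
      nrow(post_scores) == 0L) {
    abort("`post_scores` must be a non-empty data frame with item_id and score.",
          class = "tdcontrol_error_input")
  }
  if (is.data.frame(reference_chance)) {
    reference_chance <- setNames(reference_chance$chance,
                                 reference_chance$item_id)
  }
  if (any(reference_chance <= 0) || any(reference_chance > 1)) {
    abort("Reference chances must lie in (0, 1].", class = "tdcontrol_error_input")
  }
  w <- reference_chance[as.character(post_scores$item_id)]
  if (anyNA(w)) {
    abort("Some items have no reference chance.", class = "tdcontrol_error_input")
  }
  tw <- sum(w)
  if (tw <= 0) {
    abort("Total weight is zero.", class = "tdcontrol_error_input")
  }
  agg <- tapply(w, post_scores$score, sum)
  s <- as.numeric(names(agg))
  o <- order(s)
  cumw <- cumsum(agg[o]) / tw
  value <- s[o][match(TRUE, cumw >= pct / 100 - 1e-12)]
  tibble::tibble(value = value, percentile = pct, total_weight = tw,
                 n_obs = nrow(post_scores))
}

#' Does a baseline reach functional status under a treatment factor?
#'
#' If the maximal baseline \eqn{m} requires the treatment factor
#' \eqn{T = m/ULFS} to reach the upper limit of functional status, any
#' smaller baseline \eqn{s} treated with the same factor ends at
#' \eqn{s/T = ULFS \cdot s/m \le ULFS}: end levels are proportional to
#' baseline and always enter the functional zone.
#'
#' @param baseline Baseline score level(s), positive.
#' @param factor_T Treatment factor (> 1).
#' @param ulfs Upper limit of functional status.
#' @return A tibble: `baseline`, `end_level`, `attained`.
#' @export
#' @examples
#' functional_status_check(c(80, 35), factor_T = 4, ulfs = 20)
functional_status_check <- function(baseline, factor_T, ulfs) {
  if (any(baseline <= 0) || any(factor_T <= 1) || any(ulfs <= 0)) {
    abort("Require baseline > 0, factor_T > 1 and ulfs > 0.",
          class = "tdcontrol_error_input")
  }
  end_level <- baseline / factor_T
  tibble::tibble(baseline = baseline, end_level = end_level,
                 attained = end_level <= ulfs)
}
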