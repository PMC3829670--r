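#' Regression-to-the-mean diagnostics
#'
#' Selecting items by a baseline threshold invites the objection that large
#' scores fall back by chance alone. For raw differences the objection is
#' real: the regression of \eqn{S_2 - S_1} on \eqn{S_1} has a strong negative
#' slope. Under multiplicative change, however, \eqn{\bar S_2 / S_1} is a
#' constant, so Contrast values (and hence TDC) are independent of baseline.
#' This diagnostic fits, by ordinary least squares, (i) raw VAS difference
#' (last measurement minus baseline) against baseline VAS, (ii) the VAS
#' Contrast against baseline VAS, and (iii) the last-measurement TDC against
#' baseline VAS, and reports slopes and Pearson correlations. On a cohort
#' with multiplicative change (i) shows a clear negative slope while (ii)
#' and (iii) have correlations near zero.
#'
#' @param cohort A [generate_cohort()] result (supplies the raw scores).
#' @param trial A `tdc_trial` run on the same cohort (supplies LM occasions
#'   and TDC values). If omitted, a trial is run with default settings.
#' @param min_patients Minimum cohort size (default 20).
#' @return A one-row tibble: `slope_raw`, `r_raw`, `slope_contrast`,
#'   `r_contrast`, `slope_tdc`, `r_tdc`, `n`.
#' @export
regression_diagnostics <- function(cohort, trial = NULL, min_patients = 20) {
  if (!inherits(cohort, "tdc_cohort")) {
    abort("`cohort` must be a tdc_cohort.", class = "tdcontrol_error_input")
  }
  if (is.null(trial)) trial <- run_trial(cohort$scores)
  o <- trial$outcomes
  vas <- cohort$scores[cohort$scores$item_id == "vas_pain", , drop = FALSE]
  base <- vas[vas$occasion_order == 0, c("patient_id", "value")]
  names(base)[2] <- "s1"

  lm_occ <- o[, c("patient_id", "lm_occasion", "lm_tdc")]
  lm_vas <- dplyr::inner_join(
    vas[, c("patient_id", "occasion_label", "value")],
    lm_occ, by = c("patient_id", "occasion_label" = "lm_occasion"))
  names(lm_vas)[names(lm_vas) == "value"] <- "s2"

  df <- dplyr::inner_join(base, lm_vas, by = "patient_id")
  df <- df[!is.na(df$s2) & !is.na(df$s1), , drop = FALSE]
  if (nrow(df) < min_patients) {
    abort(sprintf("Need at least %d patients with baseline and last-measurement scores.",
                  min_patients),
          class = "tdcontrol_error_input")
  }
  if (sd(df$s1) == 0) {
    abort("Baseline scores are degenerate (zero variance).",
          class = "tdcontrol_error_input")
  }

  raw_diff <- df$s2 - df$s1
  ctr <- contrast(df$s1, df$s2)
  fit_raw <- lm(raw_diff ~ df$s1)
  fit_ctr <- lm(ctr ~ df$s1)
  fit_tdc <- lm(df$lm_tdc ~ df$s1)

  tibble::tibble(
    slope_raw = unname(coef(fit_raw)[2]),
    r_raw = cor(df$s1, raw_diff),
    slope_contrast = unname(coef(fit_ctr)[2]),
    r_contrast = cor(df$s1, ctr),
    slope_tdc = unname(coef(fit_tdc)[2]),
    r_tdc = cor(df$s1, df$lm_tdc),
    n = nrow(df)
  )
}
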