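#' Run the TDC procedure on a cohort of visit scores
#'
#' The end-to-end pipeline: per patient, assemble the reference timeline and
#' per-occasion TDCs under the chosen addition mode and initial-Contrast
#' policy, run the visit-by-visit decision engine to find the stopping point,
#' then classify the short-term (EM) and ultimate (LM) outcomes. Under the
#' continued-addition mode (`"c-A"`) the timeline is re-assembled after the
#' stopping point is known, so that clinician additions can only come from
#' visits the patient actually attended.
#'
#' @param scores Long-format visit-score table (see [read_visit_scores()]).
#' @param cfg A [cutoff_config()].
#' @param mode,policy See [assemble_reference_timeline()].
#' @param thresholds An [sdd_thresholds()] object.
#' @return An object of class `tdc_trial`: a list with `outcomes` (one row
#'   per patient, see [decide_patient()]), `tdc` (per-patient per-occasion
#'   TDC values actually used), and the configuration. Methods: [tidy()],
#'   [glance()], [autoplot()], `print()`.
#' @export
#' @examples
#' coh <- generate_cohort(simulation_config(n_patients = 6, seed = 7))
#' trial <- run_trial(coh$scores)
#' glance(trial)
run_trial <- function(scores, cfg = cutoff_config(),
                      mode = c("s-A", "c-A", "NA"),
                      policy = c("zero", "baseline_relative"),
                      thresholds = sdd_thresholds()) {
  mode <- match.arg(mode)
  policy <- match.arg(policy)
  check_score_frame(scores)

  run_one <- function(p) {
    tl <- assemble_reference_timeline(p, mode = mode, policy = policy,
                                      thresholds = thresholds)
    out <- decide_patient(tl$tdc, cfg)
    if (mode == "c-A") {
      # drop treatment visits after the stopping point: additions the
      # clinician never saw must not leak into the post-treatment ledger
      tx_orders <- sort(unique(p$occasion_order[p$rater == "clinician"]))
      if (out$n_visits < length(tx_orders)) {
        drop <- tx_orders[seq.int(out$n_visits + 1L, length(tx_orders))]
        tl <- assemble_reference_timeline(
          p[!(p$occasion_order %in% drop), , drop = FALSE],
          mode = mode, policy = policy, thresholds = thresholds)
        out <- decide_patient(tl$tdc, cfg)
      }
    }
    list(out = out, tdc = tl$tdc)
  }

  res <- scores |>
    dplyr::group_split(.data$patient_id) |>
    purrr::map(run_one)

  structure(
    list(outcomes = dplyr::bind_rows(purrr::map(res, "out")),
         tdc = dplyr::bind_rows(purrr::map(res, "tdc")),
         cutoffs = cfg, mode = mode, policy = policy,
         thresholds = thresholds),
    class = "tdc_trial"
  )
}

#' @export
print.tdc_trial <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<tdc_trial> %d patients (mode %s, policy %s)\n",
              g$n, x$mode, x$policy))
  cat(sprintf("  success: PEM %.1f%%  EM %.1f%%  LM %.1f%%;  mean duration %.1f weeks (%.1f visits)\n",
              g$success_pct_pem, g$success_pct_em, g$success_pct_lm,
              g$mean_duration_weeks, g$mean_visits))
  invisible(x)
}

#' @rdname run_trial
#' @param x A `tdc_trial`.
#' @param ... Unused.
#' @export
tidy.tdc_trial <- function(x, ...) {
  x$outcomes
}

#' @rdname run_trial
#' @export
glance.tdc_trial <- function(x, ...) {
  o <- x$outcomes
  pem <- success_rate(o, "PEM")
  em <- success_rate(o, "EM")
  lm <- success_rate(o, "LM")
  tibble::tibble(
    n = nrow(o),
    success_pct_pem = pem$success_pct,
    success_pct_em = em$success_pct,
    success_pct_lm = lm$success_pct,
    n_discrepancy_em = em$n_discrepancy,
    n_discrepancy_lm = lm$n_discrepancy,
    mean_duration_weeks = mean(o$duration_weeks, na.rm = TRUE),
    mean_visits = mean(o$n_visits, na.rm = TRUE),
    mean_tdc_em = mean(o$em_tdc, na.rm = TRUE),
    mean_tdc_lm = mean(o$lm_tdc, na.rm = TRUE)
  )
}

#' Plot post-treatment TDC distributions of a trial
#'
#' Histograms of per-patient TDC at the end measurement and last
#' measurement, with the success cut-off marked. A clear responder /
#' non-responder mixture shows up as a bimodal LM distribution whose trough
#' lies near the cut-off.
#'
#' @param object A `tdc_trial`.
#' @param binwidth Histogram bin width in TDC units.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tdc_trial <- function(object, binwidth = 0.1, ...) {
  o <- object$outcomes
  df <- dplyr::bind_rows(
    tibble::tibble(occasion = "EM", tdc = o$em_tdc),
    tibble::tibble(occasion = "LM", tdc = o$lm_tdc)
  )
  df <- df[!is.na(df$tdc), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tdc)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey65", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$cutoffs$success_cutoff,
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~occasion, ncol = 1) +
    ggplot2::labs(x = "TDC", y = "patients",
                  title = "Post-treatment TDC distributions",
                  subtitle = sprintf("dashed line: success cut-off %.3f",
                                     object$cutoffs$success_cutoff)) +
    ggplot2::theme_minimal()
}

#' Plot one patient's TDC trajectory
#'
#' @param trial A `tdc_trial`.
#' @param patient_id Patient to plot.
#' @return A ggplot object with the overall, anamnestic and clinical TDC
#'   trajectories and both decision cut-offs.
#' @export
plot_patient_trajectory <- function(trial, patient_id) {
  df <- trial$tdc[trial$tdc$patient_id == patient_id, , drop = FALSE]
  if (nrow(df) == 0L) {
    abort(sprintf("Patient %s not found in this trial.", patient_id),
          class = "tdcontrol_error_input")
  }
  long <- tidyr::pivot_longer(
    df, c("tdc", "tdc_anamnestic", "tdc_clinical"),
    names_to = "series", values_to = "value")
  long$series <- c(tdc = "overall", tdc_anamnestic = "anamnestic",
                   tdc_clinical = "clinical")[long$series]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$weeks_elapsed, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_hline(yintercept = trial$cutoffs$success_cutoff,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = trial$cutoffs$responsiveness_cutoff,
                        linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "weeks", y = "TDC", colour = NULL,
                  title = sprintf("TDC trajectory, patient %s", patient_id)) +
    ggplot2::theme_minimal()
}
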