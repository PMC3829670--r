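#' Configuration of the synthetic-cohort generator
#'
#' The generator emulates a chronic-pain cohort scored on 6 anamnestic items
#' (one 0-100 mm pain VAS plus five 0-4 adjectival items) and 42 clinical 0-4
#' items, as in a myogenous temporomandibular-disorder trial. Latent item
#' severity changes multiplicatively per visit interval — the relative-change
#' model that the TDC index assumes — with per-item log-normal jitter;
#' observed scores add measurement noise calibrated to the printed
#' smallest-detectable differences and are clipped and discretised to the
#' scale (0-4 items: additive noise; VAS: proportional error). A fraction of patients are true responders; the rest keep their
#' latent level. Items with low baselines can flare to high levels for one
#' or more visits, exercising the added-reference pathways.
#'
#' Measurement noise on the 0-4 scales uses
#' \eqn{\sigma = SDD / (1.96\sqrt{2})}: the short-term SDD of 1.9 units gives
#' \eqn{\sigma \approx 0.686}. The printed 49 mm VAS SDD is a long-term value
#' dominated by biological fluctuation, not instrument error, so the VAS uses
#' a proportional short-term measurement error instead.
#'
#' @param n_patients Cohort size (default 118).
#' @param n_anamnestic Number of anamnestic items including the VAS (6).
#' @param n_clinical Number of clinical 0-4 items (42).
#' @param responder_fraction Probability that a patient truly responds
#'   (default 0.7, in line with reported short-term success of conventional
#'   TMD therapy).
#' @param improvement_factor Multiplicative latent change per visit interval
#'   for responders (< 1; default 0.70).
#' @param non_responder_factor Same for non-responders (default 1.0).
#' @param floor_fraction Residual latent level of responders as a fraction of
#'   baseline (default 0.05): improvement plateaus there.
#' @param traj_jitter SD of the per-item log-normal jitter applied to the
#'   latent trajectory at each occasion (default 0.2).
#' @param noise_sd_points SD of additive measurement noise on 0-4 items
#'   (default 1.9 / (1.96 * sqrt(2))).
#' @param noise_rel_vas Relative (log-normal) measurement error of the VAS
#'   (default 0.15): marking a 100 mm line has roughly proportional,
#'   Weber-like error, so residual pain of a few mm is not swamped by a
#'   fixed error floor.
#' @param flare_probability Per-item per-occasion chance that a low-baseline
#'   item flares to a high level (default 0.003, giving additions in roughly
#'   the fraction of patients reported for this kind of cohort).
#' @param flare_persistence Probability that a flare persists into the next
#'   occasion (geometric continuation; default 0.5).
#' @param relapse_probability Chance that a responder relapses during
#'   follow-up (default 0.15).
#' @param relapse_level Latent level of a relapsed responder as a fraction of
#'   baseline (default 0.8).
#' @param severity_range Range of the per-patient mean latent severity on the
#'   0-4 scale from which item baselines are drawn.
#' @param item_spread SD of the per-item log-normal spread around the patient
#'   severity.
#' @param vas_range Range (mm) of the latent baseline VAS.
#' @param visit_interval_weeks Weeks between treatment visits (default 4).
#' @param em_delay_weeks Weeks between end of treatment and the assessor's
#'   end measurement (default 5).
#' @param max_weeks Maximal treatment duration used to lay out the visit
#'   calendar (default 30; the decision engine enforces its own limits).
#' @param seed Master seed; each patient derives an independent substream
#'   from it, so cohorts are reproducible patient by patient.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 118,
                              n_anamnestic = 6,
                              n_clinical = 42,
                              responder_fraction = 0.7,
                              improvement_factor = 0.70,
                              non_responder_factor = 1.0,
                              floor_fraction = 0.05,
                              traj_jitter = 0.2,
                              noise_sd_points = 1.9 / (1.96 * sqrt(2)),
                              noise_rel_vas = 0.15,
                              flare_probability = 0.003,
                              flare_persistence = 0.5,
                              relapse_probability = 0.15,
                              relapse_level = 0.8,
                              severity_range = c(0.30, 1.55),
                              item_spread = 0.60,
                              vas_range = c(15, 90),
                              visit_interval_weeks = 4,
                              em_delay_weeks = 5,
                              max_weeks = 30,
                              seed = 1L) {
  probs <- c(responder_fraction, flare_probability, flare_persistence,
             relapse_probability)
  if (any(probs < 0) || any(probs > 1)) {
    abort("Probabilities must lie in [0, 1].", class = "tdcontrol_error_input")
  }
  if (improvement_factor <= 0 || non_responder_factor <= 0) {
    abort("Trajectory factors must be positive.", class = "tdcontrol_error_input")
  }
  if (n_patients < 1 || n_anamnestic < 2 || n_clinical < 1) {
    abort("Invalid cohort dimensions.", class = "tdcontrol_error_input")
  }
  if (abs(seed) >= 2^31 - 1) {
    abort("`seed` must be a 32-bit integer.", class = "tdcontrol_error_input")
  }
  structure(as.list(environment()), class = "simulation_config")
}

patient_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1009 + i * 7919) %% 2147483629)
}

clip01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic cohort of visit scores
#'
#' Draws latent baselines and trajectories per patient under a
#' [simulation_config()] and emits a long-format visit-score table (the
#' [read_visit_scores()] contract) together with a ground-truth sidecar.
#' The visit calendar is: baseline (assessor, week 0), treatment visits every
#' `visit_interval_weeks` up to `max_weeks` (clinician), then the assessor's
#' end measurement and 6- and 12-month follow-ups. The decision engine
#' consumes visits only up to each patient's stopping point.
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `tdc_cohort`: `scores` (long tibble), `truth`
#'   (per-patient responder/relapse status and latent parameters), `config`.
#' @export
#' @examples
#' coh <- generate_cohort(simulation_config(n_patients = 4, seed = 42))
#' dplyr::count(coh$scores, occasion_label)
generate_cohort <- function(cfg = simulation_config()) {
  if (!inherits(cfg, "simulation_config")) {
    abort("`cfg` must be a simulation_config().", class = "tdcontrol_error_input")
  }
  # enough visits that the maximal-duration rule can always fire
  n_tx <- ceiling(cfg$max_weeks / cfg$visit_interval_weeks)
  tx_weeks <- seq_len(n_tx) * cfg$visit_interval_weeks
  em_week <- max(tx_weeks) + cfg$em_delay_weeks
  occ <- tibble::tibble(
    occasion_label = c("baseline", paste0("T", seq_len(n_tx)), "EM", "FU6", "FU12"),
    occasion_order = 0:(n_tx + 3L),
    weeks_elapsed = c(0, tx_weeks, em_week, em_week + 26, em_week + 52),
    rater = c("assessor", rep("clinician", n_tx), rep("assessor", 3))
  )
  n_points <- cfg$n_anamnestic - 1L + cfg$n_clinical
  items <- tibble::tibble(
    item_id = c("vas_pain",
                sprintf("A%02d", seq_len(cfg$n_anamnestic - 1L)),
                sprintf("C%02d", seq_len(cfg$n_clinical))),
    item_class = c(rep("anamnestic", cfg$n_anamnestic),
                   rep("clinical", cfg$n_clinical)),
    scale = c("vas_0_100", rep("points_0_4", n_points))
  )
  n_occ <- nrow(occ)

  patients <- vector("list", cfg$n_patients)
  truth <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    set.seed(patient_seed(cfg$seed, i))
    pid <- sprintf("P%03d", i)
    responder <- rbinom(1, 1, cfg$responder_fraction) == 1
    relapse <- responder && rbinom(1, 1, cfg$relapse_probability) == 1
    mu <- runif(1, cfg$severity_range[1], cfg$severity_range[2])
    vas0 <- runif(1, cfg$vas_range[1], cfg$vas_range[2])
    base_pts <- clip01(mu * rlnorm(n_points, 0, cfg$item_spread), 0, 4)
    base_lat <- c(vas0, base_pts)  # row 1 = VAS

    f <- if (responder) cfg$improvement_factor else cfg$non_responder_factor
    # multiplicative change per interval, floored at the residual level
    prog <- pmax(f ^ (occ$weeks_elapsed / cfg$visit_interval_weeks),
                 cfg$floor_fraction)
    if (!responder) prog <- pmin(prog, 1)  # non-responders hover at baseline
    if (relapse) {
      fu <- occ$occasion_label %in% c("FU6", "FU12")
      prog[fu] <- cfg$relapse_level
    }

    lat <- outer(base_lat, prog) *
      matrix(rlnorm(length(base_lat) * n_occ, 0, cfg$traj_jitter),
             nrow = length(base_lat))
    lat[, 1] <- base_lat  # baseline observed without trajectory jitter

    # flares: low-baseline 0-4 items may shoot to a high level transiently
    obs_base_pts <- round(clip01(base_pts + rnorm(n_points, 0, cfg$noise_sd_points), 0, 4))
    flare_eligible <- which(obs_base_pts <= 1) + 1L  # latent row indices
    n_flares <- 0L
    if (cfg$flare_probability > 0 && length(flare_eligible)) {
      for (r in flare_eligible) {
        hit <- which(rbinom(n_occ - 1L, 1, cfg$flare_probability) == 1) + 1L
        if (length(hit)) {
          start <- hit[1]
          dur <- 1L + stats::rgeom(1, 1 - cfg$flare_persistence)
          span <- start:min(start + dur - 1L, n_occ)
          lat[r, span] <- pmax(lat[r, span], runif(1, 3, 4))
          n_flares <- n_flares + 1L
        }
      }
    }

    obs <- lat
    obs[1, ] <- clip01(lat[1, ] * rlnorm(n_occ, 0, cfg$noise_rel_vas), 0, 100)
    obs[-1, ] <- round(clip01(lat[-1, , drop = FALSE] +
                                matrix(rnorm(n_points * n_occ, 0, cfg$noise_sd_points),
                                       nrow = n_points), 0, 4))
    obs[-1, 1] <- obs_base_pts  # keep the baseline draw used for flare eligibility

    patients[[i]] <- tibble::tibble(
      patient_id = pid,
      occasion_label = rep(occ$occasion_label, each = nrow(items)),
      occasion_order = rep(occ$occasion_order, each = nrow(items)),
      weeks_elapsed = rep(occ$weeks_elapsed, each = nrow(items)),
      rater = rep(occ$rater, each = nrow(items)),
      item_id = rep(items$item_id, n_occ),
      item_class = rep(items$item_class, n_occ),
      scale = rep(items$scale, n_occ),
      value = as.vector(obs)
    )
    truth[[i]] <- tibble::tibble(
      patient_id = pid, responder = responder, relapse = relapse,
      severity = mu, vas_baseline_latent = vas0, n_flares = n_flares
    )
  }

  structure(
    list(scores = dplyr::bind_rows(patients),
         truth = dplyr::bind_rows(truth),
         config = cfg),
    class = "tdc_cohort"
  )
}

#' @export
print.tdc_cohort <- function(x, ...) {
  cat(sprintf("<tdc_cohort> %d patients, %d score rows (seed %s)\n",
              nrow(x$truth), nrow(x$scores), format(x$config$seed)))
  invisible(x)
}

#' Simulate a full trial with adaptive treatment duration
#'
#' Runs the whole TDC procedure on a synthetic cohort: reference selection
#' and per-occasion TDC under the chosen addition mode and initial-Contrast
#' policy, the visit-by-visit decision engine, post-treatment classification
#' and follow-up. Ground truth from the cohort is attached to the outcome
#' records, so recovery of the responder fraction can be checked.
#'
#' @param cohort A [generate_cohort()] result.
#' @param cfg A [cutoff_config()].
#' @param mode,policy Passed to [compute_tdc()].
#' @return A `tdc_trial` object (see [run_trial()]) whose `outcomes` carry
#'   the truth columns.
#' @export
simulate_trial <- function(cohort, cfg = cutoff_config(),
                           mode = c("s-A", "c-A", "NA"),
                           policy = c("zero", "baseline_relative")) {
  if (!inherits(cohort, "tdc_cohort")) {
    abort("`cohort` must be a tdc_cohort from generate_cohort().",
          class = "tdcontrol_error_input")
  }
  trial <- run_trial(cohort$scores, cfg = cfg, mode = mode, policy = policy)
  trial$outcomes <- dplyr::left_join(trial$outcomes, cohort$truth,
                                     by = "patient_id")
  trial$truth <- cohort$truth
  trial
}
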