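cfg <- cutoff_config()

test_that("cutoff_config validates its invariants", {
  expect_error(cutoff_config(responsiveness_cutoff = -0.4, success_cutoff = -0.2),
               class = "tdcontrol_error_input")
  expect_error(cutoff_config(min_weeks = 10, max_weeks = 6),
               class = "tdcontrol_error_input")
  expect_equal(cfg$responsiveness_cutoff, -0.212)
  expect_equal(cfg$success_cutoff, -0.379)
})

test_that("the discrepancy rule fires only when the patient disagrees with success", {
  expect_false(discrepancy_rule(-0.674, -0.685, cfg))  # worked patient
  expect_true(discrepancy_rule(-0.40, -0.10, cfg))
  expect_false(discrepancy_rule(-0.30, -0.10, cfg))    # overall not successful
  expect_false(discrepancy_rule(-0.40, -0.212, cfg))   # anamnestic at the boundary responds
  expect_warning(res <- discrepancy_rule(-0.50, NA_real_, cfg))
  expect_false(res)
})

test_that("the discrepancy rule can only flip successful to unsuccessful", {
  set.seed(42)
  for (i in 1:200) {
    ov <- runif(1, -1, 0.2)
    an <- runif(1, -1, 0.2)
    plain <- ov <= cfg$success_cutoff
    ruled <- classify_post_treatment(ov, an, cfg)
    if (!plain) {
      expect_equal(ruled$classification, "unsuccessful")
      expect_false(ruled$discrepancy)
    }
    if (ruled$classification == "successful") expect_true(plain)
  }
})

hist_row <- function(tdc, weeks, anam = tdc) {
  tibble::tibble(tdc = tdc, tdc_anamnestic = anam, weeks_elapsed = weeks)
}

test_that("treatment-visit evaluation follows the staged rules", {
  # unresponsive once the therapy-specific minimum duration has elapsed
  expect_equal(evaluate_treatment_visit(hist_row(-0.15, 8), cfg),
               "end_unresponsive")
  # before the minimum duration the same TDC just continues
  expect_equal(evaluate_treatment_visit(hist_row(-0.15, 4), cfg), "continue")
  # a tie at the responsiveness cut-off still counts as responsive
  expect_equal(evaluate_treatment_visit(hist_row(-0.212, 8), cfg), "continue")
  # two successive successes within the confirmation interval
  h <- dplyr::bind_rows(hist_row(-0.40, 10), hist_row(-0.45, 14))
  expect_equal(evaluate_treatment_visit(h, cfg), "end_potentially_successful")
  # a single success is not enough
  expect_equal(evaluate_treatment_visit(hist_row(-0.40, 10), cfg), "continue")
  # between cut-offs below the limits: continue
  expect_equal(evaluate_treatment_visit(hist_row(-0.30, 4), cfg), "continue")
  # spacing outside the confirmation interval blocks the success ending
  h_wide <- dplyr::bind_rows(hist_row(-0.40, 4), hist_row(-0.45, 12))
  expect_equal(evaluate_treatment_visit(h_wide, cfg), "continue")
  # discrepancy at the later visit blocks the success ending
  h_disc <- dplyr::bind_rows(hist_row(-0.40, 10), hist_row(-0.45, 14, anam = -0.1))
  expect_equal(evaluate_treatment_visit(h_disc, cfg), "continue")
  # duration cap
  h_cap <- dplyr::bind_rows(hist_row(-0.30, 26), hist_row(-0.30, 30))
  expect_equal(evaluate_treatment_visit(h_cap, cfg), "end_max_duration")
  expect_error(evaluate_treatment_visit(hist_row(c(-0.3, -0.4), c(8, 4)), cfg),
               class = "tdcontrol_error_input")
})

test_that("post-treatment classification has an inclusive success boundary", {
  expect_equal(classify_post_treatment(-0.674, -0.685, cfg)$classification,
               "successful")
  expect_equal(classify_post_treatment(-0.379, -0.50, cfg)$classification,
               "successful")
  expect_equal(classify_post_treatment(-0.378, -0.50, cfg)$classification,
               "unsuccessful")
})

test_that("follow-up stops at the first unsuccessful occasion", {
  em_bad <- list(classification = "unsuccessful", discrepancy = FALSE,
                 occasion_label = "EM", tdc_value = -0.2)
  lm <- run_followup(em_bad, NULL, cfg)
  expect_equal(lm$lm_occasion, "EM")
  expect_equal(lm$lm_class, "unsuccessful")

  em_ok <- list(classification = "successful", discrepancy = FALSE,
                occasion_label = "EM", tdc_value = -0.6)
  fus <- tibble::tibble(occasion_label = c("FU6", "FU12"),
                        tdc = c(-0.55, -0.70),
                        tdc_anamnestic = c(-0.55, -0.70))
  lm <- run_followup(em_ok, fus, cfg)
  expect_equal(lm$lm_occasion, "FU12")
  expect_equal(lm$lm_class, "successful")

  fus$tdc[1] <- -0.20  # relapse at 6 months terminates follow-up
  lm <- run_followup(em_ok, fus, cfg)
  expect_equal(lm$lm_occasion, "FU6")
  expect_equal(lm$lm_class, "unsuccessful")

  # successful at EM but no follow-up data: flagged incomplete
  lm <- run_followup(em_ok, NULL, cfg)
  expect_false(lm$followup_complete)
  expect_true(is.na(lm$lm_class))
})

test_that("success_rate reports fractions, counts and discrepancy uses", {
  df <- tibble::tibble(
    em_class = rep(c("successful", "unsuccessful"), c(89, 29)),
    em_discrepancy = rep(c(FALSE, TRUE, FALSE), c(89, 4, 25)),
    lm_class = rep(c("successful", "unsuccessful", NA), c(60, 56, 2)),
    lm_discrepancy = FALSE)
  em <- success_rate(df, "EM")
  expect_equal(round(em$success_pct, 1), 75.4)  # 89 of 118
  expect_equal(em$n_discrepancy, 4)
  lm <- success_rate(df, "LM")
  expect_equal(lm$n, 116)  # incomplete follow-ups excluded
  zero <- success_rate(tibble::tibble(em_class = rep("unsuccessful", 5),
                                      em_discrepancy = FALSE), "EM")
  expect_equal(zero$success_pct, 0)
})

test_that("a more negative success cut-off never yields more successes", {
  set.seed(9)
  coh <- generate_cohort(simulation_config(n_patients = 30, seed = 303))
  cuts <- c(-0.30, -0.379, -0.45, -0.55)
  succ <- vapply(cuts, function(sc) {
    tr <- run_trial(coh$scores, cfg = cutoff_config(success_cutoff = sc))
    success_rate(tr$outcomes, "EM")$n_successful
  }, integer(1))
  expect_true(all(diff(succ) <= 0))
})

test_that("terminal records respect the therapy duration limits", {
  coh <- generate_cohort(simulation_config(n_patients = 40, seed = 77))
  tr <- run_trial(coh$scores)
  o <- tr$outcomes
  expect_true(all(o$duration_weeks <= 32))  # last scheduled visit covers max_weeks
  expect_true(all(o$n_visits <= cutoff_config()$max_visits))
  expect_true(all(o$terminal_action %in%
                    c("end_unresponsive", "end_potentially_successful",
                      "end_max_duration")))
})
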