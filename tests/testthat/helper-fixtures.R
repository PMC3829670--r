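# Shared fixtures, built in code.

# The worked patient example: 10 reference items, reference scores and the
# scores at the end measurement.
worked_patient_pairs <- function() {
  tibble::tibble(
    item_id = c("vas_pain", "A01", "A02", "A03",
                "C01", "C02", "C03", "C04", "C05", "C06"),
    item_class = rep(c("anamnestic", "clinical"), c(4, 6)),
    s1 = c(20, 3, 3, 3, 2, 2, 2, 2, 2, 2),
    s2 = c(3, 1, 1, 0, 0, 0, 1, 1, 0, 1)
  )
}

worked_patient_scores <- function() {
  read_visit_scores(system.file("extdata", "worked_example_scores.csv",
                                package = "tdcontrol"))
}

# Minimal long-format patient: baseline + treatment visits + EM/FU occasions,
# with item values supplied per occasion as named lists item_id -> value.
make_patient <- function(patient_id, items, occasions) {
  rows <- lapply(seq_along(occasions), function(k) {
    occ <- occasions[[k]]
    vals <- unlist(occ$values)[items$item_id]
    tibble::tibble(
      patient_id = patient_id,
      occasion_label = occ$label,
      occasion_order = k - 1L,
      weeks_elapsed = occ$weeks,
      rater = occ$rater,
      item_id = items$item_id,
      item_class = items$item_class,
      scale = items$scale,
      value = unname(vals)
    )
  })
  dplyr::bind_rows(rows)
}

simple_items <- function() {
  tibble::tibble(
    item_id = c("vas_pain", "A01", "A02", "C01", "C02", "C03"),
    item_class = c("anamnestic", "anamnestic", "anamnestic",
                   "clinical", "clinical", "clinical"),
    scale = c("vas_0_100", rep("points_0_4", 5))
  )
}

occ_spec <- function(label, weeks, rater, values) {
  list(label = label, weeks = weeks, rater = rater, values = values)
}
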