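test_that("basic reference selection applies the SDD rule literally", {
  p <- worked_patient_scores()
  base <- p[p$occasion_order == 0, ]
  refs <- select_basic_references(base)
  expect_equal(nrow(refs), 10)  # the worked patient has 10 reference items
  expect_setequal(refs$item_id,
                  c("vas_pain", "A01", "A02", "A03", paste0("C0", 1:6)))
  expect_true(all(refs$reference_score == refs$baseline_score))

  # all 0-4 baselines at 0/1 and VAS at 0: nothing to monitor
  low <- base
  low$value <- ifelse(low$scale == "vas_0_100", 0, pmin(low$value, 1))
  expect_equal(nrow(select_basic_references(low)), 0)

  # 47 items all scoring exactly 2 all qualify
  many <- tibble::tibble(
    item_id = sprintf("I%02d", 1:47), item_class = "clinical",
    scale = "points_0_4", value = 2)
  expect_equal(nrow(select_basic_references(many)), 47)

  expect_error(select_basic_references(rbind(base, base[1, ])),
               class = "tdcontrol_error_input")
})

test_that("added-reference detection requires a 0/1 to 3/4 transition", {
  base <- tibble::tibble(
    item_id = c("C01", "C02", "C03", "C04"), item_class = "clinical",
    scale = "points_0_4", value = c(1, 0, 2, 1))
  refs <- select_basic_references(base)  # C03 only
  visit <- base
  visit$value <- c(3, 4, 4, 2)
  adds <- detect_added_references(refs, visit, base, occasion_order = 2L)
  # C01 (1->3) and C02 (0->4) qualify; C03 is already basic; C04 reaches only 2
  expect_setequal(adds$item_id, c("C01", "C02"))
  expect_equal(adds$reference_score[adds$item_id == "C01"], 3)
  expect_equal(initial_contrast(adds[adds$item_id == "C01", ],
                                policy = "baseline_relative"), 0.5)
  expect_equal(initial_contrast(adds[adds$item_id == "C02", ],
                                policy = "baseline_relative"), 1)
  expect_equal(initial_contrast(adds, policy = "zero"), c(0, 0))
})

# one patient whose item C03 flares from 0 to 4 at treatment visit T2 and
# persists through EM and follow-up
flaring_patient <- function() {
  items <- simple_items()
  v0 <- list(vas_pain = 40, A01 = 3, A02 = 2, C01 = 2, C02 = 2, C03 = 0)
  v1 <- list(vas_pain = 30, A01 = 2, A02 = 2, C01 = 1, C02 = 1, C03 = 0)
  v2 <- list(vas_pain = 20, A01 = 1, A02 = 1, C01 = 1, C02 = 1, C03 = 4)
  em <- list(vas_pain = 10, A01 = 1, A02 = 1, C01 = 0, C02 = 0, C03 = 4)
  fu <- list(vas_pain = 5, A01 = 0, A02 = 1, C01 = 0, C02 = 0, C03 = 0)
  make_patient("F01", items, list(
    occ_spec("baseline", 0, "assessor", v0),
    occ_spec("T1", 4, "clinician", v1),
    occ_spec("T2", 8, "clinician", v2),
    occ_spec("EM", 13, "assessor", em),
    occ_spec("FU6", 39, "assessor", fu)
  ))
}

test_that("addition modes govern which ledger the post-treatment TDC uses", {
  p <- flaring_patient()

  na_tl <- assemble_reference_timeline(p, mode = "NA")
  expect_true(all(na_tl$references$kind == "basic"))
  expect_equal(unique(table(na_tl$contrasts$occasion_label)), 5L)

  sa_tl <- assemble_reference_timeline(p, mode = "s-A")
  # clinician sees the flare at T2 ...
  t2 <- sa_tl$contrasts[sa_tl$contrasts$occasion_label == "T2", ]
  expect_true("C03" %in% t2$item_id)
  # ... and the assessor re-adds it at EM relative to baseline
  em <- sa_tl$contrasts[sa_tl$contrasts$occasion_label == "EM", ]
  expect_true("C03" %in% em$item_id)
  em_ref <- sa_tl$references[sa_tl$references$item_id == "C03" &
                               sa_tl$references$added_by == "assessor", ]
  expect_equal(nrow(em_ref), 1)
  expect_equal(em_ref$reference_score, 4)

  ca_tl <- assemble_reference_timeline(p, mode = "c-A")
  # continued mode: the treatment-period reference score carries through,
  # so the EM Contrast of C03 is (4-4)/(4+4) = 0, not a fresh addition
  em_ca <- ca_tl$contrasts[ca_tl$contrasts$occasion_label == "EM" &
                             ca_tl$contrasts$item_id == "C03", ]
  expect_equal(em_ca$contrast, 0)
  expect_false(any(ca_tl$references$item_id == "C03" &
                     ca_tl$references$added_by == "assessor"))
})

test_that("initial-Contrast policies differ exactly at the visit of addition", {
  p <- flaring_patient()
  zero <- assemble_reference_timeline(p, mode = "s-A", policy = "zero")
  rel <- assemble_reference_timeline(p, mode = "s-A", policy = "baseline_relative")
  c03_t2_zero <- zero$contrasts$contrast[zero$contrasts$occasion_label == "T2" &
                                           zero$contrasts$item_id == "C03"]
  c03_t2_rel <- rel$contrasts$contrast[rel$contrasts$occasion_label == "T2" &
                                         rel$contrasts$item_id == "C03"]
  expect_equal(c03_t2_zero, 0)
  expect_equal(c03_t2_rel, 1)  # (4-0)/(4+0) against baseline
  # at FU6 the flare has waned to zero but keeps contributing with C = -1
  c03_fu <- zero$contrasts$contrast[zero$contrasts$occasion_label == "FU6" &
                                      zero$contrasts$item_id == "C03"]
  expect_equal(c03_fu, -1)
})

test_that("reference sets grow monotonically and NA is a subset of the others", {
  p <- flaring_patient()
  for (mode in c("s-A", "c-A", "NA")) {
    tl <- assemble_reference_timeline(p, mode = mode)
    counts <- tl$contrasts |>
      dplyr::count(occasion_order) |>
      dplyr::arrange(occasion_order)
    expect_true(all(diff(counts$n) >= 0), info = mode)
    na_items <- assemble_reference_timeline(p, mode = "NA")$references$item_id
    expect_true(all(na_items %in% tl$references$item_id), info = mode)
  }
})

test_that("without additions all modes agree, and zero policy gives TDC 0 under no change", {
  items <- simple_items()
  vals <- list(vas_pain = 40, A01 = 3, A02 = 2, C01 = 2, C02 = 2, C03 = 1)
  p <- make_patient("S01", items, list(
    occ_spec("baseline", 0, "assessor", vals),
    occ_spec("T1", 4, "clinician", vals),
    occ_spec("T2", 8, "clinician", vals),
    occ_spec("EM", 13, "assessor", vals)
  ))
  tls <- lapply(c("s-A", "c-A", "NA"), function(m)
    assemble_reference_timeline(p, mode = m)$tdc)
  expect_equal(tls[[1]], tls[[2]])
  expect_equal(tls[[1]], tls[[3]])
  expect_true(all(tls[[1]]$tdc == 0))  # no score changes anywhere
})

test_that("a patient with no pronounced signs raises a reference error", {
  items <- simple_items()
  none <- list(vas_pain = 0, A01 = 1, A02 = 0, C01 = 1, C02 = 0, C03 = 1)
  p <- make_patient("N01", items, list(
    occ_spec("baseline", 0, "assessor", none),
    occ_spec("EM", 10, "assessor", none)
  ))
  expect_error(assemble_reference_timeline(p),
               class = "tdcontrol_error_no_references")
})

test_that("compute_tdc stacks per-patient timelines", {
  p1 <- worked_patient_scores()
  p2 <- p1
  p2$patient_id <- "P002"
  out <- compute_tdc(dplyr::bind_rows(p1, p2))
  expect_equal(nrow(out), 4)
  expect_setequal(unique(out$patient_id), c("P001", "P002"))
})
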