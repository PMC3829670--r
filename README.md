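# tdcontrol

Treatment Duration Control (TDC) for routine outcome monitoring and
randomized controlled trials in which treatment duration is patient- and
therapy-specific.

Chronic-pain trials traditionally evaluate all patients after a fixed
treatment period, which penalises slow therapies and blurs comparisons with
clinical care, where treatment ends when the patient is well. TDC is a
relative-change index that lets a clinician end treatment in a standardized
way. For each monitored **reference item** — an item whose baseline score is
pronounced enough that its possible decrease exceeds the smallest detectable
difference — the **Contrast** between a later score *S₂* and its reference
score *S₁* is

    C = (S₂ − S₁) / (S₂ + S₁)  ∈ [−1, +1]

(−1: the sign fully resolved; 0: no change; +1: appeared from zero), and

    TDC = Σᵢ Cᵢ / n

is the equally weighted mean over the patient's reference items. Because a
patient with the maximal baseline *m* needs a relative decrease by the
treatment factor *T = m/ULFS* to reach the Upper Limit of Functional Status,
and end levels under a fixed factor are proportional to baseline, a single
calibrated cut-off (TDC ≤ −0.379, a 55% single-score decrease) marks
potential success for every patient; a second cut-off (TDC > −0.212 after
the therapy-specific minimum duration, a 35% decrease) ends treatment of
unresponsive patients. An anamnestic **discrepancy rule** lets the patient's
own account of daily functioning veto a success call, and reference items
can be **added** during treatment or follow-up when late signs flare
(0/1 → 3/4), under three bookkeeping modes (`s-A`, `c-A`, `NA`).

The package provides:

* `contrast()`, `tdc()`, factor conversions, reversed-scale and
  unknown-maximum transforms (`complement_contrast()`,
  `unknown_max_contrast()`), and the ratio-averaging comparison;
* adaptive reference selection and the per-occasion timeline
  (`select_basic_references()`, `detect_added_references()`,
  `assemble_reference_timeline()`, `compute_tdc()`);
* the decision engine (`cutoff_config()`, `evaluate_treatment_visit()`,
  `classify_post_treatment()`, `run_followup()`, `decide_patient()`,
  `success_rate()`);
* cut-off calibration (`cutoff_from_profile()`,
  `rank_patients_by_severity()`, `weighted_percentile_ulfs()`,
  `functional_status_check()`);
* a synthetic-cohort simulator and diagnostics (`simulation_config()`,
  `generate_cohort()`, `simulate_trial()`, `regression_diagnostics()`);
* tidy I/O, per-patient reports, `tidy()`/`glance()`/`autoplot()` methods
  for trial objects, and a thin CLI (`inst/scripts/tdc`).

## Worked example

The shipped fixture contains the worked patient: ten reference items
(VAS 20 mm and nine 0–4 items) scored at baseline and at the assessor's end
measurement.

```r
library(tdcontrol)
path <- system.file("extdata", "worked_example_scores.csv", package = "tdcontrol")
report_patient(read_visit_scores(path))
#> Patient P001: 10 reference items (10 basic, 0 added)
#>  occasion_label weeks_elapsed    rater n_items    tdc tdc_anamnestic tdc_clinical
#>        baseline             0 assessor      10  0.000          0.000        0.000
#>              EM            10 assessor      10 -0.674         -0.685       -0.666
```

The overall TDC of −0.674 is well below the success cut-off, the anamnestic
subset (−0.685) agrees, so the discrepancy rule does not fire and this
outcome is classed successful.

The success cut-off itself derives from the maximal-severity baseline
profile of a pilot sample against the panel's functional limit of 1.40
units:

```r
cutoff_from_profile(c("2" = 7, "3" = 10, "4" = 15), ulfs = 1.40)
#>   cutoff factor_recip factor_T pct_decrease summed_score n_items
#> 1 -0.378        0.451     2.22         54.9          104      32
cutoff_rounded_to_percent(-0.37793)   # the shipped decision cut-off
#> [1] -0.379
```

An end-to-end synthetic trial (118 patients, 70% true responders):

```r
coh   <- generate_cohort(simulation_config(seed = 2026))
trial <- simulate_trial(coh)
glance(trial)
#>       n success_pct_pem success_pct_em success_pct_lm n_discrepancy_em ...
#> 1   118            73.7           72.0           61.0                5
success_rate(tidy(trial), "LM")
#>   occasion     n n_successful n_unsuccessful n_discrepancy success_pct
#> 1 LM         118           72             46             7        61.0
autoplot(trial)   # bimodal long-term TDC histogram with the cut-off marked
```

Short-term success (72.0%) recovers the simulated responder fraction;
follow-up removes relapses, so long-term success is lower — follow-up can
only remove successes, never add them.

## Command line

```sh
Rscript inst/scripts/tdc calibrate --profile 2:7,3:10,4:15 --ulfs 1.40
Rscript inst/scripts/tdc simulate --seed 7 --out scores.csv
Rscript inst/scripts/tdc score --input scores.csv --out tdc.csv
Rscript inst/scripts/tdc decide --input scores.csv --out outcomes.csv
```

## Vignette

`vignettes/treatment-duration-control.Rmd` documents the model, the
selection and decision rules, the calibration arithmetic and its numerical
conventions, what the synthetic-data generator does and does not emulate,
and known limitations.
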