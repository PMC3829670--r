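---
title: "Treatment Duration Control: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Treatment Duration Control: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdcontrol)
```

## The problem

Conventional routine outcome monitoring (ROM) tracks *raw* score change
against a reliable-change threshold and a normative level. That framing has
two well-known drawbacks for chronic-pain care. First, a patient with severe
baseline symptoms must shed many raw points to reach the functional zone,
while a patient who starts just above it can "succeed" with a change barely
beyond measurement noise — even though patients judge improvement in
*relative* terms. Second, selecting items by a baseline threshold invites
regression-to-the-mean bias whenever the outcome is a raw difference.

Treatment Duration Control (TDC) replaces raw change with relative change.
For each monitored ("reference") item the **Contrast** between a later score
$S_2$ and its reference score $S_1$ is

$$C = \frac{S_2 - S_1}{S_2 + S_1} \in [-1, +1],$$

a symmetric transform of the multiplication factor $R = S_2/S_1$
($C = (R-1)/(R+1)$): an increase and a decrease by the same factor give
Contrasts of equal size and opposite sign, and $C$ stays finite when a sign
resolves completely ($S_2 = 0 \Rightarrow C = -1$), where $\log R$ does not.
TDC at an evaluation occasion is the equally weighted mean of the Contrasts
of all reference items. Equal weighting is deliberate: every item reflects
pain or pain-driven impairment, and patient expectations of relief are
roughly constant in relative terms across scoring domains.
`compare_averaging_methods()` reproduces the demonstration of why the mean
Contrast (or mean log-ratio) is the defensible average of ratios, while the
ratio-of-means is dominated by the largest baseline and the plain
mean-of-ratios lacks a symmetric zero. For $|\log_{10} R| \le 0.8$ the
Contrast tracks $\log_{10} R$ within 15% relative deviation
(`log_ratio_deviation()`), so TDC is approximately the log of the geometric
mean factor across items.

## Why a single treatment factor works for every baseline

If the most severely affected patient, with overall baseline level $m$,
needs a relative decrease by the treatment factor $T = m/\mathrm{ULFS}$ to
reach the upper limit of functional status (ULFS), then any patient with a
smaller baseline $s \le m$ treated by the same factor ends at
$s/T = \mathrm{ULFS}\cdot s/m \le \mathrm{ULFS}$: end levels are
*proportional to baseline* and always enter the functional zone
(`functional_status_check()`). This is why a single TDC cut-off, calibrated
on the maximal-severity patient, serves the whole sample.

## Reference items

Score changes below the smallest detectable difference (SDD) of a single
score are noise. Items are therefore monitored adaptively:

* **Basic reference items** — 0–4 items whose baseline is at least 2 units
  (their maximal possible decrease then exceeds the short-term SDD of
  1.9 units), plus the predominant-pain VAS. The VAS inclusion rule is
  configurable (`sdd_thresholds(vas_reference_min = )`); the default admits
  any positive baseline, since every enrolled patient presents with pain.
  No added-reference rule is defined for the VAS: it can only be basic.
* **Added reference items** — items whose score rises from 0/1 at baseline
  to 3/4 later (a potential decrease of at least 3 units, beyond the
  long-term SDD of 2.2 units). The score at the visit of addition becomes
  the item's reference score. The rule is implemented literally on the
  score levels (0/1 → 3/4) rather than on a generic SDD inequality, because
  those levels define it on this scale. An item qualifying at several
  visits is added at the earliest one only; once added, an item contributes
  a Contrast at every later occasion, even when its score wanes to zero.

Addition bookkeeping is rater-aware. During treatment the clinician detects
additions; post-treatment occasions belong to a blinded assessor. Three
modes are supported (`assemble_reference_timeline()`): **s-A** (the
standard: post-treatment TDCs treat the treatment period as a black box and
use only assessor-detected additions, referenced against baseline — immune
to clinician-bound bias and to differences in visit frequency or duration),
**c-A** (clinician additions carry their treatment-period reference scores
into follow-up), and **NA** (basic items only). In `run_trial()` the c-A
ledger is rebuilt after the stopping visit is known, so additions can only
come from visits the patient actually attended.

At the visit of addition the initial Contrast is either computed against
baseline (`policy = "baseline_relative"`, giving +0.5 to +1 and flagging
the worsening) or set to zero (`policy = "zero"`, the default), which
treats added and basic items identically — a basic item's Contrast at its
own reference visit is zero by construction — and largely removes the
inter-mode bias in post-treatment TDC values.

## Cut-offs and the decision engine

Two cut-offs drive the visit-by-visit procedure (`cutoff_config()`):

* **Responsiveness, −0.212** (a 35% single-score decrease,
  $(65-100)/(65+100)$): once the therapy-specific minimum duration has
  elapsed, a TDC above it ends treatment as unresponsive. A tie at −0.212
  counts as responsive (the printed rule is strictly "greater than").
* **Success, −0.379** (a 55% decrease): treatment ends as potentially
  successful after two successive visits at or below it, spaced within the
  3–6 week confirmation interval, provided the discrepancy rule does not
  object. The boundary is inclusive.

The success cut-off comes from calibration (`cutoff_from_profile()`): the
maximal-severity profile in a pilot sample — 7 items scoring 2, 10 scoring
3, 15 scoring 4 (summed score 104 over 32 items) — against the panel-agreed
ULFS of 1.40 units gives the mean Contrast −0.378, an overall factor
$1/T = 0.451$ ($T = 2.22$), i.e. a 54.9% single-score decrease. The shipped
cut-off −0.379 arises by rounding 54.9% to 55% and transforming back
(`cutoff_rounded_to_percent()`). Severity ranking uses summed baseline
score, then item count (`rank_patients_by_severity()`).

Two numerical conventions matter here and are worth stating explicitly:

* **Calibration runs at full precision.** Rounding the three per-score
  Contrasts to 3 decimals first happens to give the same −0.378 for the
  pilot profile, but for the profile {7×2, 9×3, 17×4} it yields −0.384
  where full precision gives −0.385; full precision is used throughout.
  For the ULFS = 1.08 recalibration both conventions agree on −0.482 (a
  value of −0.486 sometimes quoted for this configuration does not survive
  brute-force recomputation and is treated as a transcription error).
* **Reporting rounds with base `round()`** (`round_tdc()`), i.e. the
  IEEE/spreadsheet behaviour, with per-item Contrasts rounded to three
  decimals before subset means in `report_patient()` — this reproduces the
  reference tables digit for digit (e.g. a clinical-subset mean of
  −0.6665 reporting as −0.666). Internal arithmetic is never rounded.

The **discrepancy rule** gives the patient's own account priority: if the
overall TDC signals success but the anamnestic-subset TDC (daily
functioning, reported by the patient) is still above the responsiveness
cut-off, the occasion is classed unfinished/unsuccessful. The rule can only
remove successes. When a patient has no anamnestic reference item the rule
is inapplicable and returns `FALSE` with a warning; at post-treatment
occasions it is evaluated on the same reference timeline as the overall
TDC. Degenerate inputs follow the same philosophy of explicit, conservative
behaviour: `contrast(0, 0)` is 0 (no change in an absent sign — reachable
in added-item bookkeeping though never for reference scores, which are
at least 2), and a patient with no reference items at all raises an error
rather than a silent `NaN`.

Outcome classification is staged: PEM (clinician, last treatment visit),
EM (assessor, short-term outcome; an unfavourable PEM does not block an
assessor-confirmed success), then follow-up at 6 and 12 months for
EM-successful patients only — the first unsuccessful occasion terminates
follow-up and becomes the last measurement (LM). Patients successful at EM
but lacking follow-up data are flagged incomplete and excluded from LM
summaries. "Two successive visits" is checked with the discrepancy rule at
the later visit; whether it should also bind at the earlier one is not
specified anywhere, and the later-visit reading is the implemented one.

## Scale transformations

Reversed scales (larger = better, e.g. a health VAS) are handled by
complementing against the scale maximum before the Contrast
(`complement_contrast()`). When an item's unimpaired maximum is unknown
(e.g. maximal mouth opening), the lower 95% confidence limit of normal
values serves as the initial maximum; a later score exceeding it replaces
the maximum from that visit on (`unknown_max_contrast()`,
`unknown_max_timeline()` — the update uses strictly-greater comparison, as
in the worked 43 mm example).

## Estimating the ULFS in retrospect

`weighted_percentile_ulfs()` estimates the ULFS as the 95th percentile of
post-treatment scores of successfully treated patients, each observation
weighted by its item's empirical chance of being a reference item (the
package accepts any per-item probability map; reported ranges are 47–82%
for anamnestic and 6–69% for clinical items). The percentile convention is
the step function — the smallest score whose cumulative weight reaches the
target fraction — because the scores are discrete 0–4 values and no
interpolation convention is defined for this estimator; it is documented
and testable against an exhaustive sort-and-accumulate oracle, and with
uniform weights it coincides with the plain empirical percentile.

## The synthetic cohort generator

No patient-level data are deposited, so validation rests on synthetic
cohorts (`simulation_config()`, `generate_cohort()`). The generator
emulates the study conditions: 118 patients, 6 anamnestic items (one
0–100 mm VAS) and 42 clinical 0–4 items; visits every 4 weeks within
therapy limits of 3–15 visits and 6–30 weeks; an assessor end measurement
about 5 weeks after treatment and follow-ups at 6 and 12 months.

Latent item severity changes **multiplicatively** per visit interval — the
relative-change model the index assumes — with log-normal per-item jitter;
responders (fraction 0.7, in line with reported short-term success of
conventional therapy for this disorder) improve by factor 0.70 per
interval down to a residual 5% of baseline, non-responders hover at
baseline, and 15% of responders relapse during follow-up. Observed 0–4
scores add Gaussian noise with $\sigma = SDD/(1.96\sqrt2) \approx 0.686$
(from the printed short-term SDD of 1.9 units) and are rounded and clipped;
the VAS uses a proportional (log-normal, 15%) measurement error, because
the printed 49 mm VAS SDD is a long-term figure dominated by biological
fluctuation and a fixed error floor would swamp residual pain of a few
millimetres. Baseline severity spread (patient mean 0.30–1.55 scale units,
item spread 0.60) was calibrated once by Monte-Carlo so that per-patient
reference counts have mean ≈ 14–15 and range ≈ 2–35, matching the cohort
the procedure was developed on; the default flare rate (0.003 per eligible
item per occasion, persistence 0.5) yields added items in roughly the
reported fraction of patients. Low-baseline items can flare to 3–4 for one
or more occasions, exercising both the clinician-detected and
assessor-detected addition pathways. Each patient draws an independent
substream of the master seed, so cohorts are reproducible patient by
patient.

What the generator does **not** emulate: item-level correlation structure
beyond the shared patient severity, therapist or therapy effects,
missing data, and partial responders between the two latent classes.
Passing property tests therefore show that the *procedure* behaves as
designed under its own model assumptions — bimodal long-term TDC with a dip
near the cut-off, recovery of the responder fraction, elimination of
regression to the mean, LM successes never exceeding EM successes — not
that any particular clinical success rate is to be expected.

A replicate calibration sweep of the regression diagnostics (30 cohorts of
118) shows the Contrast-vs-baseline and TDC-vs-baseline correlations
centred on zero (means −0.04 and −0.01, SD ≈ 0.11) while the raw-difference
correlation averages −0.55: the envelope used in the tests (|r| < 0.15 at
the canonical seed, raw r < −0.4) sits well inside the typical behaviour.

## Problem sizes and test design

The shipped tests run cohorts of 118 (the emulated sample size) for
distributional checks and 500 for the responder-fraction recovery, with
smaller cohorts (25–40) for structural properties; these sizes give the
statistical checks comfortable margins while keeping the suite quick.
Property tests use fixed seeds; exact worked-example values are asserted to
three decimals, the precision the procedure itself reports.

## Known limitations

* TDC values of different patients average different numbers of items, so
  their variances differ; the package reports per-patient item counts, but
  any cross-patient parametric analysis of TDC values should account for
  this (stratification or rank-based tests).
* The ULFS and the success cut-off are disorder-specific; defaults here are
  for myogenous temporomandibular disorder and must be recalibrated for
  other conditions (a degenerative disorder would have a higher ULFS and a
  less negative cut-off).
* The engine implements the computational rules only; care-policy steps
  after an unsuccessful outcome (stepping up or switching therapy) are out
  of scope.
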