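---
title: "The afscreen model: assumptions, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The afscreen model: assumptions, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afscreen)
```

`afscreen` is a patient-level Markov Monte-Carlo model of screening for
atrial fibrillation (AF) with wrist-worn photoplethysmography (PPG)
devices. This vignette explains the model itself — its states, transition
structure, parameters and costing rules — and documents every place where
the design was genuinely open, what we chose, and why.

## The state-transition model

A simulated patient is characterised by a CHA₂DS₂-VASc score (held fixed
over the simulation), a sex, and an evolving status:

* `no_af` — no atrial fibrillation;
* `af_undetected` — AF present but not diagnosed;
* `af_detected_treated` — diagnosed, on anticoagulation (NOAC);
* `af_detected_untreated` — diagnosed but not treatment-eligible
  (females with score 1, per the guideline initiation rule).

Status can only move forward: AF is never cured (cardioversion and
ablation are outside the model), and an ECG-confirmed diagnosis holds for
the rest of the simulation. Death — from stroke or from other causes — is
absorbing: the dead change no state and accrue no cost.

Time advances in 1-year cycles for at most ten years. One cycle runs, in
order:

1. **AF onset.** `no_af` patients acquire AF with the score-specific
   incidence.
2. **Detection.** In the device arm, undetected AF raises a true alert with
   the device sensitivity; any alert triggers one physician visit with ECG
   diagnostics, and a true alert is confirmed with the scenario's ECG
   confirmation rate. Patients without AF raise false alerts at the
   false-positive rate; the visit is logged and the misdiagnosis cleared
   with certainty (the physician finds no arrhythmia on the ECG — the
   `misdiagnosis_clearance` parameter is accepted for completeness but the
   model has no wrong-diagnosis branch, so values below 1 still clear).
   Whatever AF is still undetected — in either arm, including missed or
   unconfirmed alerts — can be found by standard care, which counts as
   ECG-confirmed and logs one visit. An unconfirmed alert leaves the
   patient eligible for a new alert (and its visit cost) next year.
3. **End points.** Exactly one of: a stroke (fatal with the
   status-specific case fatality, nonfatal otherwise), death from other
   causes, or no event. Stroke and other-cause death are mutually
   exclusive within a cycle; a nonfatal-stroke survivor faces other-cause
   death again only in later cycles. Major bleeding is drawn independently
   of the end point for anyone alive at cycle start. A nonfatal stroke in a
   patient with undetected AF leads to diagnosis (no separate visit cost —
   the work-up is assumed inside the stroke costs) and, if eligible,
   therapy.

**Therapy timing.** Detection in cycle *t* changes risk from cycle *t*+1:
the end-point probabilities of a cycle are snapshot after AF onset but
before detection. A newly confirmed patient therefore still carries
untreated stroke risk in the confirmation year, starts paying for NOAC the
following year, and from then on has the anticoagulated stroke incidence,
case fatality and bleeding risk. This "re-entry at the treated branch"
convention avoids granting instantaneous protection within the detection
year, which a 1-year-cycle model cannot time-resolve.

## Parameters

All parameters live in `af_parameters()`; score-indexed ones are vectors
over scores 0–9 (score 0 is representable but not simulated, since
treatment initiation makes a comparison there moot).

| parameter | default | units / meaning |
|---|---|---|
| `prevalence` | 0.01 … 0.492 | baseline AF proportion by score |
| `af_incidence` | 0.17 … 6.71 | new AF per 100 person-years |
| `stroke_incidence_untreated` | 0.2 … 14.44 | strokes per 100 py, untreated AF |
| `relative_stroke_risk_af` | 2.42 | untreated AF vs no AF |
| `noac_risk_reduction` | 0.66 | fractional stroke-risk reduction on NOAC |
| `device_sensitivity` | 0.93 | P(true alert per year) |
| `device_false_positive` | 0.002 | P(false alert per year) |
| `ecg_confirmation` | 1.0 / 0.75 / 0.5 | scenario parameter |
| `standard_care_detection` | 0.3609 | P(routine detection per year) |
| `stroke_mortality_*` | 0.34 / 0.63 / 0.42 | case fatality: no AF / untreated / NOAC |
| `other_mortality_*` | 0.06 / 0.111 / 0.111 | annual non-stroke mortality |
| `bleed_prob_on_noac` | 0.02 | annual major-bleeding P on NOAC |
| `horizon_years`, `discount_rate` | 10, 0.03 | model horizon and discounting |

Two score-indexed vectors are *derived*, not set: stroke incidence without
AF is the untreated incidence divided by the relative risk
(`derive_no_af_incidence()`), and the anticoagulated incidence is the
untreated incidence times 1 − 0.66 (`derive_noac_incidence()`). The
standard-care detection probability is the device sensitivity scaled by
the published unmonitored:monitored AF detection ratio 2.6/6.7
(`derive_standard_care_detection()`), giving 0.3609/yr. All derived values
are kept unrounded internally; 4-decimal rounding is display-only.

Two probabilities the model needs are not published anywhere we could
anchor them, so they are explicit, configurable assumptions:

* **Non-stroke mortality on NOAC** (`other_mortality_treated_af`): default
  0.111, the same as untreated AF. Treating anticoagulation as changing
  stroke outcomes but not background mortality is conservative toward the
  device arm (its survivors keep dying at the AF rate).
* **Major-bleeding probability** (`bleed_prob_on_noac`): default 0.02/yr,
  applied only while on NOAC, with the off-NOAC rate defaulting to 0. The
  event is priced (€1,995) and anticoagulation is known to raise bleeding
  risk; 2%/yr is a realistic major-bleeding rate for NOAC users. At €1,995
  per event this contributes at most a few tens of euros per patient-year
  and cannot drive the comparison.

## Costs

`af_costs()` holds unit costs in euros from the statutory-health-insurance
perspective: €437.65 for the device (bought once at baseline, no
replacement within the horizon), €67.23 per ECG visit (the exact sum of
five fee-schedule items: 13.20 + 12.90 + 9.52 + 9.96 + 21.65), €1,226.40
per NOAC year (the unrounded amount), and €1,995 per major bleeding.

Post-stroke costs follow a 10-entry schedule — entry *k* is the cost in
the *k*-th year after a stroke — anchored at €15,753 (year 1), €4,480
(year 2) and €1,481 (year 10). Intermediate years are filled by geometric
(log-linear) interpolation: between anchors (*a*, *c_a*) and (*b*, *c_b*)
the year-*k* cost is *c_a* · (*c_b*/*c_a*)^((k−a)/(b−a)). We chose the
geometric form because post-acute care costs decay multiplicatively rather
than linearly, it guarantees positivity, and it reproduces any
non-increasing anchor set with a non-increasing schedule; the published
anchors do not pin down the original fit, so this is an explicit modelling
choice. A fatal stroke incurs the year-1 cost once; a new stroke in a
survivor resets the schedule clock to year 1 (no overlapping schedules).

Discounting uses the factor (1 + r)^−(t−1) with r = 0.03: the first model
year and the baseline device purchase are undiscounted. The timing
convention (beginning-of-year) is our choice; with 3% over ten years the
alternative end-of-year convention shifts totals by at most 3%.

## The synthetic cohort

`generate_cohort()` creates the simulated population: each patient starts
alive and stroke-free, with prevalent — *undetected* — AF with the
score-specific probability. Starting prevalent AF undiagnosed is what
makes screening meaningful; a variant in which some prevalent cases are
already diagnosed would only dilute both arms equally. Sex is drawn
Bernoulli(0.5) per patient (an `exact_sex_split` option gives a
deterministic half-split for variance reduction); it matters only at score
1, where females are not treatment-eligible.

The generator reproduces the statistical structure the analysis assumes —
score-specific prevalence, a 50:50 sex mix, independence across patients —
and nothing else. It has no age structure, no comorbidity covariates, no
score progression over time, and no correlation between AF risk and
non-stroke mortality beyond what the score-indexed parameters encode.
Passing tests therefore demonstrate the internal consistency of the model
and its faithful implementation, not the external validity of the
parameter sources.

## Randomness and reproducibility

All randomness flows through R's default generator from a single seed per
cohort. Every cycle draws a fixed number of uniforms (eight per patient)
in a fixed order regardless of arm or patient state, so two arms run with
the *same* seed share random numbers patient-by-patient: with a degenerate
device (sensitivity and false-positive rate zero) the arms then produce
bit-identical histories, and in general paired-seed comparisons estimate
between-arm differences with far less Monte-Carlo noise. The experiment
grid instead derives an independent sub-seed per (score, arm, grid value)
via `derive_seed()` — a small integer hash into [1, 2³¹−2] — matching the
design of independently simulated arms. Re-running any plan with the same
base seed reproduces every output file byte-identically.

## Problem sizes and numerical checks

The package's own tests run the model at the full design size — 30,000
patients per cohort over ten years — for the headline comparisons, which
takes well under a second per cohort; the complete 36-cohort baseline grid
runs in about ten seconds on one CPU. Distributional checks (one-cycle
event frequencies against their transition probabilities) use up to 10⁶
single-status patients and 4-standard-error binomial bands. Structural
properties — absorbing death, monotone AF knowledge, stroke-count
conservation (total = nonfatal + fatal), zero-discounting equivalence,
seeded determinism, the exact €437.65 cost gap under a degenerate device —
are asserted on smaller cohorts where distribution plays no role.

Degenerate inputs are defined rather than accidental: a single stroke-cost
anchor yields a constant schedule; anchors short of the horizon continue
the last segment's geometric decay; zero prevalence/incidence cohorts are
legal and produce zero AF; probabilities are validated to [0, 1] with each
violation reported by field name.

## Known limitations

* Annual cycles without half-cycle correction: events have no within-year
  timing, and therapy begun at detection acts only from the next year.
* Background mortality is status-specific but age-independent; a 10-year
  horizon with a 6%/yr rate understates survival curvature in the elderly.
* Stroke survivors carry no excess long-term mortality beyond acute case
  fatality, and no long-term routine-care visit costs are modelled — both
  will understate absolute per-patient costs, particularly at low scores
  where survivors live long; between-arm differences are much less
  affected because the same omission applies to both arms.
* Every alert is assumed to reach a physician; lower care-seeking would
  shrink both costs and prevented strokes.
* The ECG confirmation rate is applied per alert-year independently; no
  patient-level persistence of "hard to confirm" paroxysmal AF.
* No quality-of-life weighting: outcomes are euros and stroke counts, not
  QALYs, so no ICER-per-QALY is computed.
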