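# afscreen

Patient-level Monte-Carlo cost-effectiveness model of screening for atrial
fibrillation (AF) with photoplethysmography (PPG) wrist-worn devices.

AF is one of the most common cardiac arrhythmias, often paroxysmal and
asymptomatic, and it raises stroke risk roughly 2.4-fold. Once diagnosed,
anticoagulation (NOAC) cuts the stroke risk by about two thirds — so finding
silent AF early matters. `afscreen` asks what continuous wrist-device
screening is worth, in euros and in prevented strokes, from the perspective
of statutory health insurance, for patients stratified by their
CHA₂DS₂-VASc stroke-risk score (1–9).

The package is aimed at health-economics and epidemiology researchers who
want a transparent, fully scriptable and testable state-transition
microsimulation rather than a spreadsheet.

## The model

Each simulated patient runs through annual Markov cycles over a 10-year
horizon. One cycle is:

1. **AF onset** — patients without AF acquire it with the score-specific
   incidence *I(s)*/100 per year.
2. **Detection cascade** — in the device arm, undetected AF triggers a true
   alert with sensitivity *Se* = 0.93; every alert leads to a physician
   visit with ECG, which confirms the diagnosis with the scenario's ECG
   confirmation rate *c* ∈ {1.0, 0.75, 0.5}. Patients without AF raise a
   false alert with probability 0.002/yr (visit logged, misdiagnosis
   cleared). AF still undetected afterwards can be found by standard care in
   either arm with probability 0.3609/yr. A confirmed diagnosis starts NOAC
   therapy — in males from score 1, in females from score 2 — effective
   from the next cycle.
3. **End points** — a stroke occurs with the status-specific incidence
   (untreated AF: Table values up to 14.44/100 py; on NOAC: ×(1−0.66); no
   AF: ÷2.42) and is fatal with status-specific case fatality (63% / 42% /
   34%); otherwise death from other causes (11.1% with AF, 6% without);
   major bleeding is drawn independently (0.02/yr on NOAC). A nonfatal
   stroke in undetected AF leads to diagnosis and therapy. Death is
   absorbing; AF is never cured.

Each patient-year is priced in euros — €437.65 one-time device, €67.23 per
ECG visit, €1226.40 per NOAC year, a post-stroke cost schedule anchored at
€15,753 (year 1), €4,480 (year 2) and €1,481 (year 10) with geometric
interpolation in between, €1,995 per bleeding event — and discounted at
3%/yr. Arms are compared by incremental cost, prevented (fatal) strokes,
and cost per prevented (fatal) stroke:

```
cost per prevented stroke = (Σ costs_device − Σ costs_no_device) / (strokes_no_device − strokes_device)
```

## Worked example

Score-7 patients, device arm with 75% ECG confirmation versus standard
care, 30,000 patients per arm, common random numbers:

```r
library(afscreen)
params <- af_parameters()
costs  <- af_costs()

seed <- derive_seed(2026, 7, "paired")
ref <- simulate_cohort(7, no_device_arm(),  params, costs, seed = seed)
dev <- simulate_cohort(7, device_arm(0.75), params, costs, seed = seed)
ref
#> Cohort result: score 7, no device, n = 30000
#>   average discounted cost/patient: EUR 9779.84
#>   strokes: 12259 total (6938 nonfatal, 5321 fatal)
dev
#> Cohort result: score 7, device (ECG confirmation 75%), n = 30000
#>   average discounted cost/patient: EUR 10271.56
#>   strokes: 11445 total (6781 nonfatal, 4664 fatal)

compare_arms(summarize_cohort(ref), summarize_cohort(dev))
#>   score ecg_confirmation cost_difference prevented_strokes
#> 1     7             0.75        14751733               814
#>   cost_per_prevented_stroke prevented_fatal_strokes cost_per_prevented_fatal_stroke
#> 1                  18122.52                     657                        22453.17
```

Screening this cohort costs about €492 extra per patient over 10 years and
prevents 814 strokes (657 fatal) among 30,000 patients — roughly €18,000
per prevented stroke. At low scores the same device spend prevents almost
nothing; cost-effectiveness improves steeply with the risk score.

The full study grid (9 scores × 4 arms, plus device-sensitivity and
false-positive-rate grids at 75% confirmation) runs from one call or from
the shell:

```r
plan <- experiment_plan()          # 30,000 patients per cohort
res  <- run_baseline_grid(plan, params, costs)
write_report_tables(res, dir = "results")
```

```sh
Rscript inst/scripts/afscreen.R baseline --seed 42 --out results
Rscript inst/scripts/afscreen.R default-config   # dump the YAML config
```

All model inputs can also be supplied through a YAML configuration file
(`read_af_config()` / `af_model_from_config()`).

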