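# shared fixtures: base-case parameters plus degenerate variants used to
# force or suppress single pathways

base_params <- function(...) af_parameters(...)
base_costs <- function(...) af_costs(...)

# everyone has AF from the start, nothing else can happen
all_af_params <- function(...) {
  af_parameters(prevalence = rep(1, 10), af_incidence = rep(0, 10), ...)
}

# no events at all: no AF, no strokes, no deaths, no alerts
null_params <- function(...) {
  af_parameters(
    prevalence = rep(0, 10), af_incidence = rep(0, 10),
    stroke_incidence_untreated = rep(0, 10),
    device_sensitivity = 0, device_false_positive = 0,
    standard_care_detection = 0,
    other_mortality_no_af = 0, other_mortality_untreated_af = 0,
    other_mortality_treated_af = 0, bleed_prob_on_noac = 0,
    ...
  )
}

# one-row patient state built directly, for unit-level engine checks
patient_row <- function(score = 5, sex = "male", af_status = "af_undetected",
                        alive = TRUE, years_since_last_stroke = NA_integer_,
                        stroke_count = 0L) {
  data.frame(id = 1L, score = as.integer(score), sex = sex,
             af_status = af_status, alive = alive, death_cause = "none",
             years_since_last_stroke = years_since_last_stroke,
             stroke_count = stroke_count, stringsAsFactors = FALSE)
}

# replicate a patient row n times (ids renumbered)
patient_block <- function(n, ...) {
  df <- patient_row(...)[rep(1L, n), ]
  df$id <- seq_len(n)
  rownames(df) <- NULL
  df
}

# minimal cohort-summary row for outcome-level tests
summary_row <- function(score, arm, conf, n, avg_cost, total, nonfatal,
                        fatal) {
  data.frame(score = score, arm = arm, ecg_confirmation = conf, n = n,
             avg_cost = avg_cost, total_strokes = total,
             nonfatal_strokes = nonfatal, fatal_strokes = fatal)
}
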