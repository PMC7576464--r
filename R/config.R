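#' Default model configuration
#'
#' The whole model is driven by one nested configuration list with sections
#' `params`, `costs` and `experiment`. The defaults reproduce the base case:
#' 30,000 patients per cohort, scores 1..9, device arms at ECG confirmation
#' 100/75/50%, and the one-way sensitivity grids over device sensitivity
#' (0.86, 0.93, 1.00) and false-positive rate (0.002, 0.01, 0.05) at 75%
#' confirmation.
#'
#' @return A nested list suitable for [write_af_config()] /
#'   [read_af_config()].
#' @export
default_af_config <- function() {
  p <- af_parameters()
  co <- af_costs()
  list(
    params = list(
      prevalence = as.numeric(p$prevalence),
      af_incidence = as.numeric(p$af_incidence),
      stroke_incidence_untreated = as.numeric(p$stroke_incidence_untreated),
      device_sensitivity = p$device_sensitivity,
      device_false_positive = p$device_false_positive,
      ecg_confirmation = p$ecg_confirmation,
      misdiagnosis_clearance = p$misdiagnosis_clearance,
      standard_care_detection = p$standard_care_detection,
      relative_stroke_risk_af = p$relative_stroke_risk_af,
      noac_risk_reduction = p$noac_risk_reduction,
      stroke_mortality_no_af = p$stroke_mortality_no_af,
      stroke_mortality_untreated = p$stroke_mortality_untreated,
      stroke_mortality_treated = p$stroke_mortality_treated,
      other_mortality_no_af = p$other_mortality_no_af,
      other_mortality_untreated_af = p$other_mortality_untreated_af,
      other_mortality_treated_af = p$other_mortality_treated_af,
      bleed_prob_on_noac = p$bleed_prob_on_noac,
      bleed_prob_off_noac = p$bleed_prob_off_noac,
      horizon_years = p$horizon_years,
      discount_rate = p$discount_rate,
      cohort_size = p$cohort_size
    ),
    costs = list(
      device_cost = co$device_cost,
      visit_components = as.list(co$visit_components),
      noac_annual_cost = co$noac_annual_cost,
      stroke_cost_anchors = list(year = c(1L, 2L, 10L),
                                 cost = c(15753, 4480, 1481)),
      bleeding_cost = co$bleeding_cost
    ),
    experiment = list(
      scores = 1:9,
      confirmations = c(1.0, 0.75, 0.5),
      n = p$cohort_size,
      base_seed = 20201006,
      sensitivity_values = c(0.86, 0.93, 1.00),
      false_positive_values = c(0.002, 0.01, 0.05),
      sensitivity_confirmation = 0.75
    )
  )
}

#' Write a configuration to a YAML file
#'
#' @param config Nested configuration list (see [default_af_config()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_af_config <- function(config = default_af_config(), path) {
  yaml::write_yaml(config, path, precision = 12)
  invisible(path)
}

#' Read a configuration from a YAML file
#'
#' Missing keys fall back to the defaults of [default_af_config()], so a
#' config file only needs to state what it changes.
#'
#' @param path YAML file path.
#' @return A nested configuration list.
#' @export
read_af_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_af_config(), user)
}

#' Build parameter and cost objects from a configuration
#'
#' @param config Nested configuration list.
#' @return List with validated elements `params` ([af_parameters()]),
#'   `costs` ([af_costs()]) and the `experiment` section.
#' @export
af_model_from_config <- function(config = default_af_config()) {
  pc <- config$params
  params <- af_parameters(
    prevalence = pc$prevalence,
    af_incidence = pc$af_incidence,
    stroke_incidence_untreated = pc$stroke_incidence_untreated,
    device_sensitivity = pc$device_sensitivity,
    device_false_positive = pc$device_false_positive,
    ecg_confirmation = pc$ecg_confirmation,
    misdiagnosis_clearance = pc$misdiagnosis_clearance,
    standard_care_detection = pc$standard_care_detection,
    relative_stroke_risk_af = pc$relative_stroke_risk_af,
    noac_risk_reduction = pc$noac_risk_reduction,
    stroke_mortality_no_af = pc$stroke_mortality_no_af,
    stroke_mortality_untreated = pc$stroke_mortality_untreated,
    stroke_mortality_treated = pc$stroke_mortality_treated,
    other_mortality_no_af = pc$other_mortality_no_af,
    other_mortality_untreated_af = pc$other_mortality_untreated_af,
    other_mortality_treated_af = pc$other_mortality_treated_af,
    bleed_prob_on_noac = pc$bleed_prob_on_noac,
    bleed_prob_off_noac = pc$bleed_prob_off_noac,
    horizon_years = pc$horizon_years,
    discount_rate = pc$discount_rate,
    cohort_size = pc$cohort_size
  )
  cc <- config$costs
  costs <- af_costs(
    device_cost = cc$device_cost,
    visit_components = unlist(cc$visit_components),
    noac_annual_cost = cc$noac_annual_cost,
    stroke_cost_anchors = data.frame(year = cc$stroke_cost_anchors$year,
                                     cost = cc$stroke_cost_anchors$cost),
    bleeding_cost = cc$bleeding_cost,
    horizon_years = pc$horizon_years
  )
  validate_costs(costs, horizon_years = params$horizon_years)
  list(params = params, costs = costs, experiment = config$experiment)
}
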