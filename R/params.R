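#' Score-indexed parameter vector
#'
#' Many model inputs vary with the CHA2DS2-VASc stroke-risk score, an integer
#' from 0 to 9. A score vector holds one value per score, in score order.
#'
#' @param values Numeric vector of length 10, entry `k` belonging to score
#'   `k - 1`.
#' @param kind One of `"proportion"` (must lie in `[0, 1]`) or `"rate"`
#'   (events per 100 person-years, must lie in `[0, 100)`).
#' @param name Field name used in error messages.
#' @return The validated numeric vector with class `"score_vector"`.
#' @export
score_vector <- function(values, kind = c("rate", "proportion"), name = "score_vector") {
  kind <- match.arg(kind)
  if (length(values) != 10L) {
    stop(sprintf("%s must have exactly 10 entries (scores 0..9), got %d",
                 name, length(values)), call. = FALSE)
  }
  if (!is.numeric(values) || anyNA(values)) {
    stop(sprintf("%s must be numeric with no missing values", name), call. = FALSE)
  }
  if (any(values < 0)) {
    stop(sprintf("%s has negative entries: %s", name,
                 paste(values[values < 0], collapse = ", ")), call. = FALSE)
  }
  hi <- if (kind == "proportion") 1 else 100
  if (any(values >= hi + 1e-12) && kind == "rate") {
    stop(sprintf("%s is a per-100-person-year rate and must be < 100", name),
         call. = FALSE)
  }
  if (kind == "proportion" && any(values > 1)) {
    stop(sprintf("%s is a proportion and must lie in [0, 1]", name), call. = FALSE)
  }
  structure(as.numeric(values), class = "score_vector", kind = kind)
}

#' Look up a score-indexed value
#'
#' @param v A [score_vector()] (or plain length-10 numeric).
#' @param score Integer score(s) in 0..9 (vectorised).
#' @return The value(s) for the requested score(s).
#' @export
score_value <- function(v, score) {
  if (any(score < 0 | score > 9)) {
    stop("score must be in 0..9", call. = FALSE)
  }
  unclass(v)[score + 1L]
}

#' Stroke incidence in patients without AF
#'
#' Untreated AF multiplies stroke risk by a published relative risk (2.42 in
#' the base case). Dividing the untreated-AF incidence by that ratio yields
#' the score-specific stroke incidence for patients without AF.
#'
#' @param untreated Score vector of stroke incidence in untreated AF
#'   (per 100 person-years).
#' @param relative_risk Relative stroke risk of untreated AF versus no AF;
#'   must be positive.
#' @return Score vector of stroke incidence without AF (per 100
#'   person-years), unrounded.
#' @export
derive_no_af_incidence <- function(untreated, relative_risk) {
  if (!is.numeric(relative_risk) || length(relative_risk) != 1L ||
      is.na(relative_risk) || relative_risk <= 0) {
    stop("relative_risk must be a single positive number", call. = FALSE)
  }
  score_vector(unclass(untreated) / relative_risk, kind = "rate",
               name = "stroke_incidence_no_af")
}

#' Stroke incidence in AF patients on anticoagulation
#'
#' Oral anticoagulation (NOAC, rivaroxaban in the base case) reduces the
#' stroke risk of AF patients by a fixed fraction (two thirds, 0.66, in the
#' base case).
#'
#' @param untreated Score vector of stroke incidence in untreated AF
#'   (per 100 person-years).
#' @param risk_reduction Fractional risk reduction in `[0, 1]`.
#' @return Score vector of stroke incidence on NOAC (per 100 person-years).
#' @export
derive_noac_incidence <- function(untreated, risk_reduction) {
  if (!is.numeric(risk_reduction) || length(risk_reduction) != 1L ||
      is.na(risk_reduction) || risk_reduction < 0 || risk_reduction > 1) {
    stop("risk_reduction must be a single number in [0, 1]", call. = FALSE)
  }
  score_vector(unclass(untreated) * (1 - risk_reduction), kind = "rate",
               name = "stroke_incidence_noac")
}

#' Annual probability that undiagnosed AF is found by standard care
#'
#' Home-monitoring trials report the yearly AF detection rate in actively
#' monitored versus unmonitored individuals. Scaling the device sensitivity
#' by the unmonitored:monitored detection ratio gives the yearly probability
#' that an undiagnosed AF case is picked up during routine care without a
#' device.
#'
#' @param device_sensitivity Probability that the device flags true AF.
#' @param unmonitored_rate Newly diagnosed AF per 100 person-years without
#'   active monitoring.
#' @param monitored_rate Newly diagnosed AF per 100 person-years under active
#'   monitoring; must be positive.
#' @return A single annual detection probability.
#' @export
derive_standard_care_detection <- function(device_sensitivity,
                                           unmonitored_rate,
                                           monitored_rate) {
  if (!is.numeric(monitored_rate) || length(monitored_rate) != 1L ||
      is.na(monitored_rate) || monitored_rate <= 0) {
    stop("monitored_rate must be a single positive number", call. = FALSE)
  }
  if (device_sensitivity < 0 || device_sensitivity > 1) {
    stop("device_sensitivity must lie in [0, 1]", call. = FALSE)
  }
  if (unmonitored_rate < 0) {
    stop("unmonitored_rate must be non-negative", call. = FALSE)
  }
  device_sensitivity * (unmonitored_rate / monitored_rate)
}

#' Sum the itemised components of a physician visit
#'
#' The per-visit cost is the exact sum of the fee-schedule items incurred
#' when a device alert (or routine suspicion) is worked up: ordination and
#' consultation, urgent care, telemedical care, and the ECG diagnostics.
#'
#' @param components Numeric vector of non-negative euro amounts.
#' @return Their exact sum in euros.
#' @export
sum_visit_cost <- function(components) {
  if (length(components) == 0L) return(0)
  if (!is.numeric(components) || anyNA(components)) {
    stop("components must be numeric with no missing values", call. = FALSE)
  }
  if (any(components < 0)) {
    stop(sprintf("negative cost component: %s",
                 paste(components[components < 0], collapse = ", ")),
         call. = FALSE)
  }
  sum(components)
}

#' Build the per-year post-stroke cost schedule
#'
#' Published stroke costs are available only for anchor years (first year
#' after the event, second year, tenth year). Intermediate years are filled
#' by geometric (log-linear) interpolation between neighbouring anchors:
#' between anchors `(a, c_a)` and `(b, c_b)` the year-`k` cost is
#' `c_a * (c_b / c_a)^((k - a) / (b - a))`. Years before the first anchor are
#' held at the first anchor's value; years after the last anchor continue the
#' last segment's geometric decay.
#'
#' @param anchors A data frame with columns `year` (integers within
#'   `1..horizon`, no duplicates) and `cost` (positive euros), or a named
#'   numeric vector whose names are years.
#' @param horizon Number of schedule years (the model time horizon).
#' @return Numeric vector of length `horizon`; entry `k` is the cost incurred
#'   in the `k`-th year after a stroke.
#' @export
build_stroke_cost_schedule <- function(anchors, horizon) {
  if (is.numeric(anchors) && !is.null(names(anchors))) {
    anchors <- data.frame(year = as.integer(names(anchors)), cost = unname(anchors))
  }
  if (!is.data.frame(anchors) || !all(c("year", "cost") %in% names(anchors)) ||
      nrow(anchors) == 0L) {
    stop("anchors must be a non-empty data frame with columns year and cost",
         call. = FALSE)
  }
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 1) {
    stop("horizon must be a single integer >= 1", call. = FALSE)
  }
  yrs <- as.integer(anchors$year)
  if (anyDuplicated(yrs)) {
    stop("duplicate anchor years: ",
         paste(yrs[duplicated(yrs)], collapse = ", "), call. = FALSE)
  }
  if (any(yrs < 1L) || any(yrs > horizon)) {
    stop("anchor years must lie within 1..horizon", call. = FALSE)
  }
  if (any(anchors$cost <= 0)) {
    stop("anchor costs must be positive", call. = FALSE)
  }
  o <- order(yrs)
  yrs <- yrs[o]
  cst <- anchors$cost[o]

  out <- numeric(horizon)
  if (length(yrs) == 1L) {
    out[] <- cst
    return(out)
  }
  # log-linear interpolation is linear interpolation of log-costs;
  # rule = 2 holds the ends, then the tail decay is extended explicitly
  out[] <- exp(stats::approx(yrs, log(cst), xout = seq_len(horizon),
                             rule = 2)$y)
  if (length(yrs) >= 2L && max(yrs) < horizon) {
    k <- length(yrs)
    ratio <- (cst[k] / cst[k - 1L])^(1 / (yrs[k] - yrs[k - 1L]))
    beyond <- seq(max(yrs) + 1L, horizon)
    out[beyond] <- cst[k] * ratio^(beyond - max(yrs))
  }
  out[yrs] <- cst  # anchors exact, immune to rounding in exp(log())
  out
}

#' Model parameter set
#'
#' Bundles every transition probability and rate of the state-transition
#' model, with base-case defaults. Score-indexed rates are per 100
#' person-years and are converted to annual transition probabilities as
#' `rate / 100` (plain division, matching the 1-year cycle of the model).
#'
#' @param prevalence Baseline AF prevalence by score (proportion).
#' @param af_incidence AF incidence in the general population by score
#'   (per 100 person-years).
#' @param stroke_incidence_untreated Stroke incidence in untreated AF by
#'   score (per 100 person-years).
#' @param device_sensitivity Probability a device flags true AF in a year.
#' @param device_false_positive Annual probability of a false device alert in
#'   a patient without AF.
#' @param ecg_confirmation Probability that a true device alert is confirmed
#'   by physician ECG (scenario parameter: 1.0, 0.75 or 0.5).
#' @param misdiagnosis_clearance Probability that a false alert is cleared at
#'   the ECG visit (1.0: the physician finds no arrhythmia).
#' @param standard_care_detection Annual probability that undiagnosed AF is
#'   found by routine care (both arms).
#' @param relative_stroke_risk_af Relative stroke risk, untreated AF vs no AF.
#' @param noac_risk_reduction Fractional stroke-risk reduction on NOAC.
#' @param stroke_mortality_no_af,stroke_mortality_untreated,stroke_mortality_treated
#'   Case fatality of a stroke by AF/treatment status.
#' @param other_mortality_no_af Annual non-stroke mortality without AF.
#' @param other_mortality_untreated_af Annual non-stroke mortality with
#'   untreated AF.
#' @param other_mortality_treated_af Annual non-stroke mortality with treated
#'   AF. Not published; defaults to the untreated-AF value (conservative).
#' @param bleed_prob_on_noac Annual probability of a major bleeding event
#'   while on NOAC. Not published; default 0.02.
#' @param bleed_prob_off_noac Annual major-bleeding probability off NOAC
#'   (default 0).
#' @param horizon_years Simulation horizon in years (default 10).
#' @param discount_rate Annual discount rate for costs (default 0.03).
#' @param cohort_size Default number of simulated patients per cohort
#'   (default 30000).
#' @param stroke_incidence_no_af,stroke_incidence_noac Optional overrides for
#'   the derived incidence vectors; by default derived from
#'   `stroke_incidence_untreated` via [derive_no_af_incidence()] and
#'   [derive_noac_incidence()].
#' @return A validated object of class `"af_parameters"`.
#' @export
af_parameters <- function(prevalence = c(0.01, 0.015, 0.034, 0.067, 0.118,
                                         0.182, 0.255, 0.302, 0.403, 0.492),
                          af_incidence = c(0.17, 0.21, 0.49, 0.94, 1.65,
                                           2.31, 2.75, 3.39, 4.09, 6.71),
                          stroke_incidence_untreated = c(0.2, 0.6, 2.5, 3.7, 5.5,
                                                         8.4, 11.4, 13.1, 12.6, 14.44),
                          device_sensitivity = 0.93,
                          device_false_positive = 0.002,
                          ecg_confirmation = 1.0,
                          misdiagnosis_clearance = 1.0,
                          standard_care_detection = derive_standard_care_detection(
                            device_sensitivity = 0.93,
                            unmonitored_rate = 2.6,
                            monitored_rate = 6.7),
                          relative_stroke_risk_af = 2.42,
                          noac_risk_reduction = 0.66,
                          stroke_mortality_no_af = 0.34,
                          stroke_mortality_untreated = 0.63,
                          stroke_mortality_treated = 0.42,
                          other_mortality_no_af = 0.06,
                          other_mortality_untreated_af = 0.111,
                          other_mortality_treated_af = 0.111,
                          bleed_prob_on_noac = 0.02,
                          bleed_prob_off_noac = 0,
                          horizon_years = 10L,
                          discount_rate = 0.03,
                          cohort_size = 30000L,
                          stroke_incidence_no_af = NULL,
                          stroke_incidence_noac = NULL) {
  untreated <- score_vector(stroke_incidence_untreated, "rate",
                            "stroke_incidence_untreated")
  if (is.null(stroke_incidence_no_af)) {
    stroke_incidence_no_af <- derive_no_af_incidence(untreated,
                                                     relative_stroke_risk_af)
  }
  if (is.null(stroke_incidence_noac)) {
    stroke_incidence_noac <- derive_noac_incidence(untreated,
                                                   noac_risk_reduction)
  }
  p <- structure(list(
    prevalence = score_vector(prevalence, "proportion", "prevalence"),
    af_incidence = score_vector(af_incidence, "rate", "af_incidence"),
    stroke_incidence_untreated = untreated,
    stroke_incidence_no_af = score_vector(stroke_incidence_no_af, "rate",
                                          "stroke_incidence_no_af"),
    stroke_incidence_noac = score_vector(stroke_incidence_noac, "rate",
                                         "stroke_incidence_noac"),
    device_sensitivity = device_sensitivity,
    device_false_positive = device_false_positive,
    ecg_confirmation = ecg_confirmation,
    misdiagnosis_clearance = misdiagnosis_clearance,
    standard_care_detection = standard_care_detection,
    relative_stroke_risk_af = relative_stroke_risk_af,
    noac_risk_reduction = noac_risk_reduction,
    stroke_mortality_no_af = stroke_mortality_no_af,
    stroke_mortality_untreated = stroke_mortality_untreated,
    stroke_mortality_treated = stroke_mortality_treated,
    other_mortality_no_af = other_mortality_no_af,
    other_mortality_untreated_af = other_mortality_untreated_af,
    other_mortality_treated_af = other_mortality_treated_af,
    bleed_prob_on_noac = bleed_prob_on_noac,
    bleed_prob_off_noac = bleed_prob_off_noac,
    horizon_years = as.integer(horizon_years),
    discount_rate = discount_rate,
    cohort_size = as.integer(cohort_size)
  ), class = "af_parameters")
  validate_parameters(p)
}

#' Cost parameter set
#'
#' Unit costs in euros from the statutory-health-insurance perspective.
#' Amounts are kept unrounded internally; rounding is display-only.
#'
#' @param device_cost One-time device purchase price (EUR).
#' @param visit_components Itemised euro amounts of one physician visit with
#'   ECG diagnostics; their sum is the per-visit cost.
#' @param noac_annual_cost Annual NOAC (rivaroxaban) medication cost (EUR).
#' @param stroke_cost_anchors Anchor years and euro costs for the post-stroke
#'   cost schedule (see [build_stroke_cost_schedule()]).
#' @param bleeding_cost Cost of one major bleeding event (EUR).
#' @param horizon_years Schedule length; must match the model horizon.
#' @param stroke_cost_schedule Optional explicit schedule overriding the
#'   anchors.
#' @return A validated object of class `"af_costs"`.
#' @export
af_costs <- function(device_cost = 437.65,
                     visit_components = c(ordination_consultation = 13.20,
                                          urgent_care = 12.90,
                                          telemedical_care = 9.52,
                                          long_term_and_12_lead_ecg = 9.96,
                                          stress_ecg = 21.65),
                     noac_annual_cost = 1226.40,
                     stroke_cost_anchors = data.frame(year = c(1L, 2L, 10L),
                                                      cost = c(15753, 4480, 1481)),
                     bleeding_cost = 1995,
                     horizon_years = 10L,
                     stroke_cost_schedule = NULL) {
  if (is.null(stroke_cost_schedule)) {
    stroke_cost_schedule <- build_stroke_cost_schedule(stroke_cost_anchors,
                                                       horizon_years)
  }
  cc <- structure(list(
    device_cost = device_cost,
    visit_components = visit_components,
    visit_and_diagnostics_cost = sum_visit_cost(visit_components),
    noac_annual_cost = noac_annual_cost,
    stroke_cost_schedule = stroke_cost_schedule,
    bleeding_cost = bleeding_cost
  ), class = "af_costs")
  validate_costs(cc)
}

.check_prob <- function(x, name, errs) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    errs <- c(errs, sprintf("%s must be a probability in [0, 1], got %s",
                            name, paste(format(x), collapse = ", ")))
  }
  errs
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model parameters: probabilities
#' in `[0, 1]`, rate vectors of length 10 with consistent orderings
#' (anticoagulated and no-AF stroke incidence never exceed the untreated-AF
#' incidence), horizon and cohort size at least 1, non-negative discounting.
#'
#' @param params An `"af_parameters"` object (or plain list with the same
#'   fields).
#' @return `params`, invisibly unchanged, if valid; otherwise an error
#'   listing every violated invariant with field name and offending value.
#' @export
validate_parameters <- function(params) {
  errs <- character()
  for (nm in c("device_sensitivity", "device_false_positive",
               "ecg_confirmation", "misdiagnosis_clearance",
               "standard_care_detection",
               "stroke_mortality_no_af", "stroke_mortality_untreated",
               "stroke_mortality_treated", "other_mortality_no_af",
               "other_mortality_untreated_af", "other_mortality_treated_af",
               "bleed_prob_on_noac", "bleed_prob_off_noac")) {
    errs <- .check_prob(params[[nm]], nm, errs)
  }
  for (nm in c("prevalence", "af_incidence", "stroke_incidence_untreated",
               "stroke_incidence_no_af", "stroke_incidence_noac")) {
    v <- params[[nm]]
    if (length(v) != 10L || anyNA(v) || any(v < 0)) {
      errs <- c(errs, sprintf("%s must be 10 non-negative values", nm))
    }
  }
  tol <- 1e-9
  if (any(unclass(params$stroke_incidence_noac) >
          unclass(params$stroke_incidence_untreated) + tol)) {
    errs <- c(errs, "stroke_incidence_noac exceeds stroke_incidence_untreated at some score")
  }
  if (any(unclass(params$stroke_incidence_no_af) >
          unclass(params$stroke_incidence_untreated) + tol)) {
    errs <- c(errs, "stroke_incidence_no_af exceeds stroke_incidence_untreated at some score")
  }
  if (params$relative_stroke_risk_af <= 0) {
    errs <- c(errs, sprintf("relative_stroke_risk_af must be positive, got %s",
                            params$relative_stroke_risk_af))
  }
  if (params$noac_risk_reduction < 0 || params$noac_risk_reduction > 1) {
    errs <- c(errs, sprintf("noac_risk_reduction must lie in [0, 1], got %s",
                            params$noac_risk_reduction))
  }
  if (params$horizon_years < 1) {
    errs <- c(errs, sprintf("horizon_years must be >= 1, got %s",
                            params$horizon_years))
  }
  if (params$discount_rate < 0) {
    errs <- c(errs, sprintf("discount_rate must be >= 0, got %s",
                            params$discount_rate))
  }
  if (params$cohort_size < 1) {
    errs <- c(errs, sprintf("cohort_size must be >= 1, got %s",
                            params$cohort_size))
  }
  if (length(errs)) {
    stop("invalid parameters:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(params)
}

#' Validate a cost parameter set
#'
#' @param costs An `"af_costs"` object.
#' @param horizon_years If given, the stroke-cost schedule must have exactly
#'   this length.
#' @return `costs`, invisibly, if valid; otherwise an error naming each
#'   violated invariant.
#' @export
validate_costs <- function(costs, horizon_years = NULL) {
  errs <- character()
  for (nm in c("device_cost", "visit_and_diagnostics_cost",
               "noac_annual_cost", "bleeding_cost")) {
    x <- costs[[nm]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
      errs <- c(errs, sprintf("%s must be a single non-negative amount, got %s",
                              nm, paste(format(x), collapse = ", ")))
    }
  }
  s <- costs$stroke_cost_schedule
  if (!is.numeric(s) || length(s) < 1L || anyNA(s) || any(s < 0)) {
    errs <- c(errs, "stroke_cost_schedule must be non-negative amounts")
  } else {
    if (is.unsorted(rev(s), strictly = FALSE)) {
      errs <- c(errs, "stroke_cost_schedule must be non-increasing")
    }
    if (!is.null(horizon_years) && length(s) != horizon_years) {
      errs <- c(errs, sprintf("stroke_cost_schedule has length %d but horizon is %d",
                              length(s), horizon_years))
    }
  }
  if (any(costs$visit_components < 0)) {
    errs <- c(errs, "visit_components must be non-negative")
  }
  if (length(errs)) {
    stop("invalid costs:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(costs)
}

#' @export
print.af_parameters <- function(x, ...) {
  cat("AF screening model parameters\n")
  cat(sprintf("  horizon %d years, discount rate %.1f%%/yr, cohort size %d\n",
              x$horizon_years, 100 * x$discount_rate, x$cohort_size))
  cat(sprintf("  device: sensitivity %.2f, false-positive %.3f, ECG confirmation %.2f\n",
              x$device_sensitivity, x$device_false_positive, x$ecg_confirmation))
  cat(sprintf("  standard-care detection %.4f/yr\n", x$standard_care_detection))
  cat("  score-indexed rates (scores 0..9):\n")
  for (nm in c("prevalence", "af_incidence", "stroke_incidence_untreated",
               "stroke_incidence_no_af", "stroke_incidence_noac")) {
    cat(sprintf("    %-28s %s\n", nm,
                paste(round(unclass(x[[nm]]), 4), collapse = " ")))
  }
  invisible(x)
}

#' @export
print.af_costs <- function(x, ...) {
  cat("AF screening model costs (EUR)\n")
  cat(sprintf("  device (one-time) %.2f | visit + diagnostics %.2f | NOAC/yr %.2f | bleeding %.2f\n",
              x$device_cost, x$visit_and_diagnostics_cost,
              x$noac_annual_cost, x$bleeding_cost))
  cat("  post-stroke schedule:",
      paste(round(x$stroke_cost_schedule), collapse = " "), "\n")
  invisible(x)
}
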