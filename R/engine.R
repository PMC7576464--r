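#' Study arms
#'
#' The model compares a no-device arm (standard care only) against device
#' arms in which every patient wears a PPG screening device; device arms are
#' further distinguished by the ECG confirmation rate applied to true alerts.
#'
#' @param ecg_confirmation Probability in `[0, 1]` that a physician confirms
#'   a true device alert by ECG (scenario parameter; 1.0, 0.75 and 0.5 in the
#'   base scenarios).
#' @return An object of class `"af_arm"` with fields `label` and
#'   `ecg_confirmation`.
#' @export
device_arm <- function(ecg_confirmation = 1.0) {
  if (!is.numeric(ecg_confirmation) || length(ecg_confirmation) != 1L ||
      is.na(ecg_confirmation) || ecg_confirmation < 0 || ecg_confirmation > 1) {
    stop("ecg_confirmation must be a probability in [0, 1]", call. = FALSE)
  }
  structure(list(label = "device", ecg_confirmation = ecg_confirmation),
            class = "af_arm")
}

#' @rdname device_arm
#' @export
no_device_arm <- function() {
  structure(list(label = "no_device", ecg_confirmation = NA_real_),
            class = "af_arm")
}

#' @export
print.af_arm <- function(x, ...) {
  if (x$label == "device") {
    cat(sprintf("device arm (ECG confirmation %.0f%%)\n",
                100 * x$ecg_confirmation))
  } else {
    cat("no-device arm\n")
  }
  invisible(x)
}

#' Annual transition probabilities for each patient
#'
#' Maps each patient's current health/diagnosis status to the probabilities
#' governing one model year. Stroke incidence, stroke case fatality and
#' non-stroke mortality are keyed to status: no AF; AF without therapy
#' (undetected, or detected but treatment-ineligible); AF on NOAC. Device
#' alert probabilities apply only in the device arm: true alerts only while
#' AF is still undetected, false alerts only while AF is absent.
#' Standard-care detection applies to undetected AF in both arms.
#'
#' Rates per 100 person-years convert to annual probabilities as
#' `rate / 100` (the model runs plain 1-year cycles).
#'
#' @param cohort Patient data frame (see [generate_cohort()]); may also carry
#'   scores of 0 for parameter exploration.
#' @param arm An arm object ([device_arm()] / [no_device_arm()]).
#' @param params An [af_parameters()] object.
#' @param check_alive Error if any patient is dead (default). The simulation
#'   loop disables this and masks dead patients itself.
#' @return Data frame, one row per patient, with columns `p_af_onset`,
#'   `p_true_alert`, `p_false_alert`, `p_confirm`, `p_standard_detect`,
#'   `p_stroke`, `p_stroke_fatal`, `p_other_death`, `p_bleed` and the helper
#'   flag `on_noac`.
#' @export
transition_probabilities <- function(cohort, arm, params, check_alive = TRUE) {
  if (check_alive && any(!cohort$alive)) {
    stop("transition probabilities are undefined for dead patients",
         call. = FALSE)
  }
  st <- cohort$af_status
  bad <- !(st %in% .af_statuses)
  if (any(bad)) {
    stop("unknown af_status: ", paste(unique(st[bad]), collapse = ", "),
         call. = FALSE)
  }
  score <- cohort$score
  n <- nrow(cohort)
  device <- arm$label == "device"

  no_af <- st == "no_af"
  undet <- st == "af_undetected"
  on_noac <- st == "af_detected_treated"
  af_untreated <- undet | st == "af_detected_untreated"

  p_stroke <- numeric(n)
  p_stroke[no_af] <- score_value(params$stroke_incidence_no_af, score[no_af]) / 100
  p_stroke[af_untreated] <- score_value(params$stroke_incidence_untreated,
                                        score[af_untreated]) / 100
  p_stroke[on_noac] <- score_value(params$stroke_incidence_noac,
                                   score[on_noac]) / 100

  p_fatal <- numeric(n)
  p_fatal[no_af] <- params$stroke_mortality_no_af
  p_fatal[af_untreated] <- params$stroke_mortality_untreated
  p_fatal[on_noac] <- params$stroke_mortality_treated

  p_od <- numeric(n)
  p_od[no_af] <- params$other_mortality_no_af
  p_od[af_untreated] <- params$other_mortality_untreated_af
  p_od[on_noac] <- params$other_mortality_treated_af

  p_bleed <- rep(params$bleed_prob_off_noac, n)
  p_bleed[on_noac] <- params$bleed_prob_on_noac

  data.frame(
    p_af_onset = ifelse(no_af, score_value(params$af_incidence, score) / 100, 0),
    p_true_alert = ifelse(device & undet, params$device_sensitivity, 0),
    p_false_alert = ifelse(device & no_af, params$device_false_positive, 0),
    p_confirm = rep(if (device) arm$ecg_confirmation else 0, n),
    p_standard_detect = ifelse(undet, params$standard_care_detection, 0),
    p_stroke = p_stroke,
    p_stroke_fatal = p_fatal,
    p_other_death = p_od,
    p_bleed = p_bleed,
    on_noac = on_noac
  )
}

#' One year of screening and AF detection
#'
#' Runs the detection cascade for one cycle. In the device arm a patient
#' with undetected AF raises a true alert with the device sensitivity; every
#' alert triggers a physician visit with ECG, and the alert is confirmed
#' with the arm's ECG confirmation rate, promoting the patient to a
#' diagnosed state (anticoagulated if eligible, see [treatment_eligible()]).
#' A patient without AF raises a false alert with the false-positive rate;
#' the visit is logged and the misdiagnosis cleared. Any AF still undetected
#' afterwards — including missed or unconfirmed alerts — can be found by
#' standard care in either arm, which counts as ECG-confirmed and also logs
#' one visit. Once a diagnosis is ECG-confirmed it holds for the rest of the
#' simulation and no further screening events occur.
#'
#' Therapy initiated here lowers stroke risk only from the next cycle: the
#' endpoint step of the current cycle uses probabilities computed before
#' screening.
#'
#' Draws `3 * nrow(cohort)` uniforms from the current random stream in a
#' fixed order regardless of arm or state, so that arms share random numbers
#' when run from the same seed.
#'
#' @param cohort Patient data frame.
#' @param arm Arm object.
#' @param probs Output of [transition_probabilities()] for this cycle.
#' @return List with the updated `cohort` and an `outcome` data frame
#'   (columns `device_true_alert`, `device_false_alert`, `confirmed`,
#'   `standard_care_detected`, `ecg_visits`).
#' @export
screen_and_detect <- function(cohort, arm, probs) {
  n <- nrow(cohort)
  u_alert <- stats::runif(n)
  u_confirm <- stats::runif(n)
  u_sc <- stats::runif(n)

  alive <- cohort$alive
  true_alert <- alive & u_alert < probs$p_true_alert
  confirmed <- true_alert & u_confirm < probs$p_confirm
  false_alert <- alive & u_alert < probs$p_false_alert
  # false alerts are always cleared at the visit (misdiagnosis_clearance = 1
  # in the model: the physician finds no arrhythmia), so no state change
  sc <- alive & !confirmed & cohort$af_status == "af_undetected" &
    u_sc < probs$p_standard_detect

  newly <- confirmed | sc
  if (any(newly)) {
    eligible <- treatment_eligible(cohort$score, cohort$sex)
    cohort$af_status[newly & eligible] <- "af_detected_treated"
    cohort$af_status[newly & !eligible] <- "af_detected_untreated"
  }

  outcome <- data.frame(
    device_true_alert = true_alert,
    device_false_alert = false_alert,
    confirmed = confirmed,
    standard_care_detected = sc,
    ecg_visits = as.integer(true_alert) + as.integer(false_alert) +
      as.integer(sc)
  )
  list(cohort = cohort, outcome = outcome)
}

#' One year of endpoints: stroke, other-cause death, bleeding
#'
#' The three possible end points of a cycle are a (fatal or nonfatal)
#' stroke, no event, or death from another cause; stroke and other-cause
#' death are mutually exclusive within a cycle. A stroke is drawn first with
#' the status-specific incidence and is fatal with the status-specific case
#' fatality. A nonfatal stroke in a patient with undetected AF leads to
#' diagnosis (and therapy if eligible) — effective, like screening-based
#' detection, from the next cycle. Each stroke (re)starts the post-stroke
#' cost clock at year 1; survivors' clocks advance by one each later year.
#' Bleeding events are drawn independently for patients alive at cycle
#' start. Death is absorbing.
#'
#' Draws `4 * nrow(cohort)` uniforms in fixed order (see
#' [screen_and_detect()]).
#'
#' @param cohort Patient data frame (after [screen_and_detect()]).
#' @param probs Transition probabilities computed at cycle start.
#' @return List with the updated `cohort` and an `outcome` data frame
#'   (columns `stroke` in `none/nonfatal/fatal`, `other_death`, `bleeding`,
#'   `post_stroke_year`).
#' @export
resolve_endpoint <- function(cohort, probs) {
  n <- nrow(cohort)
  u_stroke <- stats::runif(n)
  u_fatal <- stats::runif(n)
  u_death <- stats::runif(n)
  u_bleed <- stats::runif(n)

  alive <- cohort$alive
  ys <- cohort$years_since_last_stroke
  prior <- alive & !is.na(ys)
  ys[prior] <- ys[prior] + 1L

  stroke <- alive & u_stroke < probs$p_stroke
  fatal <- stroke & u_fatal < probs$p_stroke_fatal
  other_death <- alive & !stroke & u_death < probs$p_other_death
  bleeding <- alive & u_bleed < probs$p_bleed

  ys[stroke] <- 1L
  cohort$stroke_count[stroke] <- cohort$stroke_count[stroke] + 1L

  promote <- stroke & !fatal & cohort$af_status == "af_undetected"
  if (any(promote)) {
    eligible <- treatment_eligible(cohort$score, cohort$sex)
    cohort$af_status[promote & eligible] <- "af_detected_treated"
    cohort$af_status[promote & !eligible] <- "af_detected_untreated"
  }

  cohort$years_since_last_stroke <- ys
  cohort$alive[fatal | other_death] <- FALSE
  cohort$death_cause[fatal] <- "stroke"
  cohort$death_cause[other_death] <- "other"

  outcome <- data.frame(
    stroke = ifelse(fatal, "fatal", ifelse(stroke, "nonfatal", "none")),
    other_death = other_death,
    bleeding = bleeding,
    post_stroke_year = ifelse(alive & !is.na(ys), ys, NA_integer_)
  )
  list(cohort = cohort, outcome = outcome)
}

# One full simulation over the horizon; vectorised over patients.
# Returns final states, per-patient discounted/undiscounted costs with
# category breakdown, event counters and (optionally) a long event log.
.simulate <- function(cohort, arm, params, costs, keep_log = FALSE) {
  n <- nrow(cohort)
  horizon <- params$horizon_years
  rate <- params$discount_rate
  device <- arm$label == "device"

  cost_disc <- numeric(n)
  cost_undisc <- numeric(n)
  cat_disc <- c(device = 0, visits = 0, noac = 0, stroke = 0, bleeding = 0)
  if (device) {
    # one-time purchase at baseline, undiscounted
    cost_disc <- cost_disc + costs$device_cost
    cost_undisc <- cost_undisc + costs$device_cost
    cat_disc["device"] <- n * costs$device_cost
  }
  nonfatal <- integer(n)
  fatal <- logical(n)
  visits_total <- integer(n)
  bleeds_total <- integer(n)
  log <- if (keep_log) vector("list", horizon) else NULL

  for (y in seq_len(horizon)) {
    alive0 <- cohort$alive

    # AF onset (drawn every cycle in fixed order for stream alignment)
    u_onset <- stats::runif(n)
    p_onset <- score_value(params$af_incidence, cohort$score) / 100
    onset <- alive0 & cohort$af_status == "no_af" & u_onset < p_onset
    cohort$af_status[onset] <- "af_undetected"

    # probabilities snapshot after onset, before detection: therapy started
    # this cycle takes effect next cycle
    probs <- transition_probabilities(cohort, arm, params,
                                      check_alive = FALSE)

    scr <- screen_and_detect(cohort, arm, probs)
    cohort <- scr$cohort
    ep <- resolve_endpoint(cohort, probs)
    cohort <- ep$cohort

    on_noac_now <- alive0 & probs$on_noac
    psy <- ep$outcome$post_stroke_year
    comp <- .cycle_cost_components(
      ecg_visits = ifelse(alive0, scr$outcome$ecg_visits, 0L),
      on_noac = on_noac_now,
      post_stroke_year = ifelse(alive0, psy, NA_integer_),
      bleeding = ep$outcome$bleeding & alive0,
      costs = costs
    )
    cyc <- comp$visits + comp$noac + comp$stroke + comp$bleeding
    d <- discount(1, y, rate)
    cost_undisc <- cost_undisc + cyc
    cost_disc <- cost_disc + cyc * d
    cat_disc["visits"] <- cat_disc["visits"] + sum(comp$visits) * d
    cat_disc["noac"] <- cat_disc["noac"] + sum(comp$noac) * d
    cat_disc["stroke"] <- cat_disc["stroke"] + sum(comp$stroke) * d
    cat_disc["bleeding"] <- cat_disc["bleeding"] + sum(comp$bleeding) * d

    st <- ep$outcome$stroke
    nonfatal <- nonfatal + as.integer(st == "nonfatal")
    fatal <- fatal | st == "fatal"
    visits_total <- visits_total + ifelse(alive0, scr$outcome$ecg_visits, 0L)
    bleeds_total <- bleeds_total + as.integer(ep$outcome$bleeding & alive0)

    if (keep_log) {
      keep <- which(alive0)
      log[[y]] <- data.frame(
        id = cohort$id[keep],
        year = rep(y, length(keep)),
        af_onset = onset[keep],
        device_true_alert = scr$outcome$device_true_alert[keep],
        device_false_alert = scr$outcome$device_false_alert[keep],
        confirmed = scr$outcome$confirmed[keep],
        standard_care_detected = scr$outcome$standard_care_detected[keep],
        ecg_visits = scr$outcome$ecg_visits[keep],
        on_noac_this_year = on_noac_now[keep],
        stroke = st[keep],
        other_death = ep$outcome$other_death[keep],
        bleeding = ep$outcome$bleeding[keep],
        post_stroke_year = psy[keep],
        cost_undiscounted = cyc[keep],
        cost_discounted = cyc[keep] * d
      )
    }
  }

  list(
    cohort = cohort,
    patients = data.frame(
      id = cohort$id,
      cost_discounted = cost_disc,
      cost_undiscounted = cost_undisc,
      nonfatal_strokes = nonfatal,
      fatal_stroke = fatal,
      strokes = nonfatal + as.integer(fatal),
      ecg_visits = visits_total,
      bleeds = bleeds_total,
      alive_end = cohort$alive,
      death_cause = cohort$death_cause
    ),
    categories = cat_disc,
    log = if (keep_log) do.call(rbind, log) else NULL
  )
}

#' Simulate one patient's history
#'
#' Runs the annual cycle — AF onset, screening and detection, endpoint
#' resolution — for a single patient until death or the time horizon, and
#' returns the per-cycle event record.
#'
#' @param initial One-row patient data frame ([init_patient()]).
#' @param arm Arm object.
#' @param params,costs Model parameters and costs.
#' @return Data frame with one row per lived cycle: year, screening flags,
#'   ECG visits, therapy status, stroke outcome (`none`/`nonfatal`/`fatal`),
#'   other-cause death, bleeding, post-stroke year and the cycle's
#'   (un)discounted cost. At most `horizon_years` rows; the history stops
#'   with the cycle in which the patient dies.
#' @export
simulate_patient <- function(initial, arm, params, costs = af_costs()) {
  if (!is.data.frame(initial) || nrow(initial) != 1L) {
    stop("initial must be a one-row patient data frame", call. = FALSE)
  }
  if (!initial$alive) stop("initial patient must be alive", call. = FALSE)
  res <- .simulate(initial, arm, params, costs, keep_log = TRUE)
  res$log
}

#' Simulate a full cohort in one arm
#'
#' Generates a synthetic cohort at the given score and pushes it through the
#' full time horizon, pricing every patient-year (discounted) as it goes.
#'
#' Reproducibility: all randomness flows from `seed` through R's default
#' generator. Every cycle draws the same number of uniforms in the same
#' order regardless of arm or patient state, so running two arms with the
#' *same* seed yields common random numbers (useful for variance-reduced
#' comparisons; with device sensitivity and false-positive rate both zero
#' the arms then produce identical histories). The experiment layer instead
#' derives independent seeds per arm, matching independently run
#' simulations.
#'
#' @param score CHA2DS2-VASc score in 1..9.
#' @param arm Arm object.
#' @param params,costs Model parameters and costs.
#' @param n Cohort size (default from `params$cohort_size`).
#' @param seed Integer seed, or `NULL` to continue the current stream.
#' @param keep_log Keep the long per-patient event log (memory-heavy for
#'   large cohorts).
#' @param exact_sex_split Passed to [generate_cohort()].
#' @return An object of class `"af_cohort_result"`: a list with `score`,
#'   `arm`, `n`, `seed`, per-patient results (`patients`), discounted cost
#'   totals by category (`categories`), aggregate event `counts`, the final
#'   `cohort` states and optionally `log`.
#' @export
simulate_cohort <- function(score, arm, params, costs = af_costs(),
                            n = params$cohort_size, seed = NULL,
                            keep_log = FALSE, exact_sex_split = FALSE) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  validate_costs(costs, horizon_years = params$horizon_years)
  if (!is.null(seed)) set.seed(seed)
  cohort <- generate_cohort(score, n, params, seed = NULL,
                            exact_sex_split = exact_sex_split)
  res <- .simulate(cohort, arm, params, costs, keep_log = keep_log)
  pt <- res$patients
  structure(list(
    score = as.integer(score),
    arm = arm,
    n = as.integer(n),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    horizon_years = params$horizon_years,
    patients = pt,
    categories = res$categories,
    counts = list(
      total_strokes = sum(pt$strokes),
      nonfatal_strokes = sum(pt$nonfatal_strokes),
      fatal_strokes = sum(pt$fatal_stroke),
      other_deaths = sum(pt$death_cause == "other"),
      ecg_visits = sum(pt$ecg_visits),
      bleeds = sum(pt$bleeds)
    ),
    cohort = res$cohort,
    log = res$log
  ), class = "af_cohort_result")
}

#' @export
print.af_cohort_result <- function(x, ...) {
  lab <- if (x$arm$label == "device") {
    sprintf("device (ECG confirmation %.0f%%)", 100 * x$arm$ecg_confirmation)
  } else "no device"
  cat(sprintf("Cohort result: score %d, %s, n = %d\n", x$score, lab, x$n))
  cat(sprintf("  average discounted cost/patient: EUR %.2f\n",
              mean(x$patients$cost_discounted)))
  cat(sprintf("  strokes: %d total (%d nonfatal, %d fatal)\n",
              x$counts$total_strokes, x$counts$nonfatal_strokes,
              x$counts$fatal_strokes))
  invisible(x)
}
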