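test_that("transition probabilities key stroke risk and mortality to status", {
  p <- base_params()
  pr <- transition_probabilities(patient_row(9, af_status = "af_undetected"),
                                 no_device_arm(), p)
  expect_equal(pr$p_stroke, 0.1444)
  expect_equal(pr$p_stroke_fatal, 0.63)
  expect_equal(pr$p_other_death, 0.111)
  expect_equal(pr$p_standard_detect, p$standard_care_detection)
  expect_equal(pr$p_true_alert, 0)   # no device in this arm

  pr <- transition_probabilities(patient_row(1, af_status = "af_detected_treated"),
                                 device_arm(0.75), p)
  expect_equal(pr$p_stroke, 0.00204)
  expect_equal(pr$p_stroke_fatal, 0.42)
  expect_equal(pr$p_bleed, p$bleed_prob_on_noac)
  expect_equal(pr$p_true_alert, 0)   # already detected: screening is over
  expect_equal(pr$p_standard_detect, 0)

  pr <- transition_probabilities(patient_row(0, af_status = "no_af"),
                                 device_arm(1), p)
  expect_equal(pr$p_stroke, 0.2 / 2.42 / 100)
  expect_equal(round(pr$p_stroke, 6), 0.000826)
  expect_equal(pr$p_other_death, 0.06)
  expect_equal(pr$p_false_alert, 0.002)
  expect_equal(pr$p_stroke_fatal, 0.34)

  # detected-but-untreated (female, score 1) carries untreated AF risks
  pr <- transition_probabilities(
    patient_row(1, sex = "female", af_status = "af_detected_untreated"),
    device_arm(1), p)
  expect_equal(pr$p_stroke, 0.6 / 100)
  expect_equal(pr$p_stroke_fatal, 0.63)
  expect_equal(pr$p_bleed, 0)

  expect_error(transition_probabilities(patient_row(5, alive = FALSE),
                                        no_device_arm(), p), "dead")
})

test_that("a certain alert with certain confirmation detects AF in one cycle", {
  p <- af_parameters(device_sensitivity = 1, standard_care_detection = 0)
  cohort <- patient_block(50, score = 5, af_status = "af_undetected")
  probs <- transition_probabilities(cohort, device_arm(1), p)
  set.seed(1)
  out <- screen_and_detect(cohort, device_arm(1), probs)
  expect_true(all(out$cohort$af_status == "af_detected_treated"))
  expect_true(all(out$outcome$ecg_visits == 1L))
  expect_true(all(out$outcome$confirmed))

  # female at score 1: diagnosed but treatment-ineligible
  cohort1 <- patient_block(50, score = 1, sex = "female",
                           af_status = "af_undetected")
  probs1 <- transition_probabilities(cohort1, device_arm(1), p)
  out1 <- screen_and_detect(cohort1, device_arm(1), probs1)
  expect_true(all(out1$cohort$af_status == "af_detected_untreated"))
})

test_that("with no alerts and no standard care nothing is detected and no visits accrue", {
  p <- af_parameters(device_sensitivity = 0, device_false_positive = 0,
                     standard_care_detection = 0)
  cohort <- patient_block(100, score = 5, af_status = "af_undetected")
  probs <- transition_probabilities(cohort, device_arm(1), p)
  set.seed(2)
  out <- screen_and_detect(cohort, device_arm(1), probs)
  expect_identical(out$cohort, cohort)
  expect_true(all(out$outcome$ecg_visits == 0L))
})

test_that("per-cycle detection probability matches its closed-form composition", {
  # device path or, failing that, standard care:
  # 0.93 * 0.75 + (1 - 0.93 * 0.75) * 0.3609 = 0.8067
  p <- base_params()
  n <- 200000L
  cohort <- patient_block(n, score = 5, af_status = "af_undetected")
  probs <- transition_probabilities(cohort, device_arm(0.75), p)
  set.seed(3)
  out <- screen_and_detect(cohort, device_arm(0.75), probs)
  detected <- mean(out$cohort$af_status != "af_undetected")
  p_closed <- 0.93 * 0.75 + (1 - 0.93 * 0.75) * p$standard_care_detection
  expect_equal(round(p_closed, 4), 0.8067, tolerance = 1e-4)
  se <- sqrt(p_closed * (1 - p_closed) / n)
  expect_lt(abs(detected - p_closed), 4 * se)
})

test_that("endpoints: no incidence means no strokes; certain fatal stroke kills in year 1", {
  p0 <- af_parameters(stroke_incidence_untreated = rep(0, 10))
  cohort <- patient_block(500, score = 7, af_status = "af_undetected")
  probs <- transition_probabilities(cohort, no_device_arm(), p0)
  set.seed(4)
  out <- resolve_endpoint(cohort, probs)
  expect_true(all(out$outcome$stroke == "none"))
  expect_true(all(out$cohort$stroke_count == 0L))

  p1 <- af_parameters(stroke_incidence_untreated = rep(99, 10),
                      stroke_mortality_untreated = 1)
  probs1 <- transition_probabilities(cohort, no_device_arm(), p1)
  probs1$p_stroke <- 1  # force the stroke draw to certainty
  out1 <- resolve_endpoint(cohort, probs1)
  expect_true(all(out1$outcome$stroke == "fatal"))
  expect_true(all(!out1$cohort$alive))
  expect_true(all(out1$cohort$death_cause == "stroke"))
})

test_that("one-year stroke and fatality counts in an untreated score-9 cohort match binomial expectations", {
  p <- af_parameters(prevalence = rep(1, 10), standard_care_detection = 0,
                     horizon_years = 1L)
  co <- af_costs(horizon_years = 1L,
                 stroke_cost_schedule = 15753)
  n <- 30000L
  r <- simulate_cohort(9, no_device_arm(), p, co, n = n, seed = 55)
  p_stroke <- 0.1444
  exp_strokes <- n * p_stroke
  se_strokes <- sqrt(n * p_stroke * (1 - p_stroke))
  expect_lt(abs(r$counts$total_strokes - exp_strokes), 4 * se_strokes)
  exp_fatal <- exp_strokes * 0.63
  se_fatal <- sqrt(n * p_stroke * 0.63 * (1 - p_stroke * 0.63))
  expect_lt(abs(r$counts$fatal_strokes - exp_fatal), 4 * se_fatal)
})

test_that("nonfatal stroke in undetected AF triggers diagnosis; death is absorbing", {
  p <- af_parameters(prevalence = rep(1, 10),
                     stroke_incidence_untreated = rep(99, 10),
                     stroke_mortality_untreated = 0,
                     standard_care_detection = 0, device_sensitivity = 0)
  cohort <- patient_block(200, score = 6, af_status = "af_undetected")
  probs <- transition_probabilities(cohort, no_device_arm(), p)
  probs$p_stroke <- 1
  set.seed(6)
  out <- resolve_endpoint(cohort, probs)
  expect_true(all(out$cohort$af_status == "af_detected_treated"))
  expect_true(all(out$cohort$years_since_last_stroke == 1L))
  expect_true(all(out$cohort$alive))
})

test_that("a patient history is at most the horizon, stops at death, and is seed-stable", {
  p0 <- null_params()
  pt <- patient_row(5, af_status = "no_af")
  set.seed(10)
  h <- simulate_patient(pt, no_device_arm(), p0)
  expect_equal(nrow(h), 10L)
  expect_true(all(h$stroke == "none"))
  expect_true(all(h$cost_undiscounted == 0))

  pdie <- null_params()
  pdie$other_mortality_no_af <- 1
  set.seed(10)
  h1 <- simulate_patient(pt, no_device_arm(), pdie)
  expect_equal(nrow(h1), 1L)
  expect_true(h1$other_death)

  set.seed(123)
  a <- simulate_patient(patient_row(7), device_arm(0.75), base_params())
  set.seed(123)
  b <- simulate_patient(patient_row(7), device_arm(0.75), base_params())
  expect_identical(a, b)
})

test_that("AF knowledge is monotone and the dead accrue nothing", {
  p <- base_params()
  r <- simulate_cohort(8, device_arm(0.75), p, base_costs(), n = 2000L,
                       seed = 77, keep_log = TRUE)
  log <- r$log
  # log rows exist only for cycles begun alive; after a death year there
  # must be no further rows and no further cost for that patient
  for (pid in sample(unique(log$id), 200)) {
    rows <- log[log$id == pid, ]
    expect_true(all(diff(rows$year) == 1))
    died <- rows$stroke == "fatal" | rows$other_death
    if (any(died)) expect_equal(which(died), nrow(rows))
  }
  # monotone AF knowledge: onset and detection each happen at most once per
  # patient, and never in reverse order
  detect <- log$confirmed | log$standard_care_detected
  expect_true(all(tapply(detect, log$id, sum) <= 1L))
  expect_true(all(tapply(log$af_onset, log$id, sum) <= 1L))
  both <- tapply(seq_len(nrow(log)), log$id, function(i) {
    on <- log$year[i][log$af_onset[i]]
    de <- log$year[i][detect[i]]
    length(de) == 0L || length(on) == 0L || on <= de
  })
  expect_true(all(both))
  # conservation inside the aggregate
  expect_equal(r$counts$total_strokes,
               r$counts$nonfatal_strokes + r$counts$fatal_strokes)
})

test_that("device and no-device arms are identical under a degenerate device with shared seed", {
  p <- af_parameters(device_sensitivity = 0, device_false_positive = 0)
  co <- base_costs()
  a <- simulate_cohort(6, no_device_arm(), p, co, n = 5000L, seed = 99)
  b <- simulate_cohort(6, device_arm(0.75), p, co, n = 5000L, seed = 99)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$counts, b$counts)
  expect_equal(b$patients$cost_discounted - a$patients$cost_discounted,
               rep(co$device_cost, 5000L))
})

test_that("screening with a device reduces strokes at high scores", {
  p <- base_params()
  co <- base_costs()
  # common random numbers isolate the treatment effect from cohort noise
  for (seed in 1:5) {
    for (score in c(4L, 9L)) {
      s <- derive_seed(seed, score, "crn")
      ref <- simulate_cohort(score, no_device_arm(), p, co, n = 30000L,
                             seed = s)
      dev <- simulate_cohort(score, device_arm(1.0), p, co, n = 30000L,
                             seed = s)
      expect_lt(dev$counts$total_strokes, ref$counts$total_strokes)
    }
  }
  # and the effect at score 9 dominates even independent-cohort noise
  for (seed in 1:3) {
    ref <- simulate_cohort(9, no_device_arm(), p, co, n = 30000L,
                           seed = derive_seed(seed, 9, "no_device"))
    dev <- simulate_cohort(9, device_arm(1.0), p, co, n = 30000L,
                           seed = derive_seed(seed, 9, "device", 1))
    expect_lt(dev$counts$total_strokes, ref$counts$total_strokes)
  }
})

test_that("cohort simulations are reproducible by seed", {
  p <- base_params()
  a <- simulate_cohort(3, device_arm(0.5), p, base_costs(), n = 3000L,
                       seed = 314)
  b <- simulate_cohort(3, device_arm(0.5), p, base_costs(), n = 3000L,
                       seed = 314)
  expect_identical(a$patients, b$patients)
  expect_identical(a$categories, b$categories)
})

test_that("an all-zero model yields an all-zero no-device summary", {
  p0 <- null_params()
  co0 <- af_costs(device_cost = 0, visit_components = 0,
                  noac_annual_cost = 0, bleeding_cost = 0,
                  stroke_cost_schedule = rep(1, 10))
  r <- simulate_cohort(5, no_device_arm(), p0, co0, n = 500L, seed = 8)
  s <- summarize_cohort(r)
  expect_equal(s$avg_cost, 0)
  expect_equal(s$total_strokes, 0)
  expect_true(all(r$patients$cost_undiscounted == 0))
})

test_that("one-cycle mean cost matches the closed-form event-tree expectation", {
  # single-status cohort, 1-year horizon: every patient starts with
  # detected/treated AF, so the only costs are NOAC (certain), the year-1
  # stroke cost (probability p_s) and bleeding (probability p_b):
  # E[cost] = noac + p_s * stroke_year1 + p_b * bleed
  p <- af_parameters(prevalence = rep(1, 10), horizon_years = 1L,
                     standard_care_detection = 0)
  co <- af_costs(horizon_years = 1L, stroke_cost_schedule = 15753)
  n <- 30000L
  cohort <- patient_block(n, score = 7, af_status = "af_detected_treated")
  set.seed(202)
  res <- afscreen:::.simulate(cohort, no_device_arm(), p, co)
  p_s <- 4.454 / 100  # anticoagulated stroke incidence at score 7
  p_b <- p$bleed_prob_on_noac
  expected <- co$noac_annual_cost + p_s * 15753 + p_b * co$bleeding_cost
  sd_one <- sqrt(p_s * (1 - p_s) * 15753^2 + p_b * (1 - p_b) * 1995^2)
  expect_lt(abs(mean(res$patients$cost_discounted) - expected),
            3 * sd_one / sqrt(n))
})
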