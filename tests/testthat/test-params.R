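untreated <- c(0.2, 0.6, 2.5, 3.7, 5.5, 8.4, 11.4, 13.1, 12.6, 14.44)

test_that("no-AF stroke incidence is the untreated incidence over the relative risk", {
  expect_equal(round(as.numeric(derive_no_af_incidence(untreated, 2.42)), 4),
               c(0.0826, 0.2479, 1.0331, 1.5289, 2.2727, 3.4711, 4.7107,
                 5.4132, 5.2066, 5.9669))
  v <- score_vector(untreated, "rate")
  expect_equal(as.numeric(derive_no_af_incidence(v, 1.0)), untreated)
  expect_equal(as.numeric(derive_no_af_incidence(
    score_vector(c(2.42, rep(0, 9)), "rate"), 2.42)), c(1, rep(0, 9)))
  expect_error(derive_no_af_incidence(v, 0), "positive")
  expect_error(derive_no_af_incidence(v, -1), "positive")
})

test_that("anticoagulated stroke incidence applies the fractional risk reduction", {
  expect_equal(as.numeric(derive_noac_incidence(untreated, 0.66)),
               c(0.068, 0.204, 0.85, 1.258, 1.87, 2.856, 3.876, 4.454,
                 4.284, 4.9096))
  expect_equal(as.numeric(derive_noac_incidence(untreated, 0)), untreated)
  expect_equal(as.numeric(derive_noac_incidence(rep(10, 10), 1.0)),
               rep(0, 10))
  expect_error(derive_noac_incidence(untreated, 1.2), "\\[0, 1\\]")
  expect_error(derive_noac_incidence(untreated, -0.1), "\\[0, 1\\]")
})

test_that("risk-reduction derivation round-trips to machine precision", {
  set.seed(7)
  for (r in c(0.1, 0.33, 0.66, 0.9)) {
    v <- runif(10, 0, 20)
    reduced <- derive_noac_incidence(v, r)
    expect_equal(as.numeric(reduced) / (1 - r), v, tolerance = 1e-12)
  }
})

test_that("standard-care detection scales device sensitivity by the monitoring ratio", {
  expect_equal(round(derive_standard_care_detection(0.93, 2.6, 6.7), 4),
               0.3609)
  expect_equal(derive_standard_care_detection(1.0, 5, 5), 1.0)
  expect_equal(derive_standard_care_detection(0.5, 1, 4), 0.125)
  expect_error(derive_standard_care_detection(0.93, 2.6, 0), "positive")
})

test_that("visit cost is the exact sum of its fee-schedule items", {
  expect_equal(sum_visit_cost(c(13.20, 12.90, 9.52, 9.96, 21.65)), 67.23)
  expect_equal(sum_visit_cost(c(35.62, 31.61)), 67.23)
  expect_equal(sum_visit_cost(numeric(0)), 0)
  expect_error(sum_visit_cost(c(10, -1)), "negative")
})

test_that("stroke-cost schedule hits anchors exactly and interpolates geometrically", {
  anchors <- data.frame(year = c(1L, 2L, 10L), cost = c(15753, 4480, 1481))
  s <- build_stroke_cost_schedule(anchors, 10L)
  expect_length(s, 10L)
  expect_identical(s[c(1, 2, 10)], c(15753, 4480, 1481))
  # closed-form geometric interpolation, evaluated independently
  expect_equal(s[5], 4480 * (1481 / 4480)^(3 / 8), tolerance = 1e-10)
  for (k in 3:9) {
    expect_equal(s[k], 4480 * (1481 / 4480)^((k - 2) / 8), tolerance = 1e-10)
  }
  expect_false(is.unsorted(rev(s)))
})

test_that("stroke-cost schedule handles degenerate anchor sets", {
  expect_equal(build_stroke_cost_schedule(data.frame(year = 1, cost = 500), 10L),
               rep(500, 10))
  # tail extrapolation continues the last segment's decay
  s <- build_stroke_cost_schedule(data.frame(year = c(1, 5), cost = c(16, 1)), 10L)
  expect_equal(s[1:5], 16 * (1 / 16)^((0:4) / 4), tolerance = 1e-10)
  expect_equal(s[6:10], (1 / 2)^(1:5), tolerance = 1e-10)
  expect_error(build_stroke_cost_schedule(
    data.frame(year = c(1, 1), cost = c(2, 3)), 10L), "duplicate")
  expect_error(build_stroke_cost_schedule(
    data.frame(year = 11, cost = 5), 10L), "within")
  expect_error(build_stroke_cost_schedule(
    data.frame(year = 1, cost = -5), 10L), "positive")
})

test_that("base-case parameters and costs validate", {
  expect_silent(validate_parameters(af_parameters()))
  expect_silent(validate_costs(af_costs(), horizon_years = 10L))
})

test_that("each single-field corruption fails validation naming the field", {
  corrupt <- list(
    device_sensitivity = 1.3,
    device_false_positive = -0.1,
    ecg_confirmation = 2,
    standard_care_detection = -1,
    stroke_mortality_untreated = 1.5,
    other_mortality_no_af = -0.2,
    bleed_prob_on_noac = 7,
    discount_rate = -0.03,
    horizon_years = 0,
    cohort_size = 0
  )
  for (nm in names(corrupt)) {
    p <- af_parameters()
    p[[nm]] <- corrupt[[nm]]
    expect_error(validate_parameters(p), nm, fixed = TRUE)
  }
  # derived vectors must never exceed the untreated incidence
  p <- af_parameters()
  p$stroke_incidence_noac <- score_vector(rep(50, 10), "rate")
  expect_error(validate_parameters(p), "stroke_incidence_noac")
  co <- af_costs()
  co$stroke_cost_schedule[3] <- -1
  expect_error(validate_costs(co), "stroke_cost_schedule")
  co <- af_costs()
  co$stroke_cost_schedule <- rev(co$stroke_cost_schedule)
  expect_error(validate_costs(co), "non-increasing")
})

test_that("score vectors enforce length, sign and range", {
  expect_error(score_vector(1:5), "10 entries")
  expect_error(score_vector(c(-1, rep(0, 9))), "negative")
  expect_error(score_vector(c(150, rep(0, 9)), "rate"), "< 100")
  expect_error(score_vector(c(1.5, rep(0, 9)), "proportion"), "\\[0, 1\\]")
  expect_error(score_value(score_vector(rep(0, 10)), 10), "0..9")
})

test_that("configuration round-trips through YAML and rebuilds the model", {
  cfg <- default_af_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_af_config(cfg, path)
  cfg2 <- read_af_config(path)
  expect_equal(cfg2$params$stroke_incidence_untreated, untreated)
  m <- af_model_from_config(cfg2)
  expect_s3_class(m$params, "af_parameters")
  expect_equal(m$costs$visit_and_diagnostics_cost, 67.23)
  expect_equal(m$params$standard_care_detection,
               af_parameters()$standard_care_detection)
  # partial configs fall back to defaults
  writeLines("params:\n  device_sensitivity: 0.86", path)
  m2 <- af_model_from_config(read_af_config(path))
  expect_equal(m2$params$device_sensitivity, 0.86)
  expect_equal(m2$params$device_false_positive, 0.002)
})
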