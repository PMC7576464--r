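#' Derive an independent sub-seed for one cohort
#'
#' The experiment grid gives every (score, arm, grid value) cohort its own
#' reproducible random stream, derived deterministically from the base seed
#' by a simple integer hash. Arms are independent by default, matching
#' independently run simulations; pass the *same* seed directly to
#' [simulate_cohort()] for common-random-numbers comparisons instead.
#'
#' @param base_seed Integer base seed.
#' @param score Integer score.
#' @param arm_label Arm label string (e.g. `"no_device"`, `"device"`).
#' @param grid_value Numeric scenario tag (ECG confirmation, sensitivity or
#'   false-positive grid value); default 0.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(base_seed, score, arm_label, grid_value = 0) {
  m <- 2147483647  # 2^31 - 1, keeps everything in exact double arithmetic
  h <- as.numeric(base_seed) %% m
  mix <- function(h, x) ((h * 69069) %% m + as.numeric(x)) %% m
  h <- mix(h, score * 2654435)
  for (ch in utf8ToInt(arm_label)) h <- mix(h, ch)
  h <- mix(h, round(grid_value * 1e6))
  as.integer(h %% (m - 1)) + 1L
}

#' Define the experimental grid
#'
#' The full study design: scores 1..9, one no-device arm plus device arms at
#' ECG confirmation 100/75/50%, 30,000 patients per cohort, and one-way
#' sensitivity grids over device sensitivity and false-positive rate run at
#' 75% confirmation.
#'
#' @param scores Subset of 1..9.
#' @param confirmations Device-arm ECG confirmation rates.
#' @param n Patients per cohort.
#' @param base_seed Base seed for [derive_seed()].
#' @param sensitivity_values Device-sensitivity grid.
#' @param false_positive_values False-positive-rate grid.
#' @param sensitivity_confirmation ECG confirmation used in the sensitivity
#'   grids.
#' @return An object of class `"af_experiment_plan"`.
#' @export
experiment_plan <- function(scores = 1:9,
                            confirmations = c(1.0, 0.75, 0.5),
                            n = 30000L,
                            base_seed = 20201006,
                            sensitivity_values = c(0.86, 0.93, 1.00),
                            false_positive_values = c(0.002, 0.01, 0.05),
                            sensitivity_confirmation = 0.75) {
  if (length(scores) == 0L || any(scores < 1 | scores > 9)) {
    stop("scores must be a non-empty subset of 1..9", call. = FALSE)
  }
  if (length(confirmations) == 0L ||
      any(confirmations < 0 | confirmations > 1)) {
    stop("confirmations must be non-empty probabilities", call. = FALSE)
  }
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  for (nm in c("sensitivity_values", "false_positive_values")) {
    v <- get(nm)
    if (length(v) == 0L || any(v < 0 | v > 1)) {
      stop(nm, " must be non-empty probabilities", call. = FALSE)
    }
  }
  structure(list(scores = as.integer(scores),
                 confirmations = confirmations,
                 n = as.integer(n),
                 base_seed = base_seed,
                 sensitivity_values = sensitivity_values,
                 false_positive_values = false_positive_values,
                 sensitivity_confirmation = sensitivity_confirmation),
            class = "af_experiment_plan")
}

#' Run the baseline experimental grid
#'
#' Simulates, for every score in the plan, the no-device arm and one device
#' arm per ECG confirmation rate, then compares each device arm against the
#' no-device reference. A `"mean"` row per arm averages over scores, as in
#' the summary tables.
#'
#' @param plan An [experiment_plan()].
#' @param params,costs Model parameters and costs.
#' @param verbose Print one progress line per cohort.
#' @return List of class `"af_baseline_result"` with data frames
#'   `summaries` (one row per cohort plus mean rows) and `comparisons` (one
#'   row per score x confirmation).
#' @export
run_baseline_grid <- function(plan, params, costs = af_costs(),
                              verbose = FALSE) {
  stopifnot(inherits(plan, "af_experiment_plan"))
  summaries <- list()
  comparisons <- list()
  for (score in plan$scores) {
    t0 <- proc.time()[["elapsed"]]
    seed_ref <- derive_seed(plan$base_seed, score, "no_device")
    ref <- summarize_cohort(simulate_cohort(score, no_device_arm(), params,
                                            costs, n = plan$n,
                                            seed = seed_ref))
    summaries[[length(summaries) + 1L]] <- ref
    if (verbose) {
      message(sprintf("score %d no_device seed %d n %d: %.1fs, avg cost %.0f",
                      score, seed_ref, plan$n,
                      proc.time()[["elapsed"]] - t0, ref$avg_cost))
    }
    for (conf in plan$confirmations) {
      t0 <- proc.time()[["elapsed"]]
      seed_dev <- derive_seed(plan$base_seed, score, "device", conf)
      dev <- summarize_cohort(simulate_cohort(score, device_arm(conf),
                                              params, costs, n = plan$n,
                                              seed = seed_dev))
      summaries[[length(summaries) + 1L]] <- dev
      comparisons[[length(comparisons) + 1L]] <- compare_arms(ref, dev)
      if (verbose) {
        message(sprintf(
          "score %d device(conf %.2f) seed %d n %d: %.1fs, avg cost %.0f",
          score, conf, seed_dev, plan$n,
          proc.time()[["elapsed"]] - t0, dev$avg_cost))
      }
    }
  }
  summaries <- do.call(rbind, summaries)
  comparisons <- do.call(rbind, comparisons)
  structure(list(summaries = .add_mean_rows(summaries),
                 comparisons = comparisons,
                 plan = plan),
            class = "af_baseline_result")
}

# per-arm mean row over scores (the tables' "mean" line)
.add_mean_rows <- function(summaries) {
  key <- paste(summaries$arm, summaries$ecg_confirmation)
  means <- lapply(split(summaries, key), function(g) {
    data.frame(score = NA_integer_, arm = g$arm[1],
               ecg_confirmation = g$ecg_confirmation[1], n = g$n[1],
               avg_cost = mean(g$avg_cost),
               total_strokes = mean(g$total_strokes),
               nonfatal_strokes = mean(g$nonfatal_strokes),
               fatal_strokes = mean(g$fatal_strokes))
  })
  out <- rbind(summaries, do.call(rbind, means))
  rownames(out) <- NULL
  out
}

#' Run a one-way sensitivity grid
#'
#' Re-simulates every score's device arm while varying a single device
#' parameter over its grid, with ECG confirmation fixed (75% in the base
#' design). `parameter = "sensitivity"` varies the device sensitivity;
#' `"false_positive"` varies the false-positive detection rate.
#'
#' @param plan An [experiment_plan()].
#' @param params,costs Model parameters and costs.
#' @param parameter Which device parameter to vary.
#' @param verbose Print one progress line per cohort.
#' @return Data frame of class `"af_sensitivity_result"`: one
#'   [summarize_cohort()] row per (score, grid value), with the varied value
#'   in column `grid_value` and its name in `grid_parameter`.
#' @export
run_sensitivity_grid <- function(plan, params, costs = af_costs(),
                                 parameter = c("sensitivity",
                                               "false_positive"),
                                 verbose = FALSE) {
  stopifnot(inherits(plan, "af_experiment_plan"))
  parameter <- match.arg(parameter)
  values <- if (parameter == "sensitivity") plan$sensitivity_values
            else plan$false_positive_values
  arm <- device_arm(plan$sensitivity_confirmation)
  rows <- list()
  for (score in plan$scores) {
    for (v in values) {
      p <- params
      if (parameter == "sensitivity") {
        p$device_sensitivity <- v
      } else {
        p$device_false_positive <- v
      }
      validate_parameters(p)
      seed <- derive_seed(plan$base_seed, score,
                          paste0("device_", parameter), v)
      s <- summarize_cohort(simulate_cohort(score, arm, p, costs,
                                            n = plan$n, seed = seed))
      s$grid_parameter <- parameter
      s$grid_value <- v
      rows[[length(rows) + 1L]] <- s
      if (verbose) {
        message(sprintf("score %d %s=%g seed %d: avg cost %.0f",
                        score, parameter, v, seed, s$avg_cost))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("af_sensitivity_result", class(out))
  out
}

.round_eur <- function(df, cols) {
  for (cl in cols) df[[cl]] <- round(df[[cl]])
  df
}

#' Write the report tables as CSV files
#'
#' Writes the five result tables in the published layout — per-score cohort
#' summaries for the no-device and 50%-confirmation arms (`table3.csv`), the
#' 75% and 100% arms (`table4.csv`), the arm comparisons (`table5.csv`), and
#' the sensitivity grids over device sensitivity (`table6.csv`) and
#' false-positive rate (`table7.csv`) — plus full-precision machine-readable
#' variants (`*_full.csv`) and a `run_metadata.json` echoing plan and
#' package version. Euro columns in the display tables are rounded to whole
#' euros.
#'
#' @param baseline An `"af_baseline_result"` from [run_baseline_grid()].
#' @param sensitivity Optional sensitivity-grid result
#'   (`parameter = "sensitivity"`).
#' @param false_positive Optional false-positive-grid result.
#' @param dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_report_tables <- function(baseline, sensitivity = NULL,
                                false_positive = NULL, dir = ".") {
  stopifnot(inherits(baseline, "af_baseline_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  wr <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    files <<- c(files, path)
  }

  s <- baseline$summaries
  pick <- function(arm, conf) {
    g <- if (arm == "no_device") s[s$arm == "no_device", ]
         else s[s$arm == "device" & s$ecg_confirmation == conf, ]
    g <- g[order(is.na(g$score), g$score), ]
    g$score_label <- ifelse(is.na(g$score), "mean", as.character(g$score))
    g[, c("score_label", "avg_cost", "total_strokes", "nonfatal_strokes",
          "fatal_strokes")]
  }
  side_by_side <- function(a, b, la, lb) {
    names(a)[-1] <- paste0(la, "_", names(a)[-1])
    names(b)[-1] <- paste0(lb, "_", names(b)[-1])
    cbind(a, b[-1])
  }
  t3 <- side_by_side(pick("no_device", NA), pick("device", 0.5),
                     "no_device", "device_conf50")
  t4 <- side_by_side(pick("device", 0.75), pick("device", 1.0),
                     "device_conf75", "device_conf100")
  wr(t3, "table3_full.csv")
  wr(t4, "table4_full.csv")
  wr(.round_eur(t3, grep("avg_cost", names(t3), value = TRUE)), "table3.csv")
  wr(.round_eur(t4, grep("avg_cost", names(t4), value = TRUE)), "table4.csv")

  cmp <- baseline$comparisons
  cmp <- cmp[order(-cmp$ecg_confirmation, cmp$score),
             c("ecg_confirmation", "score", "cost_difference",
               "prevented_strokes", "cost_per_prevented_stroke",
               "prevented_fatal_strokes", "cost_per_prevented_fatal_stroke")]
  wr(cmp, "table5_full.csv")
  wr(.round_eur(cmp, c("cost_difference", "cost_per_prevented_stroke",
                       "cost_per_prevented_fatal_stroke")), "table5.csv")

  grid_table <- function(g) {
    g <- g[order(g$grid_value, g$score),
           c("grid_parameter", "grid_value", "score", "avg_cost",
             "total_strokes", "fatal_strokes")]
    g
  }
  if (!is.null(sensitivity)) {
    t6 <- grid_table(sensitivity)
    wr(t6, "table6_full.csv")
    wr(.round_eur(t6, "avg_cost"), "table6.csv")
  }
  if (!is.null(false_positive)) {
    t7 <- grid_table(false_positive)
    wr(t7, "table7_full.csv")
    wr(.round_eur(t7, "avg_cost"), "table7.csv")
  }

  meta <- list(
    package = "afscreen",
    version = as.character(utils::packageVersion("afscreen")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    plan = unclass(baseline$plan)
  )
  mp <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files <- c(files, mp)
  invisible(files)
}

#' @export
print.af_baseline_result <- function(x, ...) {
  cat(sprintf("Baseline grid: %d cohort summaries, %d arm comparisons\n",
              sum(!is.na(x$summaries$score)), nrow(x$comparisons)))
  print(utils::head(x$comparisons, 10))
  invisible(x)
}
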