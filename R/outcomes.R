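#' Summarise a cohort simulation
#'
#' Reduces a cohort result to the row reported per (score, arm): average
#' discounted cost per patient over the whole simulation and the stroke
#' counts, with total strokes always equal to nonfatal plus fatal.
#'
#' @param result An `"af_cohort_result"` from [simulate_cohort()].
#' @return One-row data frame with columns `score`, `arm`,
#'   `ecg_confirmation`, `n`, `avg_cost`, `total_strokes`,
#'   `nonfatal_strokes`, `fatal_strokes`.
#' @export
summarize_cohort <- function(result) {
  if (!inherits(result, "af_cohort_result") || result$n < 1) {
    stop("result must be a non-empty cohort result", call. = FALSE)
  }
  data.frame(
    score = result$score,
    arm = result$arm$label,
    ecg_confirmation = result$arm$ecg_confirmation,
    n = result$n,
    avg_cost = mean(result$patients$cost_discounted),
    total_strokes = result$counts$total_strokes,
    nonfatal_strokes = result$counts$nonfatal_strokes,
    fatal_strokes = result$counts$fatal_strokes
  )
}

#' Cost per prevented event
#'
#' The headline economic ratio: the between-arm cost difference summed over
#' all patients, divided by the number of prevented events. Signed — a
#' negative prevented count yields a negative ratio. Undefined (reported as
#' `NA`) when no events were prevented.
#'
#' @param cost_difference Total euro cost difference, device minus
#'   no-device, over all patients.
#' @param prevented Prevented events (no-device count minus device count);
#'   may be negative.
#' @return Signed euros per prevented event, or `NA` if `prevented` is zero.
#' @export
cost_per_prevented <- function(cost_difference, prevented) {
  ifelse(prevented == 0, NA_real_, cost_difference / prevented)
}

#' Compare a device arm against the no-device reference
#'
#' Computes the incremental outcomes for one score: total cost difference
#' (per-patient average difference times n, i.e. the difference of the cost
#' sums over all patients), prevented (fatal) strokes as raw signed
#' differences, and the signed cost per prevented (fatal) stroke.
#'
#' @param reference Summary row of the no-device cohort
#'   ([summarize_cohort()]).
#' @param intervention Summary row of a device cohort at the same score and
#'   n.
#' @return One-row data frame with columns `score`, `ecg_confirmation`,
#'   `cost_difference`, `prevented_strokes`, `cost_per_prevented_stroke`,
#'   `prevented_fatal_strokes`, `cost_per_prevented_fatal_stroke`.
#' @export
compare_arms <- function(reference, intervention) {
  if (reference$score != intervention$score) {
    stop("arms must share the same score", call. = FALSE)
  }
  if (reference$n != intervention$n) {
    stop("arms must share the same cohort size", call. = FALSE)
  }
  cost_diff <- (intervention$avg_cost - reference$avg_cost) * reference$n
  prevented <- reference$total_strokes - intervention$total_strokes
  prevented_fatal <- reference$fatal_strokes - intervention$fatal_strokes
  data.frame(
    score = reference$score,
    ecg_confirmation = intervention$ecg_confirmation,
    cost_difference = cost_diff,
    prevented_strokes = prevented,
    cost_per_prevented_stroke = cost_per_prevented(cost_diff, prevented),
    prevented_fatal_strokes = prevented_fatal,
    cost_per_prevented_fatal_stroke = cost_per_prevented(cost_diff,
                                                         prevented_fatal)
  )
}
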