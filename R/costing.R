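# Vectorised euro components of one patient-year. post_stroke_year indexes
# the schedule (NA = never had a stroke); fatal strokes carry year 1.
.cycle_cost_components <- function(ecg_visits, on_noac, post_stroke_year,
                                   bleeding, costs) {
  sched <- costs$stroke_cost_schedule
  horizon <- length(sched)
  psy <- post_stroke_year
  if (any(!is.na(psy) & psy > horizon)) {
    stop("post_stroke_year exceeds the stroke-cost schedule horizon",
         call. = FALSE)
  }
  stroke <- numeric(length(psy))
  idx <- which(!is.na(psy))
  stroke[idx] <- sched[psy[idx]]
  list(
    visits = as.numeric(ecg_visits) * costs$visit_and_diagnostics_cost,
    noac = as.numeric(on_noac) * costs$noac_annual_cost,
    stroke = stroke,
    bleeding = as.numeric(bleeding) * costs$bleeding_cost
  )
}

#' Undiscounted cost of one patient-year
#'
#' Sums the euro amounts a cycle's events trigger: one visit-and-diagnostics
#' fee per ECG visit, the annual NOAC cost while on therapy, the post-stroke
#' schedule cost for the current post-stroke year (a fatal stroke carries
#' the year-1 amount once), and the major-bleeding cost per bleeding event.
#' Event-free untreated years cost nothing.
#'
#' @param outcome One cycle-outcome row (or vectorised data frame) with
#'   columns `ecg_visits`, `on_noac_this_year`, `post_stroke_year` (`NA`
#'   when no stroke history) and `bleeding`, as produced by
#'   [simulate_patient()].
#' @param costs An [af_costs()] object.
#' @return Undiscounted euro amount(s), one per row.
#' @export
cycle_cost <- function(outcome, costs) {
  comp <- .cycle_cost_components(outcome$ecg_visits,
                                 outcome$on_noac_this_year,
                                 outcome$post_stroke_year,
                                 outcome$bleeding, costs)
  comp$visits + comp$noac + comp$stroke + comp$bleeding
}

#' Discount a cost to present value
#'
#' Costs of year `t` are divided by `(1 + rate)^(t - 1)`: the first model
#' year is undiscounted, as is the one-time device purchase at baseline.
#'
#' @param amount Euro amount(s).
#' @param year Model year, integer `>= 1` (vectorised).
#' @param rate Annual discount rate, `>= 0`.
#' @return Present-value amount(s).
#' @export
discount <- function(amount, year, rate) {
  if (any(year < 1)) stop("year must be >= 1", call. = FALSE)
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  amount / (1 + rate)^(year - 1)
}

#' Total discounted cost of one patient history
#'
#' Prices a per-cycle history (as returned by [simulate_patient()]): each
#' year's visit, NOAC, stroke and bleeding costs are discounted by the
#' year's factor, and the one-time device cost is added, undiscounted, in
#' the device arm only.
#'
#' @param history Cycle-outcome data frame from [simulate_patient()] (may be
#'   empty).
#' @param arm Arm object; the device price applies only for the device arm.
#' @param costs An [af_costs()] object.
#' @param rate Annual discount rate.
#' @return An object of class `"af_cost_ledger"`: list with `total`
#'   (discounted), `total_undiscounted`, `per_year` (discounted per cycle)
#'   and a discounted category `breakdown` (device, visits, noac, stroke,
#'   bleeding) that sums to the total.
#' @export
patient_total_cost <- function(history, arm, costs, rate) {
  device <- arm$label == "device"
  dev_cost <- if (device) costs$device_cost else 0
  if (is.null(history) || nrow(history) == 0L) {
    ledger <- list(
      total = dev_cost,
      total_undiscounted = dev_cost,
      per_year = numeric(0),
      breakdown = c(device = dev_cost, visits = 0, noac = 0, stroke = 0,
                    bleeding = 0)
    )
    return(structure(ledger, class = "af_cost_ledger"))
  }
  comp <- .cycle_cost_components(history$ecg_visits,
                                 history$on_noac_this_year,
                                 history$post_stroke_year,
                                 history$bleeding, costs)
  undisc <- comp$visits + comp$noac + comp$stroke + comp$bleeding
  d <- discount(1, history$year, rate)
  breakdown <- c(
    device = dev_cost,
    visits = sum(comp$visits * d),
    noac = sum(comp$noac * d),
    stroke = sum(comp$stroke * d),
    bleeding = sum(comp$bleeding * d)
  )
  structure(list(
    total = dev_cost + sum(undisc * d),
    total_undiscounted = dev_cost + sum(undisc),
    per_year = undisc * d,
    breakdown = breakdown
  ), class = "af_cost_ledger")
}

#' @export
print.af_cost_ledger <- function(x, ...) {
  cat(sprintf("Patient cost ledger: EUR %.2f discounted (%.2f undiscounted)\n",
              x$total, x$total_undiscounted))
  b <- x$breakdown
  cat(sprintf("  device %.2f | visits %.2f | NOAC %.2f | stroke %.2f | bleeding %.2f\n",
              b["device"], b["visits"], b["noac"], b["stroke"], b["bleeding"]))
  invisible(x)
}
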