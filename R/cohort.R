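#' @keywords internal
.af_statuses <- c("no_af", "af_undetected", "af_detected_treated",
                  "af_detected_untreated")

#' Initialise one simulated patient
#'
#' A patient enters the simulation either with (prevalent, still undiagnosed)
#' AF or without AF, according to the score-specific baseline prevalence.
#' Prevalent AF starts undetected: no diagnosis and no therapy, so that
#' screening can find it. Sex matters only at score 1 (where only males are
#' treatment-eligible) and is drawn Bernoulli(0.5) there; at other scores it
#' is drawn the same way but has no effect on the model.
#'
#' Draws come from R's current random stream; call `set.seed()` beforehand
#' for reproducibility, or use [generate_cohort()] which seeds for you.
#'
#' @param score CHA2DS2-VASc score, integer in 1..9.
#' @param params An [af_parameters()] object.
#' @return One-row patient data frame (see [generate_cohort()]).
#' @export
init_patient <- function(score, params) {
  generate_cohort(score, n = 1L, params = params, seed = NULL)
}

#' Generate a synthetic patient cohort
#'
#' Creates `n` independent patients at the given score with the statistical
#' structure the model assumes: AF prevalent (undetected) with the
#' score-specific probability, everyone alive and stroke-free at entry.
#'
#' @param score CHA2DS2-VASc score, integer in 1..9 (score 0 is representable
#'   in the parameters but not simulated).
#' @param n Number of patients, at least 1.
#' @param params An [af_parameters()] object.
#' @param seed Optional integer seed; if `NULL` the current random stream is
#'   used.
#' @param exact_sex_split If `TRUE`, assign exactly half of the cohort female
#'   (variance reduction) instead of per-patient Bernoulli(0.5) draws.
#' @return A data frame with one row per patient and columns `id`, `score`,
#'   `sex` (`"female"`/`"male"`), `af_status` (one of `"no_af"`,
#'   `"af_undetected"`, `"af_detected_treated"`, `"af_detected_untreated"`),
#'   `alive`, `death_cause` (`"none"`/`"stroke"`/`"other"`),
#'   `years_since_last_stroke` (`NA` until a first stroke, then the 1-based
#'   post-stroke year) and `stroke_count`.
#' @export
generate_cohort <- function(score, n, params, seed = NULL,
                            exact_sex_split = FALSE) {
  if (length(score) != 1L || is.na(score) || score < 1 || score > 9 ||
      score != round(score)) {
    stop("score must be a single integer in 1..9", call. = FALSE)
  }
  if (length(n) != 1L || is.na(n) || n < 1) {
    stop("n must be at least 1", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)

  prev <- score_value(params$prevalence, score)
  u_af <- stats::runif(n)
  if (exact_sex_split) {
    sex <- rep(c("female", "male"), length.out = n)[sample.int(n)]
  } else {
    sex <- ifelse(stats::runif(n) < 0.5, "female", "male")
  }
  data.frame(
    id = seq_len(n),
    score = rep(as.integer(score), n),
    sex = sex,
    af_status = ifelse(u_af < prev, "af_undetected", "no_af"),
    alive = rep(TRUE, n),
    death_cause = rep("none", n),
    years_since_last_stroke = rep(NA_integer_, n),
    stroke_count = rep(0L, n),
    stringsAsFactors = FALSE
  )
}

#' Is a patient eligible for anticoagulation once diagnosed?
#'
#' Guideline rule: therapy is initiated in males from score 1 and in females
#' from score 2; a female with score 1 is diagnosed but not anticoagulated.
#'
#' @param score Integer score vector.
#' @param sex Character vector, `"female"` or `"male"`.
#' @return Logical vector.
#' @export
treatment_eligible <- function(score, sex) {
  score >= 2L | sex == "male"
}
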