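#' Scheduled assessment days
#'
#' The study protocol allows up to 8 repeated assessments over 6 weeks; the
#' package uses days 0, 3, 7, 10, 14, 21, 28, 42 as the nominal schedule.
#'
#' @return Integer vector of visit days.
#' @export
visit_schedule <- function() c(0L, 3L, 7L, 10L, 14L, 21L, 28L, 42L)

check_trajectory <- function(traj) {
  need <- c("subject_id", "diagnosis", "scale", "day", "score")
  if (!all(need %in% names(traj))) {
    abort(paste0("trajectory table needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(traj$score < 0, na.rm = TRUE)) abort("scores must be non-negative")
  invisible(traj)
}

#' Last observation carried forward over a visit schedule
#'
#' Fills each scheduled day with the last earlier observed score of the same
#' subject and scale.  No extrapolation happens before baseline; a subject
#' or scale without a day-0 record is an error.
#'
#' @param traj Trajectory tibble with columns `subject_id`, `diagnosis`,
#'   `scale`, `day`, `score`.
#' @param schedule Days to complete; default [visit_schedule()].
#' @return A trajectory tibble containing, per subject and scale, exactly
#'   the union of observed and scheduled days up to the last observed day.
#' @export
locf_fill <- function(traj, schedule = visit_schedule()) {
  check_trajectory(traj)
  traj |>
    dplyr::group_by(.data$subject_id, .data$diagnosis, .data$scale) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$day)
      if (d$day[1] != 0) abort("no baseline (day 0) observation: LOCF undefined")
      days <- sort(union(d$day, schedule))
      idx <- findInterval(days, d$day)
      tibble::tibble(day = days, score = d$score[idx])
    }) |>
    dplyr::ungroup()
}

#' Baseline severity class
#'
#' Severity bands on the diagnosis-appropriate baseline scale.  Depressive
#' (F3) subjects are banded on HAM-D17: below 20 mild, 20 to 24 moderate
#' (boundaries inclusive), above 24 severe.  Schizophrenic (F2) subjects are
#' banded on PANSS-G: below 30 mild, 30 to 40 moderate, above 40 severe.
#'
#' @param score Baseline score(s), non-negative.
#' @param diagnosis `"F2"` or `"F3"` (recycled against `score`).
#' @return Character vector: `"mild"`, `"moderate"` or `"severe"`.
#' @export
baseline_severity <- function(score, diagnosis) {
  if (any(score < 0, na.rm = TRUE)) abort("scores must be non-negative")
  if (!all(diagnosis %in% c("F2", "F3"))) abort("diagnosis must be 'F2' or 'F3'")
  lo <- ifelse(diagnosis == "F3", 20, 30)
  hi <- ifelse(diagnosis == "F3", 24, 40)
  dplyr::case_when(
    score < lo ~ "mild",
    score <= hi ~ "moderate",
    TRUE ~ "severe"
  )
}

inclusion_threshold <- function(diagnosis) ifelse(diagnosis == "F3", 15, 21)

severity_scale <- function(diagnosis) ifelse(diagnosis == "F3", "HAM-D17", "PANSS-G")
response_scale <- function(diagnosis) ifelse(diagnosis == "F3", "HAM-D17", "PANSS-P")

#' Study-inclusion filter
#'
#' A subject is included if the baseline score on the diagnosis-appropriate
#' severity scale meets the entry threshold (HAM-D17 >= 15 for F3,
#' PANSS-G >= 21 for F2) and at least three assessments fall within the
#' first two weeks.
#'
#' @param traj Single-subject trajectory tibble (one diagnosis; the severity
#'   scale must be present).
#' @return Logical flag.
#' @export
inclusion_filter <- function(traj) {
  check_trajectory(traj)
  diagnosis <- traj$diagnosis[1]
  sev <- dplyr::filter(traj, .data$scale == severity_scale(diagnosis))
  if (!nrow(sev) || !any(sev$day == 0)) return(FALSE)
  baseline <- sev$score[sev$day == 0][1]
  n_early <- sum(sev$day <= 14)
  baseline >= inclusion_threshold(diagnosis) && n_early >= 3
}

#' Earliest day of a sustained baseline-score reduction
#'
#' Finds the earliest visit at which the relative reduction from baseline
#' reaches `threshold_fraction` and is *sustained*: no later visit gives back
#' more than `sustain_tolerance` (default 15%) of the achieved reduction.
#' With `anchor = "first"` (default) the achieved reduction is the one at the
#' first qualifying visit; `anchor = "max"` instead requires every later
#' reduction to stay within the tolerance of the running maximum reduction.
#'
#' @param day,score Parallel vectors of visit days (ascending, day 0 first)
#'   and scores.
#' @param threshold_fraction Required relative reduction, e.g. 0.5 for the
#'   HAM-D17 response rule.
#' @param sustain_tolerance Allowed give-back fraction of the achieved
#'   reduction; default 0.15.
#' @param anchor `"first"` or `"max"` (see above).
#' @return The qualifying day, or `NA` if none.
#' @export
sustained_reduction_day <- function(day, score, threshold_fraction,
                                    sustain_tolerance = 0.15,
                                    anchor = c("first", "max")) {
  anchor <- match.arg(anchor)
  if (length(day) != length(score)) abort("day and score lengths differ")
  o <- order(day)
  day <- day[o]
  score <- score[o]
  if (day[1] != 0) abort("first visit must be the day-0 baseline")
  baseline <- score[1]
  if (baseline <= 0) abort("baseline score must be positive")
  red <- baseline - score
  runmax <- cummax(red) # maximal reduction achieved up to each visit
  for (t in seq_along(day)) {
    if (red[t] / baseline < threshold_fraction) next
    idx_later <- seq_along(red) > t
    ok <- if (anchor == "first") {
      all(red[idx_later] >= (1 - sustain_tolerance) * red[t])
    } else {
      # a visit that has itself deteriorated beyond the tolerated give-back
      # from the running maximum cannot start a sustained reduction
      red[t] >= (1 - sustain_tolerance) * runmax[t] &&
        all(red[idx_later] >= (1 - sustain_tolerance) * runmax[idx_later])
    }
    if (ok) return(day[t])
  }
  NA_integer_
}

response_threshold <- function(diagnosis) ifelse(diagnosis == "F3", 0.50, 0.40)

check_response_scale <- function(traj) {
  diagnosis <- traj$diagnosis[1]
  sc <- response_scale(diagnosis)
  resp <- dplyr::filter(traj, .data$scale == sc)
  if (!nrow(resp)) {
    abort(paste0("diagnosis ", diagnosis, " requires scale ", sc, " for response labeling"))
  }
  resp
}

#' Treatment-response label
#'
#' Responder status: a sustained 50% HAM-D17 baseline-score reduction for
#' depressive (F3) subjects, or a sustained 40% PANSS-P reduction for
#' schizophrenic (F2) subjects.
#'
#' @param traj Single-subject trajectory tibble carrying the
#'   diagnosis-appropriate response scale.
#' @param sustain_tolerance,anchor Passed to [sustained_reduction_day()].
#' @return Logical responder flag.
#' @export
classify_response <- function(traj, sustain_tolerance = 0.15, anchor = "first") {
  check_trajectory(traj)
  resp <- check_response_scale(traj)
  d <- sustained_reduction_day(
    resp$day, resp$score, response_threshold(traj$diagnosis[1]),
    sustain_tolerance = sustain_tolerance, anchor = anchor
  )
  !is.na(d)
}

#' Onset of improvement and early-improver label
#'
#' Onset of improvement is a sustained 20% baseline-score reduction on the
#' diagnosis-appropriate response scale; subjects reaching onset within the
#' first 14 days are early improvers.
#'
#' @inheritParams classify_response
#' @return A list: `onset_day` (NA if never) and `early_improver`.
#' @export
classify_onset <- function(traj, sustain_tolerance = 0.15, anchor = "first") {
  check_trajectory(traj)
  resp <- check_response_scale(traj)
  d <- sustained_reduction_day(
    resp$day, resp$score, 0.20,
    sustain_tolerance = sustain_tolerance, anchor = anchor
  )
  list(onset_day = d, early_improver = !is.na(d) && d <= 14)
}

#' Outcome labels for a cohort of trajectories
#'
#' Applies LOCF completion, the inclusion filter, severity banding and the
#' response/onset rules to every subject of a trajectory table.
#'
#' @param trajectories Trajectory tibble (`subject_id`, `diagnosis`, `scale`,
#'   `day`, `score`) for one or more subjects; F2 subjects need PANSS-G
#'   (severity/inclusion) and PANSS-P (response) records, F3 subjects
#'   HAM-D17.
#' @param schedule LOCF completion schedule; default [visit_schedule()].
#' @param sustain_tolerance,anchor Passed to [sustained_reduction_day()].
#' @return A tibble with one row per subject: `subject_id`, `diagnosis`,
#'   `baseline`, `included`, `severity`, `responder`, `onset_day`,
#'   `early_improver`, `non_improver`.
#' @export
label_outcomes <- function(trajectories, schedule = visit_schedule(),
                           sustain_tolerance = 0.15, anchor = "first") {
  check_trajectory(trajectories)
  filled <- locf_fill(trajectories, schedule)
  filled |>
    dplyr::group_by(.data$subject_id, .data$diagnosis) |>
    dplyr::group_modify(function(d, key) {
      diagnosis <- key$diagnosis
      d2 <- dplyr::mutate(d, subject_id = key$subject_id, diagnosis = diagnosis)
      sev <- dplyr::filter(d2, .data$scale == severity_scale(diagnosis))
      baseline <- if (nrow(sev)) sev$score[sev$day == 0][1] else NA_real_
      included <- inclusion_filter(d2)
      # excluded subjects never carry outcome labels (responder => included)
      responder <- included && classify_response(d2, sustain_tolerance, anchor)
      onset <- classify_onset(d2, sustain_tolerance, anchor)
      tibble::tibble(
        baseline = baseline,
        included = included,
        severity = if (is.na(baseline)) NA_character_ else baseline_severity(baseline, diagnosis),
        responder = responder,
        onset_day = as.integer(onset$onset_day),
        early_improver = onset$early_improver,
        non_improver = is.na(onset$onset_day)
      )
    }) |>
    dplyr::ungroup()
}
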