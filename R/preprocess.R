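# Raw trial records -> oriented, baseline-subtracted heading series with
# validity masks and trial-to-trial changes. All rules operate per
# participant; `preprocess_participant()` strings them together and
# `preprocess_cohort()` maps over a long trial-record tibble.

first_acq_index <- function(data) {
  i <- which(data$phase == "acquisition")
  if (!length(i)) stop("participant has no acquisition trials")
  i[1]
}

#' Orient and baseline-subtract a participant's heading series
#'
#' Headings of participants who experienced a counter-clockwise clamp are
#' sign-flipped so that positive always means the expected adaptation
#' direction (away from the clamp); the heading on the first acquisition
#' trial is then treated as the baseline reach angle and subtracted from
#' every trial.
#'
#' @param data One participant's trial records (trial-record schema).
#' @return Numeric oriented, baseline-subtracted heading series (degrees).
#' @export
orient_and_baseline <- function(data) {
  dir <- unique(data$clamp_dir)
  stopifnot(length(dir) == 1, dir %in% c("cw", "ccw"))
  oriented <- if (dir == "ccw") -data$hand_angle_deg else data$hand_angle_deg
  i0 <- first_acq_index(data)
  if (is.na(oriented[i0])) stop("first acquisition trial heading is missing")
  oriented - oriented[i0]
}

#' Flag heading-angle outlier trials
#'
#' Lab rule: |theta| > 100 degrees off the target, or a trial-to-trial change
#' larger than 25 degrees. Web rule: theta outside (-50, 70) degrees, or a
#' change larger than 20 degrees. Change-based flags mark the later trial of
#' the pair.
#'
#' @param theta Oriented heading series (degrees).
#' @param platform `"lab"` or `"web"`.
#' @return Logical mask, TRUE = outlier.
#' @export
flag_outliers <- function(theta, platform = c("lab", "web")) {
  platform <- match.arg(platform)
  d <- c(NA, diff(theta))
  if (platform == "lab")
    range_bad <- abs(theta) > 100
  else
    range_bad <- theta < -50 | theta > 70
  jump_bad <- !is.na(d) & abs(d) > if (platform == "lab") 25 else 20
  range_bad | jump_bad
}

#' Flag slow trials
#'
#' Trials where the reaction time exceeded 400 ms and/or the movement time
#' exceeded 300 ms (strict inequalities). These are excluded from the
#' trial-to-trial change analyses, but not from time-course exports.
#'
#' @param data One participant's trial records.
#' @return Logical mask, TRUE = slow.
#' @export
flag_slow_trials <- function(data) {
  data$rt_ms > 400 | data$mt_ms > 300
}

#' Trial-to-trial heading changes with validity
#'
#' `delta[n] = theta[n] - theta[n-1]`, valid only where both trials of the
#' pair are unmasked and belong to the same phase (the undefined pair
#' spanning the acquisition/probe boundary is never valid).
#'
#' @param theta Oriented heading series.
#' @param mask Logical exclusion mask (outliers and/or slow trials).
#' @param phase Phase label per trial.
#' @return A tibble with `delta` and `valid`.
#' @export
delta_heading <- function(theta, mask, phase) {
  n <- length(theta)
  stopifnot(n >= 2, length(mask) == n, length(phase) == n)
  delta <- c(NA, diff(theta))
  valid <- c(FALSE, !mask[-1] & !mask[-n] & phase[-1] == phase[-n])
  tibble::tibble(delta = delta, valid = valid)
}

#' Feedback correction per trial
#'
#' The within-movement change in heading: the angle measured at the target's
#' radial distance minus the angle 50 ms after movement initiation. Values
#' near zero indicate the absence of online corrections, i.e. purely
#' feedforward reaches.
#'
#' @param data One participant's trial records.
#' @return A list with the per-trial `correction` (degrees), the participant
#'   `mean`, and `by_cs`, the mean correction per CS-type (`"+"`/`"-"`,
#'   differential designs only) for the CS+ vs CS- paired comparison.
#' @export
feedback_correction <- function(data) {
  stopifnot(all(c("hand_angle_deg", "angle_50ms_deg") %in% names(data)))
  correction <- data$hand_angle_deg - data$angle_50ms_deg
  acq <- data$phase == "acquisition"
  by_cs <- NULL
  if (!any(data$cs == "compound")) {
    type <- ifelse(data$cs == infer_cs_plus(data), "+", "-")
    by_cs <- c(`+` = mean(correction[acq & type == "+"]),
               `-` = mean(correction[acq & type == "-"]))
  }
  list(correction = correction, mean = mean(correction[acq]), by_cs = by_cs)
}

# Which physical cue played the CS+ role, inferred from the records: the cue
# paired with the 15-degree clamp during acquisition ("compound" for the
# compound design).
infer_cs_plus <- function(data) {
  acq <- data[data$phase == "acquisition", ]
  if (any(acq$cs == "compound")) return("compound")
  plus <- unique(acq$cs[!is.na(acq$clamp_deg) & acq$clamp_deg == 15])
  if (length(plus) != 1)
    stop("cannot infer the CS+ cue: expected exactly one cue paired with the 15 degree clamp")
  plus
}

#' Preprocess one participant's records
#'
#' Applies orientation and baseline subtraction, outlier and slow-trial
#' flagging, and the trial-to-trial change computation; annotates each trial
#' with its CS type relative to the inferred CS+ cue.
#'
#' @param data One participant's trial records.
#' @return The input tibble augmented with `theta`, `outlier`, `slow`,
#'   `delta`, `delta_valid` and `cs_type` (`"+"`, `"-"`, with the compound
#'   counting as `"+"` in the compound design).
#' @export
preprocess_participant <- function(data) {
  theta <- orient_and_baseline(data)
  outlier <- flag_outliers(theta, unique(data$platform))
  slow <- flag_slow_trials(data)
  d <- delta_heading(theta, outlier | slow, data$phase)
  plus <- infer_cs_plus(data)
  out <- tibble::as_tibble(data)
  out$theta <- theta
  out$outlier <- outlier
  out$slow <- slow
  out$delta <- d$delta
  out$delta_valid <- d$valid
  out$cs_type <- ifelse(data$cs == plus, "+", "-")
  out
}

#' Preprocess every participant of a cohort
#'
#' @param cohort Long tibble of trial records (several participants).
#' @return Long tibble of augmented records, in participant order.
#' @export
preprocess_cohort <- function(cohort) {
  parts <- split(cohort, factor(cohort$participant_id,
                                levels = unique(cohort$participant_id)))
  do.call(rbind, lapply(parts, preprocess_participant))
}
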