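#' @name gait-parameters
#' @title Spatiotemporal gait parameters and head orientation
#' @description
#' Operational definitions of the outcome measures computed from a trial:
#' gait speed over the 3-9 m walkway window (spine-shoulder point), step
#' length as the median difference of consecutive anterior-posterior step
#' locations between 1 and 9 m, crossing step length at gait initiation and
#' at the mid-walkway obstacle, and baseline-corrected median head pitch.
#' A parameter that cannot be computed is returned as `NA` carrying a
#' `reason` attribute (see [missing_reason()]); trials are never silently
#' dropped here.
NULL

.gc_missing <- function(reason) structure(NA_real_, reason = reason)

#' Reason a parameter is missing
#'
#' @param x A value returned by one of the parameter functions.
#' @return The recorded reason string, or `NA` if the value is present.
#' @export
missing_reason <- function(x) {
  r <- attr(x, "reason")
  if (is.null(r)) NA_character_ else r
}

# first upward crossing time of a position track through `target`,
# linearly interpolated between the bracketing samples
.gc_cross_time <- function(t, y, target) {
  below <- y < target
  idx <- which(below[-length(y)] & !below[-1L])
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1L]
  t[i] + (target - y[i]) / (y[i + 1L] - y[i]) * (t[i + 1L] - t[i])
}

#' Gait speed from the spine-shoulder track
#'
#' Distance travelled between 3 and 9 m on the walkway divided by the time
#' elapsed, using the spine-shoulder point; crossing times are linearly
#' interpolated between the bracketing samples. The 3 m run-in leaves room to
#' adapt to a speed cue.
#'
#' @param record A `trial_record`.
#' @return Gait speed in cm/s, or `NA` with a `reason` attribute if the
#'   track does not traverse both window edges.
#' @export
gait_speed <- function(record) {
  tr <- record$tracks$spine_shoulder
  t3 <- .gc_cross_time(tr$t, tr$y_ap, 3)
  t9 <- .gc_cross_time(tr$t, tr$y_ap, 9)
  if (is.na(t3) || is.na(t9)) return(.gc_missing("window not traversed"))
  600 / (t9 - t3)
}

#' Step length from merged stance events
#'
#' Median of the differences in the anterior-posterior direction of
#' consecutive step locations between 1 and 9 m on the walkway; both feet
#' are pooled and time-ordered, and a difference qualifies only when both of
#' its step locations lie inside the (closed) window.
#'
#' @param record A `trial_record`.
#' @param events Merged `stance_events` (see [merge_bilateral()]).
#' @return Step length in cm, or `NA` with a `reason` attribute when fewer
#'   than two qualifying differences exist.
#' @export
step_length <- function(record, events) {
  ev <- events[order(events$t_start), , drop = FALSE]
  loc <- ev$step_location
  if (length(loc) < 2L) return(.gc_missing("insufficient steps in window"))
  in_win <- loc >= 1 & loc <= 9
  d <- diff(loc)
  ok <- in_win[-length(loc)] & in_win[-1L]
  d <- d[ok]
  if (length(d) < 2L) return(.gc_missing("insufficient steps in window"))
  stats::median(d) * 100
}

#' Crossing step length
#'
#' At gait initiation: the first step location minus the median
#' anterior-posterior position of the leading limb during the annotated
#' pre-start standing segment. Halfway: the first step location beyond 5 m
#' minus the last step location before 5 m, both feet pooled in time order.
#'
#' @param record A `trial_record` with a `standing_end` annotation (for
#'   `location = "initiation"`).
#' @param events Merged `stance_events`.
#' @param location `"initiation"` or `"halfway"`.
#' @return Crossing step length in cm, or `NA` with a `reason` attribute.
#' @export
crossing_step_length <- function(record, events,
                                 location = c("initiation", "halfway")) {
  location <- match.arg(location)
  ev <- events[order(events$t_start), , drop = FALSE]
  if (location == "initiation") {
    t_stand <- record$annotations$standing_end
    lead <- record$annotations$leading_limb
    if (is.null(t_stand) || is.null(lead))
      return(.gc_missing("no standing-segment annotation"))
    foot <- record$tracks[[paste0(lead, "_foot")]]
    stand <- foot$y_ap[foot$t <= t_stand]
    if (length(stand) == 0L) return(.gc_missing("no standing samples"))
    steps <- ev[ev$t_start > t_stand, , drop = FALSE]
    if (nrow(steps) == 0L) return(.gc_missing("no step after standing"))
    (steps$step_location[1L] - stats::median(stand)) * 100
  } else {
    loc <- ev$step_location
    after <- which(loc > 5)
    if (length(after) == 0L) return(.gc_missing("no post-obstacle step"))
    i <- after[1L]
    before <- which(loc[seq_len(i - 1L)] < 5)
    if (length(before) == 0L) return(.gc_missing("no pre-obstacle step"))
    (loc[i] - loc[max(before)]) * 100
  }
}

#' Walking head pitch
#'
#' Median headset pitch over the samples whose own anterior-posterior
#' position lies between 3 and 7 m, minus the supplied straight-ahead
#' baseline pitch (by default taken from the static-trial calibration).
#'
#' @param record A `trial_record`.
#' @param baseline_pitch Straight-ahead reference pitch in degrees.
#' @return Baseline-corrected median pitch in degrees (positive downward),
#'   or `NA` with a `reason` attribute if the 3-7 m span is not covered.
#' @export
head_pitch_walking <- function(record, baseline_pitch = 0) {
  hs <- record$tracks$headset
  if (is.null(hs)) return(.gc_missing("no headset track"))
  idx <- hs$y_ap >= 3 & hs$y_ap <= 7
  if (!any(idx) || max(hs$y_ap) < 7 || min(hs$y_ap) > 3)
    return(.gc_missing("3-7 m span not covered"))
  stats::median(hs$pitch[idx]) - baseline_pitch
}

#' Static head pitch per fixated line
#'
#' For a static trial: per ground line, the median pitch within the
#' annotated fixation window minus the baseline pitch, where baseline is the
#' median pitch over the pooled straight-ahead segments at the start and end
#' of the trial.
#'
#' @param record A static `trial_record` with `fixations` and `straight`
#'   annotations.
#' @return data.frame with columns `distance_cm` and `pitch_deg`; lines with
#'   a missing window get `NA` pitch.
#' @export
head_pitch_static <- function(record) {
  ann <- record$annotations
  if (is.null(ann$fixations) || is.null(ann$straight))
    stop("record lacks static-trial annotations")
  hs <- record$tracks$headset
  in_win <- function(w) hs$t >= w[1L] & hs$t < w[2L]
  base_idx <- Reduce(`|`, lapply(seq_len(nrow(ann$straight)), function(i)
    in_win(c(ann$straight$t_start[i], ann$straight$t_end[i]))))
  baseline <- stats::median(hs$pitch[base_idx])
  pitch <- vapply(seq_len(nrow(ann$fixations)), function(i) {
    idx <- in_win(c(ann$fixations$t_start[i], ann$fixations$t_end[i]))
    if (!any(idx)) return(NA_real_)
    stats::median(hs$pitch[idx]) - baseline
  }, numeric(1))
  data.frame(distance_cm = ann$fixations$distance_cm, pitch_deg = pitch)
}

#' Extract all gait parameters of one trial
#'
#' Dispatches on the trial's task and returns a one-row data.frame holding
#' the applicable outcome measures and, for unavailable ones, the recorded
#' missing-data reason.
#'
#' @param record A walking `trial_record`.
#' @param events Optional pre-computed merged stance events; detected with
#'   the default thresholds when omitted.
#' @param baseline_pitch Straight-ahead pitch reference for head orientation.
#' @param detector Named list of [detect_stances()] settings.
#' @return One-row data.frame with trial identity columns, the parameter
#'   columns (`gait_speed_cms`, `step_length_cm`, `crossing_init_cm`,
#'   `crossing_halfway_cm`, `head_pitch_deg`) and a `missing_reason` column.
#' @export
extract_gait_params <- function(record, events = NULL, baseline_pitch = 0,
                                detector = list()) {
  spec <- record$spec
  if (is.null(events)) {
    det <- utils::modifyList(list(v_thresh = 0.2, min_duration = 0.15,
                                  merge_gap = 0.05, smooth_window = 0.17),
                             detector)
    events <- .gc_trial_events(record, det$v_thresh, det$min_duration,
                               det$merge_gap, det$smooth_window)
  }
  task <- spec$task
  gs <- sl <- ci <- ch <- hp <- .gc_missing("not applicable")
  if (task == "gait_speed") {
    gs <- gait_speed(record)
    hp <- head_pitch_walking(record, baseline_pitch)
  } else if (task == "step_length") {
    sl <- step_length(record, events)
    hp <- head_pitch_walking(record, baseline_pitch)
  } else if (task %in% c("crossing_length", "crossing_height")) {
    ci <- crossing_step_length(record, events, "initiation")
    ch <- crossing_step_length(record, events, "halfway")
  }
  vals <- list(gait_speed_cms = gs, step_length_cm = sl, crossing_init_cm = ci,
               crossing_halfway_cm = ch, head_pitch_deg = hp)
  reasons <- vapply(vals, missing_reason, character(1))
  reasons <- reasons[!is.na(reasons) & reasons != "not applicable"]
  data.frame(
    trial_id = if (!is.null(spec$trial_id)) spec$trial_id else NA_character_,
    participant_id = spec$participant_id, task = task, content = spec$content,
    modulation = spec$modulation, imposed_value = spec$imposed_value,
    headset = spec$headset,
    analysis_included = isTRUE(spec$analysis_included),
    gait_speed_cms = as.numeric(gs), step_length_cm = as.numeric(sl),
    crossing_init_cm = as.numeric(ci), crossing_halfway_cm = as.numeric(ch),
    head_pitch_deg = as.numeric(hp),
    missing_reason = if (length(reasons)) paste(reasons, collapse = "; ")
                     else NA_character_,
    stringsAsFactors = FALSE)
}
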