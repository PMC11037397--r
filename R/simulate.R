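#' Noise and execution configuration for the simulator
#'
#' Collects every stochastic ingredient of a simulated trial. Position jitter
#' emulates markerless-tracking noise; execution SDs emulate within-trial
#' variability in how precisely a walker follows a cue; `adherence_bias` is a
#' systematic over/under-shoot of the cued value; `preview_distance` is how
#' far ahead of the feet the gaze point sits when following floor cues, which
#' with eye height fixes the head pitch via `atan(eye_height / preview)`.
#'
#' @param marker_noise_sd Per-sample position jitter SD, meters. Default 0.005.
#' @param step_exec_sd Per-step execution SD of step length, cm. Default 2.
#' @param speed_exec_sd Per-trial execution SD of gait speed, cm/s. Default 4.
#' @param adherence_bias Systematic execution bias (cm or cm/s depending on
#'   task). Default 0.
#' @param pitch_noise_sd Head-pitch jitter SD, degrees. Default 2.
#' @param preview_distance Gaze preview distance for floor cues, meters (> 0).
#'   Default 2.4.
#' @param crossing_margin_init,crossing_margin_halfway Clearance margin on
#'   each side of a 2D obstacle, meters, for the gait-initiation and the
#'   mid-walkway crossing respectively.
#' @param swing_duration Swing-phase duration, seconds.
#' @param fs Sampling rate, Hz (Kinect-v2-style default 30).
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(marker_noise_sd = 0.005, step_exec_sd = 2,
                         speed_exec_sd = 4, adherence_bias = 0,
                         pitch_noise_sd = 2, preview_distance = 2.4,
                         crossing_margin_init = 0.20,
                         crossing_margin_halfway = 0.28,
                         swing_duration = 0.4, fs = 30) {
  stopifnot(marker_noise_sd >= 0, step_exec_sd >= 0, speed_exec_sd >= 0,
            pitch_noise_sd >= 0, preview_distance > 0,
            crossing_margin_init > 0, crossing_margin_halfway > 0,
            swing_duration > 0, fs > 0)
  structure(list(marker_noise_sd = marker_noise_sd, step_exec_sd = step_exec_sd,
                 speed_exec_sd = speed_exec_sd, adherence_bias = adherence_bias,
                 pitch_noise_sd = pitch_noise_sd,
                 preview_distance = preview_distance,
                 crossing_margin_init = crossing_margin_init,
                 crossing_margin_halfway = crossing_margin_halfway,
                 swing_duration = swing_duration, fs = fs),
            class = "noise_config")
}

#' Cohort-level simulation configuration
#'
#' Describes the simulated study population: cohort size, the between-subject
#' distribution of preferred gait speed, step length and eye height, headset
#' allocation, an optional per-condition adherence-bias map, and the
#' within-trial [noise_config()]. Defaults mirror a cohort of 21 walkers with
#' preferred speed 127 +/- 16 cm/s and preferred step length 68 +/- 10 cm,
#' split evenly over the two headsets.
#'
#' @param n_participants Cohort size (>= 2).
#' @param mean_baseline_speed,between_sd_speed Mean and between-subject SD of
#'   preferred gait speed, cm/s.
#' @param mean_baseline_step,between_sd_step Mean and between-subject SD of
#'   preferred step length, cm.
#' @param mean_eye_height,between_sd_eye Mean and SD of eye height, m.
#' @param adherence_bias Optional data.frame with columns `task`, `content`,
#'   `modulation`, `bias` giving condition-specific execution biases; `NA` in
#'   a key column matches any level. Conditions not matched fall back to the
#'   scalar bias in `noise`.
#' @param noise A [noise_config()].
#' @param seed Master seed; all participant- and trial-level streams are
#'   derived from it so results are fully reproducible and earlier
#'   participants are unchanged when the cohort grows.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 21, mean_baseline_speed = 127,
                          between_sd_speed = 16, mean_baseline_step = 68,
                          between_sd_step = 10, mean_eye_height = 1.65,
                          between_sd_eye = 0.05, adherence_bias = NULL,
                          noise = noise_config(), seed = 1L) {
  stopifnot(n_participants >= 2, between_sd_speed >= 0, between_sd_step >= 0,
            inherits(noise, "noise_config"))
  if (!is.null(adherence_bias))
    stopifnot(is.data.frame(adherence_bias),
              all(c("task", "bias") %in% names(adherence_bias)))
  structure(list(n_participants = as.integer(n_participants),
                 mean_baseline_speed = mean_baseline_speed,
                 between_sd_speed = between_sd_speed,
                 mean_baseline_step = mean_baseline_step,
                 between_sd_step = between_sd_step,
                 mean_eye_height = mean_eye_height,
                 between_sd_eye = between_sd_eye,
                 adherence_bias = adherence_bias,
                 noise = noise, seed = as.integer(seed)),
            class = "cohort_config")
}

# look up the adherence bias applying to one trial spec
.gc_bias_for <- function(spec, cfg_bias, default_bias) {
  if (is.null(cfg_bias)) return(default_bias)
  m <- cfg_bias
  for (key in c("task", "content", "modulation")) {
    if (!key %in% names(m)) next
    keep <- is.na(m[[key]]) | m[[key]] == spec[[key]]
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) == 0L) default_bias else m$bias[[1L]]
}

# smoothstep ramp on [0, 1]
.gc_smoothstep <- function(s) s * s * (3 - 2 * s)

# sample one foot's trajectory from its landing times/positions.
# placements: positions p0, p1, ... ; land_times: times of landings p1..;
# the foot is stationary between landings and swings smoothly into each
# landing. Swing lasts `swing` seconds but never more than 45% of the
# stride (inter-landing interval), so fast cadences keep a stance phase.
.gc_foot_path <- function(t, p, land_t, swing) {
  y <- rep(p[1L], length(t))
  z <- numeric(length(t))
  for (j in seq_along(land_t)) {
    t1 <- land_t[j]
    stride <- if (j > 1L) t1 - land_t[j - 1L] else Inf
    t0 <- t1 - min(swing, 0.45 * stride)
    idx <- t >= t0 & t < t1
    if (any(idx)) {
      s <- .gc_smoothstep((t[idx] - t0) / (t1 - t0))
      y[idx] <- p[j] + (p[j + 1L] - p[j]) * s
      z[idx] <- 0.05 * 4 * s * (1 - s) * abs(p[j + 1L] - p[j]) /
        max(abs(p[j + 1L] - p[j]), 0.3)
    }
    y[t >= t1] <- p[j + 1L]
  }
  list(y = y, z = z)
}

#' Simulate one cued walking trial
#'
#' Generates a kinematically plausible walking trial on a 10 m walkway: at
#' least one second of quiet standing, gait initiation, then steady walking
#' past 9 m. Foot tracks are stationary during stance (plus marker noise) and
#' advance with a smooth monotone swing profile; the spine-shoulder point
#' moves through the mid-feet positions at footfall times, which makes its
#' average velocity equal the executed gait speed. The cued parameter is
#' executed as imposed value + adherence bias + execution noise; for
#' obstacle-crossing trials the crossing step (first step, and the first step
#' after the 5 m obstacle) is lengthened to clear the imposed obstacle depth
#' plus the configured margins. Headset pitch follows gaze-to-ground
#' geometry, `atan(eye_height / preview_distance)`, except for the
#' eye-height speed-bird cue where it is zero. All latents drawn are recorded
#' in `$truth` for recovery testing.
#'
#' @param spec One trial row from [enumerate_design()] (list or one-row
#'   data.frame) with a non-static task.
#' @param profile The [participant_profile()].
#' @param noise A [noise_config()].
#' @param bias Optional override of `noise$adherence_bias` for this trial.
#' @return An object of class `trial_record`: list with elements `spec`,
#'   `tracks` (named list `spine_shoulder`, `left_foot`, `right_foot`,
#'   `headset` of data.frames), `truth`, and `annotations`.
#' @export
simulate_walking_trial <- function(spec, profile, noise = noise_config(),
                                   bias = NULL) {
  if (is.data.frame(spec)) spec <- as.list(spec[1L, ])
  stopifnot(inherits(profile, "participant_profile"),
            inherits(noise, "noise_config"))
  if (identical(spec$task, "static"))
    stop("use simulate_static_trial() for static trials")
  if (is.null(bias)) bias <- noise$adherence_bias

  task <- spec$task
  fs <- noise$fs
  pref_step <- profile$baseline_step_length / 100   # m
  pref_speed <- profile$baseline_speed / 100        # m/s

  # executed latents ---------------------------------------------------------
  if (task == "gait_speed") {
    v <- (spec$imposed_value + bias + stats::rnorm(1, 0, noise$speed_exec_sd)) / 100
    if (v <= 0.3) stop("executed speed implausibly low; check noise/bias config")
    target_step <- pref_step
  } else if (task == "step_length") {
    target_cm <- spec$imposed_value + bias
    if (target_cm - 4 * noise$step_exec_sd <= 0)
      stop("step-length config admits non-positive steps (imposed + bias - 4*sd <= 0)")
    target_step <- target_cm / 100
    # walkers slow down for shorter imposed steps (cadence adapts partially)
    v <- pref_speed * sqrt(target_step / pref_step)
  } else { # crossing tasks
    v <- pref_speed
    target_step <- pref_step
  }

  # footfall sequence --------------------------------------------------------
  lead <- profile$leading_limb
  trail <- if (lead == "left") "right" else "left"
  x_lead0 <- 0
  x_trail0 <- -0.12
  t_stand <- 1.2

  margin <- if (task == "crossing_length") {
    c(init = noise$crossing_margin_init, half = noise$crossing_margin_halfway)
  } else c(init = NA, half = NA)
  depth <- if (task == "crossing_length") spec$imposed_value / 100 else NA

  step_len <- function() {
    if (task == "step_length")
      (spec$imposed_value + bias + stats::rnorm(1, 0, noise$step_exec_sd)) / 100
    else
      target_step + stats::rnorm(1, 0, noise$step_exec_sd) / 100
  }

  locs <- x_lead0
  lens <- numeric(0)
  is_cross <- logical(0)
  crossed_half <- task != "crossing_length"
  repeat {
    x <- locs[length(locs)]
    if (x > 9.7) break
    if (task == "crossing_length" && length(locs) == 1L) {
      # gait-initiation crossing step over the obstacle at the start line
      L <- margin[["init"]] + depth + margin[["init"]] +
        stats::rnorm(1, 0, noise$step_exec_sd) / 100
      is_cross <- c(is_cross, TRUE)
    } else if (!crossed_half && x + step_len() > 5 - margin[["half"]] && x < 5) {
      # shorten the approach step to the obstacle edge, then cross
      if (x < 5 - margin[["half"]] - 0.05) {
        L <- (5 - margin[["half"]]) - x
        is_cross <- c(is_cross, FALSE)
      } else {
        L <- (5 + depth + margin[["half"]]) - x +
          stats::rnorm(1, 0, noise$step_exec_sd) / 100
        is_cross <- c(is_cross, TRUE)
        crossed_half <- TRUE
      }
    } else {
      L <- step_len()
      is_cross <- c(is_cross, FALSE)
    }
    lens <- c(lens, L)
    locs <- c(locs, x + L)
  }
  n_steps <- length(lens)
  land_t <- t_stand + cumsum(lens / v)
  t_end <- land_t[n_steps] + 1.0

  # tracks --------------------------------------------------------------------
  t <- seq(0, t_end, by = 1 / fs)
  feet <- list()
  # leading foot lands at locs[2], locs[4], ... ; trailing at locs[3], ...
  lead_land_idx <- seq(2L, n_steps + 1L, by = 2L)
  trail_land_idx <- seq(3L, n_steps + 1L, by = 2L)
  feet[[lead]] <- .gc_foot_path(t, c(x_lead0, locs[lead_land_idx]),
                                land_t[lead_land_idx - 1L], noise$swing_duration)
  feet[[trail]] <- .gc_foot_path(t, c(x_trail0, locs[trail_land_idx]),
                                 land_t[trail_land_idx - 1L], noise$swing_duration)

  # spine-shoulder through mid-feet positions at footfalls => mean velocity v
  mid_t <- c(0, t_stand, land_t)
  mid_y <- c((x_lead0 + x_trail0) / 2, (x_lead0 + x_trail0) / 2,
             (locs[-1L] + locs[-length(locs)]) / 2)
  spine_y <- stats::approx(mid_t, mid_y, xout = t, rule = 2)$y

  nse <- function(n) stats::rnorm(n, 0, noise$marker_noise_sd)
  nt <- length(t)
  tracks <- list(
    spine_shoulder = data.frame(t = t, y_ap = spine_y + nse(nt),
                                z = 1.45 + nse(nt)),
    left_foot = data.frame(t = t, y_ap = feet$left$y + nse(nt),
                           z = feet$left$z + nse(nt)),
    right_foot = data.frame(t = t, y_ap = feet$right$y + nse(nt),
                            z = feet$right$z + nse(nt)))

  # headset: rides with the trunk; pitch from gaze-to-ground geometry
  fix_pitch <- if (identical(spec$content, "ar_bird")) 0 else
    atan(profile$eye_height / noise$preview_distance) * 180 / pi
  tracks$headset <- data.frame(
    t = t, y_ap = spine_y + nse(nt),
    pitch = fix_pitch + stats::rnorm(nt, 0, noise$pitch_noise_sd))

  truth <- list(
    executed_speed_cms = v * 100,
    step_lengths_cm = lens * 100,
    step_locations_m = locs[-1L],
    step_feet = rep(c(lead, trail), length.out = n_steps),
    crossing_init_cm = if (task == "crossing_length") lens[1L] * 100 else NA_real_,
    crossing_halfway_cm = if (task == "crossing_length" && any(is_cross[-1L]))
      lens[which(is_cross[-1L])[1L] + 1L] * 100 else NA_real_,
    fixation_pitch_deg = fix_pitch)

  structure(list(spec = spec, tracks = tracks, truth = truth,
                 annotations = list(standing_start = 0, standing_end = t_stand,
                                    leading_limb = lead)),
            class = "trial_record")
}

#' Simulate a static head-orientation trial
#'
#' Quiet standing while fixating ground lines at the given distances for 5 s
#' each, book-ended by straight-ahead segments. Noise-free fixation pitch for
#' a line at distance `d` is `atan(eye_height / d)` (degrees, positive
#' downward); straight ahead is 0 degrees. Fixation windows and the
#' straight-ahead segments are annotated for the extraction layer.
#'
#' @param profile A [participant_profile()].
#' @param distances Line distances in cm (positive). Defaults to the
#'   projected-line set 10, 30, 60, 100, 150, 210, 280 cm.
#' @param noise A [noise_config()].
#' @param content Condition label for the lines (`"real_world"` or `"ar"`).
#' @return A `trial_record` whose annotations carry `fixations` (data.frame
#'   `distance_cm`, `t_start`, `t_end`) and `straight` windows.
#' @export
simulate_static_trial <- function(profile,
                                  distances = c(10, 30, 60, 100, 150, 210, 280),
                                  noise = noise_config(),
                                  content = "real_world") {
  stopifnot(inherits(profile, "participant_profile"), all(distances > 0),
            inherits(noise, "noise_config"))
  fs <- noise$fs
  seg_straight <- 3
  seg_fix <- 5
  n_fix <- length(distances)
  t_end <- 2 * seg_straight + n_fix * seg_fix
  t <- seq(0, t_end, by = 1 / fs)

  pitch_true <- numeric(length(t))
  fix <- data.frame(distance_cm = distances,
                    t_start = seg_straight + (seq_len(n_fix) - 1) * seg_fix,
                    t_end = seg_straight + seq_len(n_fix) * seg_fix)
  true_pitch <- atan(profile$eye_height / (distances / 100)) * 180 / pi
  for (i in seq_len(n_fix)) {
    idx <- t >= fix$t_start[i] & t < fix$t_end[i]
    pitch_true[idx] <- true_pitch[i]
  }

  nse <- function(n) stats::rnorm(n, 0, noise$marker_noise_sd)
  nt <- length(t)
  still <- function() data.frame(t = t, y_ap = nse(nt), z = nse(nt))
  tracks <- list(
    spine_shoulder = still(), left_foot = still(), right_foot = still(),
    headset = data.frame(t = t, y_ap = nse(nt),
                         pitch = pitch_true +
                           stats::rnorm(nt, 0, noise$pitch_noise_sd)))

  spec <- list(participant_id = profile$participant_id, task = "static",
               content = content, modulation = NA_character_,
               imposed_value = NA_real_, headset = profile$headset,
               analysis_included = TRUE)
  structure(list(
    spec = spec, tracks = tracks,
    truth = list(pitch_by_line = data.frame(distance_cm = distances,
                                            pitch_deg = true_pitch)),
    annotations = list(
      fixations = fix,
      straight = data.frame(t_start = c(0, t_end - seg_straight),
                            t_end = c(seg_straight, t_end)))),
    class = "trial_record")
}

# derived, stable sub-seed; stays below 2^31 - 1
.gc_sub_seed <- function(master, pidx, tidx = 0L) {
  as.integer((as.numeric(master) %% 1e6 * 1009 + pidx * 7919 + tidx * 13) %%
               2147483587)
}

#' Simulate a full cohort
#'
#' Draws participant baselines from the configured between-subject
#' distributions, allocates headsets in an alternating (even) split,
#' enumerates each participant's design and simulates every trial. Each
#' participant and trial has its own seed stream derived from the master
#' seed, so a given participant's data are reproducible and unaffected by
#' cohort size.
#'
#' @param cfg A [cohort_config()].
#' @param tasks Optional subset of tasks to simulate (e.g. `"step_length"`);
#'   `NULL` simulates the whole design including static trials.
#' @return List with `profiles` (data.frame) and `records` (list of
#'   `trial_record`).
#' @export
simulate_cohort <- function(cfg = cohort_config(), tasks = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  headsets <- rep(c("HL2", "ML2"), length.out = cfg$n_participants)
  profiles <- vector("list", cfg$n_participants)
  records <- list()

  rho <- 0.85  # preferred speed and step length covary strongly in walkers
  for (p in seq_len(cfg$n_participants)) {
    set.seed(.gc_sub_seed(cfg$seed, p))
    z1 <- stats::rnorm(1)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)
    bs <- max(60, cfg$mean_baseline_speed + cfg$between_sd_speed * z1)
    bl <- max(35, cfg$mean_baseline_step + cfg$between_sd_step * z2)
    eh <- min(2, max(1, stats::rnorm(1, cfg$mean_eye_height, cfg$between_sd_eye)))
    prof <- participant_profile(sprintf("P%02d", p), bs, bl, eh, headsets[p],
                                sample(c("left", "right"), 1))
    profiles[[p]] <- data.frame(participant_id = prof$participant_id,
                                baseline_speed = bs, baseline_step_length = bl,
                                eye_height = eh, headset = headsets[p],
                                leading_limb = prof$leading_limb,
                                stringsAsFactors = FALSE)
    design <- enumerate_design(prof, seed = cfg$seed)
    if (!is.null(tasks)) design <- design[design$task %in% tasks, , drop = FALSE]
    for (i in seq_len(nrow(design))) {
      spec <- as.list(design[i, ])
      set.seed(.gc_sub_seed(cfg$seed, p, i))
      rec <- if (spec$task == "static") {
        simulate_static_trial(prof, noise = cfg$noise, content = spec$content)
      } else {
        simulate_walking_trial(spec, prof, cfg$noise,
                               bias = .gc_bias_for(spec, cfg$adherence_bias,
                                                   cfg$noise$adherence_bias))
      }
      rec$spec$trial_id <- sprintf("%s_T%02d", prof$participant_id, i)
      records[[length(records) + 1L]] <- rec
    }
  }
  list(profiles = do.call(rbind, profiles), records = records)
}
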