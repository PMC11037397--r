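#' Participant profile
#'
#' Bundles the per-participant quantities the experimental design is anchored
#' on: the preferred ("baseline") gait speed and step length measured during
#' uncued walks, eye height (drives head-pitch geometry), the allocated AR
#' headset, and the limb used to initiate gait.
#'
#' @param participant_id Character label, unique within a cohort.
#' @param baseline_speed Preferred gait speed in cm/s; must be positive.
#' @param baseline_step_length Preferred step length in cm; must be positive.
#' @param eye_height Eye height above the floor in meters, in `[1, 2]`.
#' @param headset Allocated headset, `"HL2"` or `"ML2"`.
#' @param leading_limb Limb that initiates gait, `"left"` or `"right"`.
#' @return An object of class `participant_profile` (a named list).
#' @examples
#' participant_profile("P01", baseline_speed = 127, baseline_step_length = 68,
#'                     eye_height = 1.65, headset = "HL2")
#' @export
participant_profile <- function(participant_id, baseline_speed,
                                baseline_step_length, eye_height,
                                headset = c("HL2", "ML2"),
                                leading_limb = c("right", "left")) {
  headset <- match.arg(headset)
  leading_limb <- match.arg(leading_limb)
  stopifnot(is.character(participant_id), length(participant_id) == 1L)
  if (!is.numeric(baseline_speed) || baseline_speed <= 0)
    stop("baseline_speed must be a positive number (cm/s)")
  if (!is.numeric(baseline_step_length) || baseline_step_length <= 0)
    stop("baseline_step_length must be a positive number (cm)")
  if (!is.numeric(eye_height) || eye_height < 1 || eye_height > 2)
    stop("eye_height must lie in [1, 2] meters")
  structure(
    list(participant_id = participant_id,
         baseline_speed = as.numeric(baseline_speed),
         baseline_step_length = as.numeric(baseline_step_length),
         eye_height = as.numeric(eye_height),
         headset = headset,
         leading_limb = leading_limb),
    class = "participant_profile")
}

# condition sets per cued task; content admissibility mirrors the experiment
.gc_tasks <- function() {
  list(
    gait_speed      = list(contents = c("real_world", "ar", "ar_bird"),
                           offsets = c(low = -20, mid = 0, high = 20)),
    step_length     = list(contents = c("real_world", "ar", "ar_sound"),
                           offsets = c(low = -15, mid = 0, high = 15)),
    crossing_length = list(contents = c("real_world", "ar"),
                           values = c(low = 15, mid = 30, high = 45)),
    crossing_height = list(contents = c("real_world", "ar"),
                           values = c(low = 5, mid = 10, high = 15))
  )
}

#' Enumerate the trial set for one participant
#'
#' Builds the full cued-trial design for a participant: two static
#' head-orientation trials plus 30 cued walking trials — 9 gait-speed
#' (3 contents x 3 modulations), 9 step-length, 6 obstacle-crossing-depth and
#' 6 hurdle-height trials. Tasks come in a fixed order (static, gait speed,
#' step length, crossing length, crossing height); content and modulation
#' order within a task are randomized reproducibly from `seed`. Imposed
#' values are filled from the profile: baseline +/- 20 cm/s for speed,
#' baseline +/- 15 cm for step length, fixed depths/heights for the crossing
#' tasks. Hurdle-height trials are generated but flagged
#' `analysis_included = FALSE` (their vertical kinematics are not analysed).
#'
#' @param profile A [participant_profile()].
#' @param seed Integer seed controlling the per-participant condition order.
#' @param include_calibration If `TRUE`, prepend three uncued baseline walks
#'   (two without, one with the headset) flagged `analysis_included = FALSE`
#'   and not counted among the 30 cued walking trials.
#' @return A data.frame with one row per trial and columns `participant_id`,
#'   `task`, `content`, `modulation`, `imposed_value`, `headset`,
#'   `analysis_included`.
#' @examples
#' p <- participant_profile("P01", 127, 68, 1.65, "HL2")
#' d <- enumerate_design(p, seed = 1)
#' sum(d$task != "static")  # 30 cued walking trials
#' @export
enumerate_design <- function(profile, seed = 1L, include_calibration = FALSE) {
  stopifnot(inherits(profile, "participant_profile"))
  seed <- as.integer(seed)
  rows <- list()

  if (include_calibration) {
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = profile$participant_id,
      task = "baseline_walk",
      content = c("real_world", "real_world", "real_world"),
      modulation = "mid",
      imposed_value = profile$baseline_speed,
      headset = c("none", "none", profile$headset),
      analysis_included = FALSE,
      stringsAsFactors = FALSE)
  }

  # two static head-orientation trials (real-world lines, AR lines)
  rows[[length(rows) + 1L]] <- data.frame(
    participant_id = profile$participant_id,
    task = "static",
    content = c("real_world", "ar"),
    modulation = NA_character_,
    imposed_value = NA_real_,
    headset = profile$headset,
    analysis_included = TRUE,
    stringsAsFactors = FALSE)

  tasks <- .gc_tasks()
  # private RNG stream so design enumeration never perturbs caller RNG
  rng <- .gc_with_seed(seed + .gc_string_hash(profile$participant_id), function() {
    lapply(tasks, function(spec) {
      contents <- sample(spec$contents)
      mods <- lapply(contents, function(x) sample(c("low", "mid", "high")))
      list(contents = contents, mods = mods)
    })
  })

  for (task in names(tasks)) {
    spec <- tasks[[task]]
    contents <- rng[[task]]$contents
    for (i in seq_along(contents)) {
      mods <- rng[[task]]$mods[[i]]
      imposed <- switch(task,
        gait_speed = profile$baseline_speed + spec$offsets[mods],
        step_length = profile$baseline_step_length + spec$offsets[mods],
        spec$values[mods])
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = profile$participant_id,
        task = task,
        content = contents[i],
        modulation = mods,
        imposed_value = unname(imposed),
        headset = profile$headset,
        analysis_included = task != "crossing_height",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# evaluate fn() under a temporary seed, restoring the caller's RNG state
.gc_with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}

# stable small string hash (additive, order-sensitive); keeps per-participant
# streams fixed when the cohort grows
.gc_string_hash <- function(x) {
  v <- utf8ToInt(x)
  as.integer(sum(v * (seq_along(v) %% 31L + 1L)) %% 100003L)
}

#' Write or read a design table
#'
#' Flat CSV round trip for the trial design produced by [enumerate_design()].
#'
#' @param design Design data.frame.
#' @param path File path.
#' @return `read_design` returns the design data.frame.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "task", "content", "modulation",
              "imposed_value", "headset", "analysis_included")
  missing <- setdiff(needed, names(d))
  if (length(missing))
    stop("design file lacks columns: ", paste(missing, collapse = ", "))
  d
}
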