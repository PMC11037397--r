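#' Run configuration for the full pipeline
#'
#' @param cohort A [cohort_config()].
#' @param detector Named list of [detect_stances()] settings (`v_thresh`,
#'   `min_duration`, `merge_gap`, `smooth_window`).
#' @param tasks Which cued tasks to simulate and analyse. Hurdle-height
#'   trials are always excluded from analysis even when simulated.
#' @param alpha Significance level for equivalence and post-hoc tests,
#'   in (0, 0.5).
#' @param seed Optional override of the cohort master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       detector = list(),
                       tasks = c("gait_speed", "step_length",
                                 "crossing_length", "crossing_height",
                                 "static"),
                       alpha = 0.05, seed = NULL) {
  stopifnot(inherits(cohort, "cohort_config"), alpha > 0, alpha < 0.5)
  tasks <- match.arg(tasks, several.ok = TRUE)
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort,
                 detector = utils::modifyList(
                   list(v_thresh = 0.2, min_duration = 0.15,
                        merge_gap = 0.05, smooth_window = 0.17), detector),
                 tasks = tasks, alpha = alpha),
            class = "run_config")
}

# straight-ahead headset pitch calibration from a participant's static trials
.gc_static_baselines <- function(records) {
  out <- list()
  for (rec in records) {
    if (!identical(rec$spec$task, "static")) next
    hs <- rec$tracks$headset
    st <- rec$annotations$straight
    idx <- Reduce(`|`, lapply(seq_len(nrow(st)), function(i)
      hs$t >= st$t_start[i] & hs$t < st$t_end[i]))
    pid <- rec$spec$participant_id
    out[[pid]] <- c(out[[pid]], stats::median(hs$pitch[idx]))
  }
  vapply(out, mean, numeric(1))
}

#' Run a cued-walking experiment end to end
#'
#' Simulates the cohort, detects stance events, extracts the gait parameters,
#' and runs the statistical analyses: paired TOST of executed against imposed
#' values per content-by-modulation condition (gait-speed and step-length
#' tasks, bounds at 25% of the modulation), split-plot ANOVAs
#' (Headset x Content x Modulation for gait speed, step length and walking
#' head pitch; Headset x Content x Location x Modulation for crossing step
#' length; Headset x Content x Distance for static head pitch), and
#' Bonferroni post-hoc contrasts for the modulation and location factors.
#' Hurdle-height trials are simulated but excluded from analysis ("step
#' height not analyzed"); any trial whose parameter could not be extracted is
#' excluded analysis-by-analysis, and every exclusion is listed with its
#' reason in the trial accounting.
#'
#' @param cfg A [run_config()].
#' @return An object of class `results_bundle`: list with `params` (per-trial
#'   parameter table), `static_pitch` (per line), `tost` (one row per task x
#'   content x modulation), `anovas` (named list of `anova_table`s),
#'   `posthocs` (named list), `accounting`, `profiles`, and `config`.
#' @export
run_experiment <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  sim_tasks <- cfg$tasks
  need_static <- "static" %in% sim_tasks ||
    any(c("gait_speed", "step_length") %in% sim_tasks)
  sim <- simulate_cohort(cfg$cohort,
                         tasks = union(sim_tasks,
                                       if (need_static) "static" else NULL))

  baselines <- .gc_static_baselines(sim$records)

  params <- list()
  static_rows <- list()
  det <- cfg$detector
  for (rec in sim$records) {
    if (identical(rec$spec$task, "static")) {
      sp <- head_pitch_static(rec)
      static_rows[[length(static_rows) + 1L]] <- data.frame(
        participant_id = rec$spec$participant_id,
        content = rec$spec$content, headset = rec$spec$headset,
        distance_cm = sp$distance_cm, pitch_deg = sp$pitch_deg,
        stringsAsFactors = FALSE)
      next
    }
    bp <- baselines[rec$spec$participant_id]
    if (is.na(bp)) bp <- 0
    params[[length(params) + 1L]] <-
      extract_gait_params(rec, baseline_pitch = bp, detector = det)
  }
  params <- if (length(params)) do.call(rbind, params) else NULL
  static_pitch <- if (length(static_rows)) do.call(rbind, static_rows) else NULL

  # trial accounting -----------------------------------------------------------
  accounting <- NULL
  if (!is.null(params)) {
    status <- ifelse(params$task == "crossing_height",
                     "excluded: step height not analyzed",
              ifelse(!is.na(params$missing_reason),
                     paste0("missing: ", params$missing_reason), "analyzed"))
    accounting <- data.frame(trial_id = params$trial_id,
                             participant_id = params$participant_id,
                             task = params$task, content = params$content,
                             modulation = params$modulation, status = status,
                             stringsAsFactors = FALSE)
  }

  ana <- if (is.null(params)) NULL else
    params[!is.na(params$task) & params$analysis_included, , drop = FALSE]
  mod_levels <- c("low", "mid", "high")

  # TOST per content x modulation ---------------------------------------------
  tost_rows <- list()
  for (task in intersect(c("gait_speed", "step_length"), sim_tasks)) {
    dvcol <- if (task == "gait_speed") "gait_speed_cms" else "step_length_cm"
    bound <- equivalence_bound(task)
    sub <- ana[ana$task == task, , drop = FALSE]
    for (ct in unique(sub$content)) for (md in mod_levels) {
      cell <- sub[sub$content == ct & sub$modulation == md, , drop = FALSE]
      ok <- !is.na(cell[[dvcol]]) & !is.na(cell$imposed_value)
      if (sum(ok) < 3) next
      tr <- tost_paired(cell[[dvcol]][ok], cell$imposed_value[ok],
                        bound = bound, alpha = cfg$alpha)
      tost_rows[[length(tost_rows) + 1L]] <- data.frame(
        task = task, content = ct, modulation = md, n = tr$n,
        imposed_mean = mean(cell$imposed_value[ok]),
        imposed_sd = stats::sd(cell$imposed_value[ok]),
        executed_mean = mean(cell[[dvcol]][ok]),
        executed_sd = stats::sd(cell[[dvcol]][ok]),
        mean_diff = tr$mean_diff,
        t = tr$t_conventional, df = tr$df, p = tr$p_conventional,
        t_lower = tr$t_lower, p_lower = tr$p_lower,
        t_upper = tr$t_upper, p_upper = tr$p_upper,
        bound = bound, equivalent = tr$equivalent,
        stringsAsFactors = FALSE)
    }
  }
  tost <- if (length(tost_rows)) do.call(rbind, tost_rows) else NULL
  if (!is.null(tost)) {
    tost$modulation <- factor(tost$modulation, levels = mod_levels)
    tost <- tost[order(tost$task, tost$content, tost$modulation), ]
    rownames(tost) <- NULL
  }

  # ANOVAs and post-hocs --------------------------------------------------------
  anovas <- list()
  posthocs <- list()
  run_posthoc <- function(d, dv, fac) {
    tryCatch(bonferroni_posthoc(d, dv, "participant_id", fac,
                                alpha = cfg$alpha),
             error = function(e) NULL)
  }
  safe_anova <- function(d, dv, within) {
    tryCatch(suppressMessages(
      mixed_anova(d, dv, "participant_id", "headset", within)),
      error = function(e) NULL)
  }

  if ("gait_speed" %in% sim_tasks) {
    d <- ana[ana$task == "gait_speed", ]
    anovas$gait_speed <- safe_anova(d, "gait_speed_cms",
                                    c("content", "modulation"))
    posthocs$gait_speed_modulation <- run_posthoc(d, "gait_speed_cms",
                                                  "modulation")
    anovas$head_pitch_speed <- safe_anova(d, "head_pitch_deg",
                                          c("content", "modulation"))
  }
  if ("step_length" %in% sim_tasks) {
    d <- ana[ana$task == "step_length", ]
    anovas$step_length <- safe_anova(d, "step_length_cm",
                                     c("content", "modulation"))
    posthocs$step_length_modulation <- run_posthoc(d, "step_length_cm",
                                                   "modulation")
    anovas$head_pitch_step <- safe_anova(d, "head_pitch_deg",
                                         c("content", "modulation"))
  }
  if ("crossing_length" %in% sim_tasks) {
    d <- ana[ana$task == "crossing_length", ]
    long <- rbind(
      data.frame(d[c("participant_id", "headset", "content", "modulation")],
                 location = "initiation", crossing_cm = d$crossing_init_cm),
      data.frame(d[c("participant_id", "headset", "content", "modulation")],
                 location = "halfway", crossing_cm = d$crossing_halfway_cm))
    anovas$crossing <- safe_anova(long, "crossing_cm",
                                  c("content", "location", "modulation"))
    posthocs$crossing_modulation <- run_posthoc(long, "crossing_cm",
                                                "modulation")
    posthocs$crossing_location <- run_posthoc(long, "crossing_cm", "location")
  }
  if ("static" %in% sim_tasks && !is.null(static_pitch)) {
    sp <- static_pitch
    sp$distance <- factor(sp$distance_cm)
    anovas$head_pitch_static <- safe_anova(sp, "pitch_deg",
                                           c("content", "distance"))
    posthocs$static_distance <- run_posthoc(sp, "pitch_deg", "distance")
  }

  structure(list(params = params, static_pitch = static_pitch, tost = tost,
                 anovas = anovas, posthocs = posthocs,
                 accounting = accounting, profiles = sim$profiles,
                 config = cfg),
            class = "results_bundle")
}

#' Write the report tables of a results bundle
#'
#' Writes CSV tables (per-trial parameters, TOST table in the layout imposed
#' mean/SD, executed mean/SD, conventional t, TOST lower, TOST upper,
#' equivalence; one CSV per ANOVA and post-hoc; trial accounting) plus a
#' plain-text `summary.txt` listing the trial accounting, equivalence
#' verdicts and the main ANOVA effects with corrected df, epsilon and partial
#' eta-squared. Optionally writes simple modulation-level mean plots
#' (requires ggplot2).
#'
#' @param bundle A `results_bundle` from [run_experiment()].
#' @param dir Output directory (created if needed).
#' @param plots If `TRUE` and ggplot2 is installed, write modulation-mean
#'   figures as PDF.
#' @return Invisibly, the paths written.
#' @export
report <- function(bundle, dir, plots = FALSE) {
  stopifnot(inherits(bundle, "results_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wcsv <- function(x, name) {
    if (is.null(x)) return(invisible(NULL))
    p <- file.path(dir, name)
    utils::write.csv(as.data.frame(x), p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wcsv(bundle$params, "trial_params.csv")
  wcsv(bundle$static_pitch, "static_pitch.csv")
  wcsv(bundle$tost, "tost.csv")
  wcsv(bundle$accounting, "accounting.csv")
  for (nm in names(bundle$anovas))
    wcsv(bundle$anovas[[nm]], paste0("anova_", nm, ".csv"))
  for (nm in names(bundle$posthocs))
    wcsv(bundle$posthocs[[nm]], paste0("posthoc_", nm, ".csv"))

  sm <- file.path(dir, "summary.txt")
  con <- file(sm, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Cued-walking experiment summary")
  w("===============================")
  if (!is.null(bundle$accounting)) {
    tab <- table(bundle$accounting$status)
    w("\nTrial accounting (%d trials):", nrow(bundle$accounting))
    for (s in names(tab)) w("  %-45s %d", s, tab[[s]])
    excl <- bundle$accounting[bundle$accounting$status != "analyzed", ,
                              drop = FALSE]
    if (nrow(excl)) {
      w("\nExcluded/missing trials:")
      for (i in seq_len(nrow(excl)))
        w("  %s (%s/%s/%s): %s", excl$trial_id[i], excl$task[i],
          excl$content[i], excl$modulation[i], excl$status[i])
    }
  }
  if (!is.null(bundle$tost)) {
    w("\nEquivalence (TOST, alpha = %g):", bundle$config$alpha)
    for (i in seq_len(nrow(bundle$tost)))
      w("  %-12s %-12s %-5s bound %.2f: mean diff %6.2f, equivalent: %s",
        bundle$tost$task[i], bundle$tost$content[i],
        as.character(bundle$tost$modulation[i]), bundle$tost$bound[i],
        bundle$tost$mean_diff[i], ifelse(bundle$tost$equivalent[i], "yes", "no"))
  }
  for (nm in names(bundle$anovas)) {
    a <- bundle$anovas[[nm]]
    if (is.null(a)) next
    w("\nANOVA: %s", nm)
    for (i in seq_len(nrow(a)))
      w("  %-32s F(%.2f, %.2f) = %8.3f, p = %-9.3g eta_p^2 = %.3f%s",
        a$effect[i], a$df_num_corr[i], a$df_den_corr[i], a$F[i], a$p[i],
        a$eta_p_sq[i],
        ifelse(a$correction[i] == "none", "",
               sprintf(" [%s eps %.3f]", a$correction[i], a$epsilon_used[i])))
  }
  for (nm in names(bundle$posthocs)) {
    ph <- bundle$posthocs[[nm]]
    if (is.null(ph)) next
    w("\nPost-hoc (Bonferroni): %s", nm)
    for (i in seq_len(nrow(ph)))
      w("  %s vs %s: diff %7.2f, t(%d) = %7.2f, p_bonf = %-9.3g %s",
        ph$level_a[i], ph$level_b[i], ph$mean_diff[i], ph$df[i], ph$t[i],
        ph$p_bonf[i], ifelse(ph$significant[i], "*", ""))
  }
  paths <- c(paths, sm)

  if (plots && requireNamespace("ggplot2", quietly = TRUE) &&
      !is.null(bundle$params)) {
    for (task in c("gait_speed", "step_length")) {
      dvcol <- if (task == "gait_speed") "gait_speed_cms" else "step_length_cm"
      d <- bundle$params[bundle$params$task == task &
                           !is.na(bundle$params[[dvcol]]), ]
      if (!nrow(d)) next
      d$modulation <- factor(d$modulation, levels = c("low", "mid", "high"))
      d$.value <- d[[dvcol]]
      gp <- ggplot2::ggplot(d, ggplot2::aes(
        x = !!as.name("modulation"), y = !!as.name(".value"))) +
        ggplot2::geom_boxplot() +
        ggplot2::facet_wrap(ggplot2::vars(!!as.name("content"))) +
        ggplot2::labs(title = task, y = dvcol)
      p <- file.path(dir, paste0("modulation_", task, ".pdf"))
      ggplot2::ggsave(p, gp, width = 7, height = 4)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
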