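#' Serialize a trial record
#'
#' A trial record is written as one tidy CSV of its tracks (columns `t`,
#' `point`, `y_ap`, `z`, `pitch`; `z` is empty for the headset row and
#' `pitch` for body points) plus a JSON sidecar holding the spec, the
#' ground-truth latents and the annotations. `read_trial_record` restores
#' the record from the two files.
#'
#' @param record A `trial_record`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem; defaults to the trial id (or `"trial"`).
#' @return Invisibly, the two paths written.
#' @export
write_trial_record <- function(record, dir, stem = NULL) {
  stopifnot(inherits(record, "trial_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(stem))
    stem <- if (!is.null(record$spec$trial_id)) record$spec$trial_id else "trial"

  long <- do.call(rbind, lapply(names(record$tracks), function(pt) {
    tr <- record$tracks[[pt]]
    data.frame(t = tr$t, point = pt, y_ap = tr$y_ap,
               z = if ("z" %in% names(tr)) tr$z else NA_real_,
               pitch = if ("pitch" %in% names(tr)) tr$pitch else NA_real_,
               stringsAsFactors = FALSE)
  }))
  csv <- file.path(dir, paste0(stem, "_tracks.csv"))
  utils::write.csv(long, csv, row.names = FALSE)

  side <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(
    list(spec = record$spec, truth = record$truth,
         annotations = record$annotations),
    side, auto_unbox = TRUE, digits = NA, na = "null", dataframe = "columns")
  invisible(c(tracks = csv, sidecar = side))
}

#' @rdname write_trial_record
#' @param stem_path Path prefix used when writing (directory plus stem).
#' @export
read_trial_record <- function(stem_path) {
  csv <- paste0(stem_path, "_tracks.csv")
  side <- paste0(stem_path, ".json")
  long <- utils::read.csv(csv, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  tracks <- lapply(split(long, long$point), function(d) {
    d <- d[order(d$t), ]
    out <- data.frame(t = d$t, y_ap = d$y_ap)
    if (!all(is.na(d$z))) out$z <- d$z
    if (!all(is.na(d$pitch))) out$pitch <- d$pitch
    out
  })
  ann <- meta$annotations
  for (nm in c("fixations", "straight"))
    if (!is.null(ann[[nm]])) ann[[nm]] <- as.data.frame(ann[[nm]])
  structure(list(spec = as.list(meta$spec), tracks = tracks,
                 truth = meta$truth, annotations = ann),
            class = "trial_record")
}

#' Write a cohort manifest
#'
#' One row per simulated trial with its identity and file stem, alongside
#' the participant profiles.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory.
#' @param write_records If `TRUE`, also serialize every trial record.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(sim, dir, write_records = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- do.call(rbind, lapply(sim$records, function(r)
    data.frame(trial_id = r$spec$trial_id, participant_id = r$spec$participant_id,
               task = r$spec$task, content = r$spec$content,
               modulation = r$spec$modulation,
               imposed_value = r$spec$imposed_value,
               headset = r$spec$headset, stringsAsFactors = FALSE)))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(sim$profiles, file.path(dir, "profiles.csv"),
                   row.names = FALSE)
  if (write_records)
    for (r in sim$records) write_trial_record(r, file.path(dir, "trials"))
  invisible(file.path(dir, "manifest.csv"))
}
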