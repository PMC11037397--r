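#' Detect stance phases of one foot
#'
#' Velocity-threshold stance detection on a single foot's anterior-posterior
#' track. The position signal is smoothed with a short boxcar (to keep
#' marker jitter from fragmenting stances), the velocity is computed by
#' central differences, and maximal intervals with `|velocity| < v_thresh`
#' become candidate stances; candidates separated by less than `merge_gap`
#' are merged, and merged intervals shorter than `min_duration` are dropped.
#' The step location of a stance is the median anterior-posterior position
#' within it.
#'
#' @param track data.frame with columns `t` (seconds, uniform rate) and
#'   `y_ap` (meters).
#' @param foot `"left"`, `"right"` or `NA` label copied into the output.
#' @param v_thresh Stance velocity threshold, m/s (default 0.2).
#' @param min_duration Minimum stance duration, s (default 0.15).
#' @param merge_gap Maximum gap merged between candidate stances, s
#'   (default 0.05).
#' @param smooth_window Boxcar position-smoothing window, s (default 0.17);
#'   set to 0 to difference the raw positions.
#' @return data.frame of class `stance_events` with columns `foot`,
#'   `t_start`, `t_end`, `step_location`; zero rows (with a message) if no
#'   interval qualifies.
#' @export
detect_stances <- function(track, foot = NA_character_, v_thresh = 0.2,
                           min_duration = 0.15, merge_gap = 0.05,
                           smooth_window = 0.17) {
  stopifnot(is.data.frame(track), all(c("t", "y_ap") %in% names(track)),
            v_thresh > 0, min_duration >= 0, merge_gap >= 0)
  t <- track$t
  y <- track$y_ap
  n <- length(t)
  empty <- data.frame(foot = character(0), t_start = numeric(0),
                      t_end = numeric(0), step_location = numeric(0))
  class(empty) <- c("stance_events", "data.frame")
  if (n < 3) return(empty)
  dt <- stats::median(diff(t))

  ys <- y
  k <- max(1L, round(smooth_window / dt))
  if (k > 1L) {
    kern <- rep(1 / k, k)
    ys <- stats::filter(y, kern, sides = 2)
    # fall back to raw values where the filter is undefined at the edges
    ys[is.na(ys)] <- y[is.na(ys)]
    ys <- as.numeric(ys)
  }

  v <- numeric(n)
  v[2:(n - 1)] <- (ys[3:n] - ys[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  v[1] <- (ys[2] - ys[1]) / (t[2] - t[1])
  v[n] <- (ys[n] - ys[n - 1]) / (t[n] - t[n - 1])

  quiet <- abs(v) < v_thresh
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values], ends[r$values])
  if (nrow(iv) == 0L) {
    message("no stance interval found")
    return(empty)
  }

  # merge intervals separated by < merge_gap
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1L) {
    for (i in 2:nrow(iv)) {
      gap <- t[iv[i, 1]] - t[merged[nrow(merged), 2]]
      if (gap < merge_gap) merged[nrow(merged), 2] <- iv[i, 2]
      else merged <- rbind(merged, iv[i, ])
    }
  }
  dur <- t[merged[, 2]] - t[merged[, 1]]
  merged <- merged[dur >= min_duration, , drop = FALSE]
  if (nrow(merged) == 0L) {
    message("no stance interval of sufficient duration")
    return(empty)
  }

  out <- data.frame(
    foot = rep(foot, nrow(merged)),
    t_start = t[merged[, 1]],
    t_end = t[merged[, 2]],
    step_location = vapply(seq_len(nrow(merged)), function(i)
      stats::median(y[merged[i, 1]:merged[i, 2]]), numeric(1)))
  class(out) <- c("stance_events", "data.frame")
  out
}

#' Merge left- and right-foot stance events
#'
#' Interleaves the two per-foot event lists into one list ordered by stance
#' onset. Strict left/right alternation is expected of clean gait; a
#' violation (or an empty side) raises a warning but the merged, time-ordered
#' list is still returned.
#'
#' @param left,right `stance_events` data.frames as returned by
#'   [detect_stances()].
#' @return A single time-ordered `stance_events` data.frame.
#' @export
merge_bilateral <- function(left, right) {
  stopifnot(is.data.frame(left), is.data.frame(right))
  if (nrow(left) == 0L || nrow(right) == 0L)
    warning("one side has no stance events")
  out <- rbind(as.data.frame(left), as.data.frame(right))
  out <- out[order(out$t_start), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) > 1L && any(out$foot[-1L] == out$foot[-nrow(out)], na.rm = TRUE))
    warning("left/right stance alternation violated")
  class(out) <- c("stance_events", "data.frame")
  out
}

# detect + merge both feet of a trial record
.gc_trial_events <- function(record, v_thresh = 0.2, min_duration = 0.15,
                             merge_gap = 0.05, smooth_window = 0.17) {
  l <- detect_stances(record$tracks$left_foot, "left", v_thresh, min_duration,
                      merge_gap, smooth_window)
  r <- detect_stances(record$tracks$right_foot, "right", v_thresh,
                      min_duration, merge_gap, smooth_window)
  suppressWarnings(merge_bilateral(l, r))
}

#' Export stance events as CSV
#'
#' @param events `stance_events` data.frame.
#' @param path Output file.
#' @param trial_id Optional trial identifier column value.
#' @export
write_events <- function(events, path, trial_id = NA_character_) {
  out <- cbind(trial_id = trial_id, as.data.frame(events))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
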