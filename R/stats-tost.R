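#' Equivalence bound from the imposed modulation
#'
#' The equivalence margin is 25% of the imposed modulation magnitude,
#' acknowledging natural gait variability: 5 cm/s for the +/- 20 cm/s speed
#' modulations and 3.75 cm for the +/- 15 cm step-length modulations.
#'
#' @param task `"gait_speed"` or `"step_length"` (the tasks whose executed
#'   values are tested for equivalence against the cue).
#' @param modulation_magnitude Magnitude of the imposed modulation in the
#'   task's units; defaults to the task's canonical modulation (20 cm/s,
#'   15 cm).
#' @return The equivalence bound (same units as the modulation).
#' @examples
#' equivalence_bound("gait_speed")   # 5 cm/s
#' equivalence_bound("step_length")  # 3.75 cm
#' @export
equivalence_bound <- function(task = c("gait_speed", "step_length"),
                              modulation_magnitude = NULL) {
  task <- match.arg(task)
  if (is.null(modulation_magnitude))
    modulation_magnitude <- switch(task, gait_speed = 20, step_length = 15)
  stopifnot(modulation_magnitude > 0)
  0.25 * modulation_magnitude
}

#' Paired two one-sided tests (TOST) for equivalence
#'
#' Tests whether executed values are equivalent to imposed values within
#' `+/- bound`: alongside the conventional paired t-test, the lower test
#' asks whether the mean difference significantly exceeds `-bound` and the
#' upper test whether it falls significantly below `+bound`. Equivalence is
#' declared when both one-sided tests reject, i.e.
#' `max(p_lower, p_upper) < alpha`. Pairs with a missing member are dropped.
#'
#' @param executed,imposed Numeric vectors of equal length (>= 3 complete
#'   pairs).
#' @param bound Positive equivalence bound, same units as the data.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `tost_result`: a list with the sample size,
#'   mean and SD of the differences, the conventional t/df/p, both one-sided
#'   t/p, the bound, and the `equivalent` verdict. If the differences have
#'   zero variance the result is flagged `degenerate` and no test is run.
#' @examples
#' tost_paired(1:5, rep(0, 5), bound = 5)
#' @export
tost_paired <- function(executed, imposed, bound, alpha = 0.05) {
  stopifnot(length(executed) == length(imposed), bound > 0,
            alpha > 0, alpha < 1)
  ok <- stats::complete.cases(executed, imposed)
  d <- executed[ok] - imposed[ok]
  n <- length(d)
  if (n < 3) stop("need at least 3 complete pairs")
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1
  if (s == 0) {
    out <- list(n = n, mean_diff = m, sd_diff = 0, df = df,
                t_conventional = NA_real_, p_conventional = NA_real_,
                t_lower = NA_real_, p_lower = NA_real_,
                t_upper = NA_real_, p_upper = NA_real_,
                bound = bound, alpha = alpha, degenerate = TRUE,
                equivalent = abs(m) < bound)
    class(out) <- "tost_result"
    return(out)
  }
  se <- s / sqrt(n)
  t_conv <- m / se
  t_lower <- (m + bound) / se
  t_upper <- (m - bound) / se
  out <- list(
    n = n, mean_diff = m, sd_diff = s, df = df,
    t_conventional = t_conv,
    p_conventional = 2 * stats::pt(-abs(t_conv), df),
    t_lower = t_lower,
    p_lower = stats::pt(t_lower, df, lower.tail = FALSE),
    t_upper = t_upper,
    p_upper = stats::pt(t_upper, df),
    bound = bound, alpha = alpha, degenerate = FALSE)
  out$equivalent <- max(out$p_lower, out$p_upper) < alpha
  class(out) <- "tost_result"
  out
}

#' @export
print.tost_result <- function(x, digits = 3, ...) {
  cat(sprintf("Paired TOST, bound = +/-%g (n = %d)\n", x$bound, x$n))
  cat(sprintf("  mean diff %s (sd %s)\n",
              format(x$mean_diff, digits = digits),
              format(x$sd_diff, digits = digits)))
  if (isTRUE(x$degenerate)) {
    cat("  zero-variance differences: no test performed\n")
  } else {
    cat(sprintf("  t(%d) = %s, p = %s (conventional)\n", x$df,
                format(x$t_conventional, digits = digits),
                format.pval(x$p_conventional, digits = digits)))
    cat(sprintf("  TOST lower t = %s, p = %s; upper t = %s, p = %s\n",
                format(x$t_lower, digits = digits),
                format.pval(x$p_lower, digits = digits),
                format(x$t_upper, digits = digits),
                format.pval(x$p_upper, digits = digits)))
  }
  cat(sprintf("  equivalent: %s\n", if (isTRUE(x$equivalent)) "yes" else "no"))
  invisible(x)
}
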