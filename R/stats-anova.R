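#' Split-plot (mixed) repeated-measures ANOVA
#'
#' Fits the classical univariate split-plot decomposition for one
#' between-subjects factor and one or more fully-crossed within-subjects
#' factors, with one observation per subject and within-cell. The
#' between-subjects effect is tested against the subjects-within-groups
#' error; every within-involving effect is tested against its own
#' effect-by-subjects error stratum (sums of squares via [stats::aov()] with
#' an `Error(subject/...)` term).
#'
#' Sphericity is handled per error stratum: Greenhouse-Geisser epsilon is
#' computed from the pooled (across groups) covariance of the orthonormalized
#' within-effect contrasts, `eps_GG = tr(S)^2 / (d * tr(S^2))` with `d` the
#' contrast dimension; the Huynh-Feldt epsilon uses the
#' between-groups-adjusted form
#' `eps_HF = ((N - g + 1) d eps_GG - 2) / (d (N - g - d eps_GG))`, capped at
#' 1. Following the usual working rule, the Huynh-Feldt correction is applied
#' when `eps_GG` exceeds 0.750 and the Greenhouse-Geisser correction
#' otherwise; effects with a single within-contrast dimension are never
#' corrected. Corrected degrees of freedom multiply both numerator and
#' denominator df by the epsilon in use. Effect size is partial eta-squared,
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' Subjects with any missing within-cell are dropped (listwise deletion,
#' applied per analysis); duplicated subject-cell observations are an error —
#' aggregate upstream.
#'
#' @param data Long-format data.frame.
#' @param dv Name of the numeric response column.
#' @param subject Name of the subject-identifier column.
#' @param between Name of the between-subjects factor (>= 2 groups).
#' @param within Character vector of within-subjects factor names.
#' @param sphericity_threshold Greenhouse-Geisser epsilon above which the
#'   Huynh-Feldt correction is preferred (default 0.750).
#' @return A data.frame of class `anova_table`, one row per effect, with
#'   columns `effect`, `ss_effect`, `df_num`, `ss_error`, `df_den`, `F`,
#'   `epsilon_gg`, `epsilon_hf`, `correction` (none/GG/HF), `epsilon_used`,
#'   `df_num_corr`, `df_den_corr`, `p`, `eta_p_sq`.
#' @export
mixed_anova <- function(data, dv, subject, between, within,
                        sphericity_threshold = 0.750) {
  stopifnot(is.data.frame(data), length(within) >= 1)
  for (v in c(dv, subject, between, within))
    if (!v %in% names(data)) stop("column not found: ", v)

  d <- data[!is.na(data[[dv]]), c(dv, subject, between, within)]
  d[[subject]] <- factor(d[[subject]])
  d[[between]] <- factor(d[[between]])
  for (w in within) d[[w]] <- factor(d[[w]])
  d <- droplevels(d)

  k <- vapply(within, function(w) nlevels(d[[w]]), integer(1))
  n_cells <- prod(k)

  # one observation per subject x cell; listwise-delete incomplete subjects
  cell_of <- function(df) {
    idx <- lapply(within, function(w) as.integer(df[[w]]))
    id <- idx[[1L]]
    if (length(within) > 1L)
      for (j in 2:length(within))
        id <- id + (idx[[j]] - 1L) * prod(k[seq_len(j - 1L)])
    id
  }
  d$.cell <- cell_of(d)
  cell_labels <- do.call(paste, c(expand.grid(lapply(within, function(w)
    levels(d[[w]]))), sep = ":"))
  empty <- setdiff(seq_len(n_cells), unique(d$.cell))
  if (length(empty))
    stop("empty within-cell(s): ", paste(cell_labels[empty], collapse = ", "))
  counts <- table(d[[subject]], factor(d$.cell, levels = seq_len(n_cells)))
  if (any(counts > 1L)) {
    bad <- which(counts > 1L, arr.ind = TRUE)[1L, ]
    stop(sprintf("duplicated observation for subject %s, within-cell %s; aggregate first",
                 rownames(counts)[bad[1L]],
                 cell_labels[as.integer(colnames(counts)[bad[2L]])]))
  }
  complete <- rownames(counts)[rowSums(counts == 1L) == n_cells]
  dropped <- setdiff(levels(d[[subject]]), complete)
  if (length(dropped))
    message("listwise deletion: dropping ", length(dropped), " subject(s): ",
            paste(dropped, collapse = ", "))
  d <- droplevels(d[d[[subject]] %in% complete, , drop = FALSE])
  if (nlevels(d[[between]]) < 2) stop("between factor needs >= 2 groups")

  subj_lev <- levels(d[[subject]])
  N <- length(subj_lev)
  grp <- d[[between]][match(subj_lev, d[[subject]])]
  g <- nlevels(grp)
  if (N - g < 1) stop("no residual degrees of freedom for subjects within groups")

  bt <- function(x) paste0("`", x, "`")
  f <- stats::as.formula(paste0(
    bt(dv), " ~ ", bt(between), " * ", paste(bt(within), collapse = " * "),
    " + Error(", bt(subject), "/(", paste(bt(within), collapse = " * "), "))"))
  fit <- stats::aov(f, data = d)
  sm <- summary(fit)

  # subject x cell response matrix for the contrast covariances
  Y <- matrix(NA_real_, N, n_cells)
  Y[cbind(match(d[[subject]], subj_lev), d$.cell)] <- d[[dv]]

  onorm <- function(kk) {
    M <- stats::contr.helmert(kk)
    sweep(M, 2, sqrt(colSums(M^2)), "/")
  }
  stratum_eps <- function(S) {
    dS <- prod(k[S] - 1L)
    if (dS < 2L) return(list(d = dS, gg = NA_real_, hf = NA_real_))
    A <- lapply(within, function(w)
      if (w %in% S) onorm(k[[w]]) else matrix(1 / sqrt(k[[w]]), k[[w]], 1))
    C <- Reduce(kronecker, rev(A))
    M <- Y %*% C
    for (gg_lev in levels(grp)) {
      rows <- which(grp == gg_lev)
      M[rows, ] <- sweep(M[rows, , drop = FALSE], 2,
                         colMeans(M[rows, , drop = FALSE]))
    }
    S_pool <- crossprod(M) / (N - g)
    gg <- sum(diag(S_pool))^2 / (dS * sum(S_pool^2))
    hf <- ((N - g + 1) * dS * gg - 2) / (dS * (N - g - dS * gg))
    list(d = dS, gg = gg, hf = min(1, hf))
  }

  rows <- list()
  for (nm in names(sm)) {
    st <- sm[[nm]][[1L]]
    rn <- trimws(rownames(st))
    parts <- strsplit(sub("^Error: ", "", nm), ":", fixed = TRUE)[[1L]]
    S <- setdiff(parts, subject)
    if (identical(parts, "Within")) {
      if (any(st$Df > 0))
        stop("unexpected residual stratum: more than one observation per cell?")
      next
    }
    res <- which(rn == "Residuals")
    if (length(res) != 1L)
      stop("stratum ", nm, " lacks a residual term (empty cells?)")
    ss_err <- st$`Sum Sq`[res]
    df_err <- st$Df[res]
    eps <- stratum_eps(S)
    for (i in setdiff(seq_len(nrow(st)), res)) {
      ss <- st$`Sum Sq`[i]
      df1 <- st$Df[i]
      F <- (ss / df1) / (ss_err / df_err)
      if (length(S) == 0L || eps$d < 2L) {
        corr <- "none"; eps_used <- 1
      } else if (eps$gg > sphericity_threshold) {
        corr <- "HF"; eps_used <- eps$hf
      } else {
        corr <- "GG"; eps_used <- eps$gg
      }
      rows[[length(rows) + 1L]] <- data.frame(
        effect = rn[i], ss_effect = ss, df_num = df1,
        ss_error = ss_err, df_den = df_err, F = F,
        epsilon_gg = eps$gg, epsilon_hf = eps$hf,
        correction = corr, epsilon_used = eps_used,
        df_num_corr = eps_used * df1, df_den_corr = eps_used * df_err,
        p = stats::pf(F, eps_used * df1, eps_used * df_err, lower.tail = FALSE),
        eta_p_sq = ss / (ss + ss_err),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_subjects") <- N
  attr(out, "n_groups") <- g
  attr(out, "dropped_subjects") <- dropped
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, digits = 3, ...) {
  cat(sprintf("Split-plot ANOVA (%d subjects, %d groups)\n",
              attr(x, "n_subjects"), attr(x, "n_groups")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-30s F(%.2f, %.2f) = %s, p = %s, eta_p^2 = %s%s\n",
                x$effect[i], x$df_num_corr[i], x$df_den_corr[i],
                format(x$F[i], digits = digits),
                format.pval(x$p[i], digits = digits),
                format(x$eta_p_sq[i], digits = digits),
                if (x$correction[i] == "none") "" else
                  sprintf(" [%s, eps = %.3f]", x$correction[i],
                          x$epsilon_used[i])))
  }
  invisible(x)
}

#' Bonferroni-corrected pairwise post-hoc t-tests
#'
#' All pairwise paired t-tests between the levels of one within-subjects
#' factor, on participant-level marginal means (each subject's values are
#' averaged over the other factors first). P-values are multiplied by the
#' number of comparisons, `k (k - 1) / 2`, and capped at 1.
#'
#' @param data Long-format data.frame.
#' @param dv,subject As in [mixed_anova()].
#' @param factor_name Name of the factor whose levels are compared.
#' @param alpha Significance level used for the `significant` flag.
#' @return data.frame with one row per level pair: the level means, the
#'   paired mean difference, `t`, `df`, raw `p`, `p_bonf` and `significant`.
#' @export
bonferroni_posthoc <- function(data, dv, subject, factor_name, alpha = 0.05) {
  stopifnot(is.data.frame(data))
  for (v in c(dv, subject, factor_name))
    if (!v %in% names(data)) stop("column not found: ", v)
  d <- data[!is.na(data[[dv]]), ]
  lev <- levels(factor(d[[factor_name]]))
  if (length(lev) < 2) stop("factor needs >= 2 levels")
  marg <- tapply(d[[dv]], list(d[[subject]], d[[factor_name]]), mean)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    a <- marg[, pairs[1, j]]
    b <- marg[, pairs[2, j]]
    ok <- stats::complete.cases(a, b)
    tt <- stats::t.test(a[ok], b[ok], paired = TRUE)
    data.frame(level_a = pairs[1, j], level_b = pairs[2, j],
               n = sum(ok), mean_a = mean(a[ok]), mean_b = mean(b[ok]),
               mean_diff = mean(a[ok] - b[ok]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- pmin(1, out$p * m)
  out$significant <- out$p_bonf < alpha
  rownames(out) <- NULL
  out
}
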