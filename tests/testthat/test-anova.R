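# long-format toy data builders -----------------------------------------------
toy_long <- function(n_per_group, ka, kb = NULL, seed = 1,
                     effect = function(g, a, b) 0, subj_sd = 2, err_sd = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  subj <- sprintf("S%02d", seq_len(n))
  grp <- rep(c("G1", "G2"), each = n_per_group)
  cells <- if (is.null(kb)) expand.grid(A = paste0("a", 1:ka))
           else expand.grid(A = paste0("a", 1:ka), B = paste0("b", 1:kb))
  d <- merge(data.frame(participant_id = subj, headset = grp), cells)
  se <- rnorm(n, 0, subj_sd)
  b <- if (is.null(kb)) 1 else as.integer(factor(d$B))
  d$y <- se[match(d$participant_id, subj)] +
    effect(as.integer(factor(d$headset)), as.integer(factor(d$A)), b) +
    rnorm(nrow(d), 0, err_sd)
  d
}

test_that("split-plot sums of squares match the explicit-means brute force", {
  d <- toy_long(4, 2, 2, seed = 8,
                effect = function(g, a, b) 0.9 * a + 0.4 * a * b + 0.3 * g * a)
  a <- mixed_anova(d, "y", "participant_id", "headset", c("A", "B"))
  bf <- brute_force_ss(d, "y", "participant_id", "headset", "A", "B")
  get <- function(eff) a$ss_effect[a$effect == eff]
  expect_equal(get("headset"), unname(bf["G"]), tolerance = 1e-9)
  expect_equal(get("A"), unname(bf["A"]), tolerance = 1e-9)
  expect_equal(get("headset:A"), unname(bf["GA"]), tolerance = 1e-9)
  expect_equal(get("B"), unname(bf["B"]), tolerance = 1e-9)
  expect_equal(get("headset:B"), unname(bf["GB"]), tolerance = 1e-9)
  expect_equal(get("A:B"), unname(bf["AB"]), tolerance = 1e-9)
  expect_equal(get("headset:A:B"), unname(bf["GAB"]), tolerance = 1e-9)
  err <- function(eff) a$ss_error[a$effect == eff]
  expect_equal(err("headset"), unname(bf["subj_G"]), tolerance = 1e-9)
  expect_equal(err("A"), unname(bf["A_subj"]), tolerance = 1e-9)
  expect_equal(err("B"), unname(bf["B_subj"]), tolerance = 1e-9)
  expect_equal(err("A:B"), unname(bf["AB_subj"]), tolerance = 1e-9)
})

test_that("F equals t-squared for one-df within effects", {
  d <- toy_long(3, 2, seed = 3, effect = function(g, a, b) 1.2 * a)
  a <- mixed_anova(d, "y", "participant_id", "headset", "A")
  # group-centred paired contrast t, computed directly
  w <- reshape(d[, c("participant_id", "headset", "A", "y")],
               idvar = c("participant_id", "headset"), timevar = "A",
               direction = "wide")
  diffs <- w$y.a2 - w$y.a1
  grp <- w$headset
  centred <- diffs - ave(diffs, grp)
  N <- length(diffs); g <- 2
  t_stat <- mean(diffs) / sqrt(sum(centred^2) / (N - g) / N)
  expect_equal(a$F[a$effect == "A"], t_stat^2, tolerance = 1e-9)
  expect_equal(a$correction[a$effect == "A"], "none")
})

test_that("epsilons and corrected p-values agree with an independent multivariate fit", {
  d <- toy_long(5, 3, 3, seed = 7,
                effect = function(g, a, b) 1.5 * b + 0.8 * (a == 2) * b)
  a <- mixed_anova(d, "y", "participant_id", "headset", c("A", "B"))
  # independent route: car's repeated-measures MANOVA summary
  subj <- unique(d$participant_id)
  cells <- expand.grid(A = factor(paste0("a", 1:3)), B = factor(paste0("b", 1:3)))
  Y <- matrix(NA_real_, length(subj), nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- d$A == cells$A[i] & d$B == cells$B[i]
    Y[, i] <- d$y[sel][match(subj, d$participant_id[sel])]
  }
  grp <- factor(d$headset[match(subj, d$participant_id)])
  fit <- lm(Y ~ grp, contrasts = list(grp = "contr.sum"))
  # car warns when its uncapped HF epsilon exceeds 1; both sides cap it
  s <- suppressWarnings(
    summary(car::Anova(fit, idata = cells, idesign = ~ A * B, type = 3),
            multivariate = FALSE))
  ut <- s$univariate.tests
  adj <- s$pval.adjustments
  for (eff in c("A", "B", "A:B")) {
    mine <- a[a$effect == eff, ]
    expect_equal(mine$ss_effect, ut[eff, "Sum Sq"], tolerance = 1e-8)
    expect_equal(mine$ss_error, ut[eff, "Error SS"], tolerance = 1e-8)
    expect_equal(mine$F, ut[eff, "F value"], tolerance = 1e-8)
    expect_equal(mine$epsilon_gg, adj[eff, "GG eps"], tolerance = 1e-8)
    expect_equal(min(1, mine$epsilon_hf), min(1, adj[eff, "HF eps"]),
                 tolerance = 1e-8)
    p_ref <- if (mine$correction == "GG") adj[eff, "Pr(>F[GG])"]
             else adj[eff, "Pr(>F[HF])"]
    expect_equal(mine$p, unname(p_ref), tolerance = 1e-8)
  }
})

test_that("GG epsilon approaches 1 under sphericity and attains its lower bound", {
  # iid errors are spherical: at n = 200 the estimate sits within 0.05 of 1
  d <- toy_long(100, 3, seed = 11, subj_sd = 1, err_sd = 1)
  a <- mixed_anova(d, "y", "participant_id", "headset", "A")
  expect_gt(a$epsilon_gg[a$effect == "A"], 0.95)
  expect_equal(a$correction[a$effect == "A"], "HF")

  # rank-one within-subject variation is maximally non-spherical: eps = 1/(k-1)
  set.seed(2)
  n <- 10
  d2 <- expand.grid(participant_id = sprintf("S%02d", 1:n),
                    A = c("a1", "a2", "a3"), stringsAsFactors = FALSE)
  d2$headset <- rep(c("G1", "G2"), each = n / 2)[match(d2$participant_id,
                                                       sprintf("S%02d", 1:n))]
  slope <- rnorm(n)
  d2$y <- slope[match(d2$participant_id, sprintf("S%02d", 1:n))] *
    as.integer(factor(d2$A))
  a2 <- mixed_anova(d2, "y", "participant_id", "headset", "A")
  expect_equal(a2$epsilon_gg[a2$effect == "A"], 0.5, tolerance = 1e-9)
  expect_equal(a2$correction[a2$effect == "A"], "GG")
})

test_that("partial eta-squared is affine-invariant and bounded", {
  d <- toy_long(4, 3, seed = 9, effect = function(g, a, b) a)
  a1 <- mixed_anova(d, "y", "participant_id", "headset", "A")
  d2 <- d; d2$y <- 3.7 * d2$y + 11
  a2 <- mixed_anova(d2, "y", "participant_id", "headset", "A")
  expect_equal(a2$eta_p_sq, a1$eta_p_sq, tolerance = 1e-9)
  expect_equal(a2$F, a1$F, tolerance = 1e-9)
  expect_true(all(a1$eta_p_sq >= 0 & a1$eta_p_sq <= 1))
})

test_that("missing and malformed inputs are handled per the deletion policy", {
  d <- toy_long(3, 3, seed = 5)
  d$y[d$participant_id == "S02" & d$A == "a2"] <- NA
  expect_message(a <- mixed_anova(d, "y", "participant_id", "headset", "A"),
                 "listwise deletion.*S02")
  expect_equal(attr(a, "n_subjects"), 5L)

  dup <- rbind(d, d[1, ])
  expect_error(mixed_anova(dup, "y", "participant_id", "headset", "A"),
               "duplicated observation")

  d2 <- toy_long(3, 2, 2, seed = 5)
  gone <- d2[!(d2$A == "a2" & d2$B == "b2"), ]
  expect_error(mixed_anova(gone, "y", "participant_id", "headset",
                           c("A", "B")),
               "empty within-cell.*a2:b2")

  one_grp <- d; one_grp$headset <- "G1"
  expect_error(mixed_anova(one_grp, "y", "participant_id", "headset", "A"),
               ">= 2 groups")
})

test_that("post-hoc contrasts use Bonferroni over all level pairs", {
  d <- toy_long(10, 3, seed = 13, effect = function(g, a, b) 2 * a)
  ph <- bonferroni_posthoc(d, "y", "participant_id", "A")
  expect_equal(nrow(ph), 3L)
  expect_equal(ph$p_bonf, pmin(1, ph$p * 3), tolerance = 1e-12)

  # equal level means: half the subjects shifted up, half down, per level pair
  n <- 8
  d2 <- expand.grid(participant_id = sprintf("S%02d", 1:n), A = c("a1", "a2"),
                    stringsAsFactors = FALSE)
  d2$y <- ifelse(xor(d2$participant_id %in% sprintf("S%02d", 1:(n / 2)),
                     d2$A == "a2"), 1, -1)
  ph2 <- bonferroni_posthoc(d2, "y", "participant_id", "A")
  expect_equal(ph2$p_bonf, 1)
})

test_that("a +15 cm modulation with 3 cm noise is detected in nearly all runs", {
  hits <- 0L
  for (s in 1:200) {
    set.seed(s)
    n <- 20
    d <- expand.grid(participant_id = sprintf("S%02d", 1:n),
                     A = c("low", "mid", "high"), stringsAsFactors = FALSE)
    d$y <- 68 + 15 * (match(d$A, c("low", "mid", "high")) - 2) +
      rnorm(nrow(d), 0, 3)
    ph <- bonferroni_posthoc(d, "y", "participant_id", "A")
    hits <- hits + all(ph$significant)
  }
  expect_gte(hits / 200, 0.95)
})
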