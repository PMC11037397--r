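test_that("noise-free step-length trial executes the imposed step exactly", {
  p <- std_profile(step = 68)
  d <- enumerate_design(p, seed = 1)
  spec <- pick_spec(d, "step_length", "mid")
  rec <- simulate_walking_trial(spec, p, nz_noise())
  expect_true(all(abs(rec$truth$step_lengths_cm - 68) < 1e-9))
  expect_true(all(abs(diff(rec$truth$step_locations_m) - 0.68) < 1e-9))
})

test_that("noise-free speed trial walks the 3-9 m window at the imposed speed", {
  p <- std_profile(speed = 127)
  d <- enumerate_design(p, seed = 1)
  spec <- pick_spec(d, "gait_speed", "high")  # imposed 147 cm/s
  rec <- simulate_walking_trial(spec, p, nz_noise())
  tr <- rec$tracks$spine_shoulder
  t3 <- approx(tr$y_ap, tr$t, xout = 3, ties = "ordered")$y
  t9 <- approx(tr$y_ap, tr$t, xout = 9, ties = "ordered")$y
  expect_equal(t9 - t3, 6 / 1.47, tolerance = 1e-6)
})

test_that("speed-bird cue keeps the head level; floor cues pitch it down", {
  p <- std_profile(eye = 1.60)
  d <- enumerate_design(p, seed = 1)
  bird <- simulate_walking_trial(pick_spec(d, "gait_speed", "mid", "ar_bird"),
                                 p, nz_noise())
  expect_true(all(bird$tracks$headset$pitch == 0))
  floorcue <- simulate_walking_trial(pick_spec(d, "gait_speed", "mid", "ar"),
                                     p, nz_noise())
  expect_equal(unique(floorcue$tracks$headset$pitch),
               atan(1.60 / 2.4) * 180 / pi, tolerance = 1e-9)
})

test_that("static fixation pitch follows gaze-to-ground geometry", {
  p <- std_profile(eye = 1.60)
  rec <- simulate_static_trial(p, distances = c(10, 160, 280), noise = nz_noise())
  expect_equal(rec$truth$pitch_by_line$pitch_deg,
               atan(1.6 / c(0.1, 1.6, 2.8)) * 180 / pi, tolerance = 1e-9)
  # 45 degrees when the line distance equals eye height
  expect_equal(rec$truth$pitch_by_line$pitch_deg[2], 45)
  # pitch strictly decreases with distance
  full <- simulate_static_trial(p, noise = nz_noise())
  expect_true(all(diff(full$truth$pitch_by_line$pitch_deg) < 0))
})

test_that("truth stances alternate feet and never move backwards", {
  p <- std_profile()
  d <- enumerate_design(p, seed = 5)
  for (task in c("gait_speed", "step_length", "crossing_length")) {
    set.seed(99)
    rec <- simulate_walking_trial(pick_spec(d, task, "mid"), p, noise_config())
    feet <- rec$truth$step_feet
    expect_true(all(feet[-1] != feet[-length(feet)]))
    expect_true(all(diff(rec$truth$step_locations_m) > 0))
  }
})

test_that("crossing trials lengthen the crossing steps by depth plus margins", {
  p <- std_profile()
  d <- enumerate_design(p, seed = 1)
  nz <- nz_noise()
  for (mod in c("low", "mid", "high")) {
    spec <- pick_spec(d, "crossing_length", mod)
    rec <- simulate_walking_trial(spec, p, nz)
    depth <- spec$imposed_value
    expect_equal(rec$truth$crossing_init_cm,
                 depth + 2 * 100 * nz$crossing_margin_init, tolerance = 1e-6)
    expect_equal(rec$truth$crossing_halfway_cm,
                 depth + 2 * 100 * nz$crossing_margin_halfway, tolerance = 0.5)
  }
})

test_that("cohort simulation is reproducible and stable under growth", {
  cfg <- cohort_config(n_participants = 3, seed = 12)
  a <- simulate_cohort(cfg, tasks = "gait_speed")
  b <- simulate_cohort(cfg, tasks = "gait_speed")
  expect_identical(lapply(a$records, `[[`, "truth"),
                   lapply(b$records, `[[`, "truth"))
  expect_identical(a$profiles, b$profiles)
  # adding participants does not reshuffle earlier ones
  big <- simulate_cohort(cohort_config(n_participants = 5, seed = 12),
                         tasks = "gait_speed")
  expect_identical(big$profiles[1:3, ], a$profiles)
  expect_identical(big$records[[1]]$truth, a$records[[1]]$truth)
})

test_that("between-subject baseline spread matches the configured SD", {
  cfg <- cohort_config(n_participants = 600, between_sd_speed = 16, seed = 5)
  sim <- simulate_cohort(cfg, tasks = character(0))
  expect_equal(nrow(sim$profiles), 600L)
  expect_lt(abs(sd(sim$profiles$baseline_speed) - 16), 1.5)
  expect_lt(abs(mean(sim$profiles$baseline_speed) - 127), 2.5)
})

test_that("the generator is unbiased: executed equals imposed on average", {
  cfg <- cohort_config(n_participants = 60, seed = 21)
  sim <- simulate_cohort(cfg, tasks = "step_length")
  err <- vapply(sim$records, function(r)
    mean(r$truth$step_lengths_cm) - r$spec$imposed_value, numeric(1))
  expect_lt(abs(mean(err)), 0.5)
})

test_that("implausible step-length configurations are rejected", {
  p <- std_profile(step = 40)
  d <- enumerate_design(p, seed = 1)
  spec <- pick_spec(d, "step_length", "low")  # imposed 25 cm
  expect_error(simulate_walking_trial(spec, p, noise_config(step_exec_sd = 10)),
               "non-positive steps")
  static_spec <- as.list(d[d$task == "static", ][1, ])
  expect_error(simulate_walking_trial(static_spec, p), "static")
})

test_that("per-condition adherence-bias map overrides the scalar default", {
  p <- std_profile()
  d <- enumerate_design(p, seed = 1)
  spec <- pick_spec(d, "step_length", "mid")
  bias_map <- data.frame(task = "step_length", content = NA, modulation = "mid",
                         bias = 4)
  cfg <- cohort_config(adherence_bias = bias_map, noise = nz_noise())
  rec <- simulate_walking_trial(spec, p, cfg$noise,
                                bias = gaitcue:::.gc_bias_for(spec,
                                                              cfg$adherence_bias,
                                                              0))
  expect_equal(unique(round(rec$truth$step_lengths_cm, 9)),
               spec$imposed_value + 4)
})
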