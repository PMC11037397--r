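---
title: "Simulating and analysing cued-walking experiments with gaitcue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing cued-walking experiments with gaitcue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(gaitcue)
```

## The problem this package addresses

External visual cues — lines or stepping targets on the floor, or holograms
rendered in an augmented-reality (AR) headset — help people with Parkinson's
disease regulate their gait. A typical laboratory protocol walks each
participant along an instrumented 10 m walkway under cues that *impose* a
gait parameter: a speed cue moving at the participant's preferred speed
± 20 cm/s, stepping targets spaced at the preferred step length ± 15 cm, or
flat obstacles 15/30/45 cm deep that must be crossed at gait initiation and
at the 5 m mark. Two questions follow:

1. **Modulation** — do executed gait parameters track the imposed levels?
   (split-plot ANOVA with Headset as the between-subjects factor and
   Content/Modulation — plus Location for obstacle crossing — within
   subjects, Bonferroni post-hocs);
2. **Equivalence** — is what participants execute statistically *equivalent*
   to what the cue imposes? (paired two one-sided tests, TOST, with bounds at
   25% of the modulation: ± 5 cm/s for speed, ± 3.75 cm for step length).

A secondary question concerns head orientation: floor-anchored cues force
the head down by an angle set by gaze geometry, `atan(eye_height /
distance)`, which matters because AR headsets have a limited vertical field
of view; an eye-height "speed bird" cue avoids the downward pitch entirely.

Raw participant kinematics from such experiments are generally not shareable.
`gaitcue` therefore pairs the full analysis chain with a synthetic-data
generator that emulates the experiment with known ground truth, so every
stage — event detection, parameter extraction, equivalence testing, the
ANOVA machinery — can be validated by parameter recovery rather than by
eyeballing.

## The synthetic generator

`simulate_walking_trial()` builds per-trial tracks for three body points
(spine-shoulder, left and right foot; anterior–posterior coordinate in
meters along the walkway) and a headset (position + pitch), sampled at 30 Hz
(the convention of Kinect-v2-based walkways; configurable). A trial is
1.2 s of quiet standing, gait initiation, then steady walking past 9 m:

* **Footfalls.** Step lengths are drawn per step. For step-length trials the
  target is `imposed + adherence_bias + N(0, step_exec_sd)`; for speed
  trials steps stay at the preferred length while the executed speed is
  `imposed + adherence_bias + N(0, speed_exec_sd)`; for crossing trials the
  crossing step is lengthened to clear the obstacle depth plus a clearance
  margin on each side. Footfall times follow from executed speed and step
  length.
* **Within-step kinematics.** Feet are stationary during stance (plus
  marker jitter) and advance along a smoothstep profile during swing. Swing
  lasts 0.4 s but never more than 45% of the stride, so short-stepping,
  high-cadence walkers retain a detectable stance phase. Only step
  locations and timing matter downstream, so no richer limb model is
  attempted. The spine-shoulder point passes through the mid-feet position
  at each footfall, which makes its mean velocity equal the executed speed.
* **Head pitch.** For floor cues, pitch is `atan(eye_height /
  preview_distance)` plus jitter; the default preview distance of 2.4 m
  puts the noise-free pitch near 34° for a 1.6 m eye height, the scale
  observed with floor-anchored cues. For the eye-height bird cue the
  noise-free pitch is 0°.
* **Cohort.** `simulate_cohort()` draws preferred speed (127 ± 16 cm/s) and
  step length (68 ± 10 cm) from correlated normals (r = 0.85; uncorrelated
  draws produce physiologically implausible cadences), alternates headsets,
  and derives one RNG stream per participant and trial from the master seed,
  so earlier participants are unchanged when a cohort grows.

Defaults that are free parameters of the generator, with their rationale:

| parameter | default | why |
|---|---|---|
| `marker_noise_sd` | 5 mm | typical markerless-tracking jitter |
| `step_exec_sd` | 2 cm | within-trial precision of cued stepping |
| `speed_exec_sd` | 4 cm/s | within-trial speed-following precision |
| `adherence_bias` | 0 | unbiased execution unless a scenario sets it |
| `pitch_noise_sd` | 2° | head micro-movements during fixation |
| `preview_distance` | 2.4 m | gaze point ahead of the feet for floor cues |
| crossing margins | 20 cm (init) / 28 cm (halfway) per side | noise-free crossing steps of ~70 and ~86 cm averaged over depths, the scale seen at the two obstacle locations; the larger halfway margin reflects crossing from ongoing gait rather than from standstill and is what makes the Location effect recoverable |

During imposed-step-length walking the simulated walker slows in proportion
to the square root of the step-length ratio, reflecting partial cadence
adaptation; without it, short imposed steps at preserved speed force
unrealistic cadences.

What the generator deliberately does **not** emulate: mediolateral and
vertical kinematics beyond a schematic swing arc, freezing episodes,
fatigue or learning across trials, sensor dropouts (missingness arises only
when extraction preconditions fail), and modulation-dependent head pitch.
Passing recovery tests on synthetic data therefore validates the *analysis
chain*, not the biomechanical fidelity of any real dataset.

## Event detection and parameter extraction

`detect_stances()` computes the anterior–posterior velocity by central
differences after a short boxcar smoothing of position (default 0.17 s —
raw 30 Hz differentiation of 5 mm jitter would otherwise fragment stances at
the 0.2 m/s threshold); maximal sub-threshold intervals separated by less
than 0.05 s are merged and kept if at least 0.15 s long. The step location
is the median position within the stance, which is robust to edge effects
of the smoothing. All thresholds are exposed.

The outcome measures follow fixed operational definitions, with windows as
closed intervals and walkway coordinates continuous from the start line:

* gait speed = 600 cm / (t(9 m) − t(3 m)) of the spine-shoulder point,
  crossing times linearly interpolated;
* step length = median difference of consecutive (bilaterally pooled,
  time-ordered) step locations when both ends lie in [1, 9] m;
* crossing step length at initiation = first step location minus the median
  standing position of the leading limb; halfway = first location past 5 m
  minus the last before 5 m;
* head pitch (walking) = median pitch while the headset itself is between
  3 and 7 m, minus the straight-ahead baseline; the baseline comes from the
  static trial's straight-ahead segments by default (a per-walk calibration
  could be substituted via the `baseline_pitch` argument);
* head pitch (static) = per-line median within the 5 s fixation window
  minus the pooled start/end straight-ahead median.

A parameter that cannot be computed is returned as `NA` with a recorded
reason; the pipeline reports each such trial in its accounting and excludes
it analysis-by-analysis — participants are dropped per ANOVA (listwise
within an analysis), never globally.

## The statistical layer

`tost_paired()` implements the paired TOST: with differences `d = executed −
imposed`, `t_lower = (mean(d) + bound) / SE` is tested against the upper
tail and `t_upper = (mean(d) − bound) / SE` against the lower tail of
Student's t with n − 1 df; equivalence requires both one-sided tests to
reject at `alpha`. Zero-variance differences are flagged degenerate rather
than tested. `equivalence_bound()` encodes the 25%-of-modulation rule.

`mixed_anova()` fits the univariate split-plot decomposition (sums of
squares via `aov()` error strata). Sphericity handling is authored here:
per within-effect stratum, Greenhouse–Geisser epsilon comes from the pooled
covariance of orthonormalized effect contrasts, `(tr S)^2 / (d tr S^2)`;
Huynh–Feldt epsilon uses the between-groups-adjusted form
`((N − g + 1) d ε_GG − 2) / (d (N − g − d ε_GG))`, capped at 1. The working
rule applies Huynh–Feldt when `ε_GG > 0.750` and Greenhouse–Geisser
otherwise; single-df within effects are never corrected. No Mauchly test is
computed — the epsilon itself drives the policy. Effect size is partial
eta-squared. Unequal group sizes are accepted (sequential SS on data that
are balanced within subjects); empty within-cells and duplicated
subject-cell observations are hard errors. `bonferroni_posthoc()` averages
each subject over non-target factors before pairing — the marginalization
scheme is a documented choice, not the only defensible one.

The head-orientation ANOVA for the speed task uses all three content levels
(both speed lines and the bird), a 2 × 3 × 3 design, since the bird
condition is precisely the one that changes head pitch.

## Numerical and design choices

* Tie and boundary samples are included (closed windows); step-location
  medians use raw, unsmoothed positions.
* Noise-free trials are exact: with all SDs and biases zero, extraction
  returns the imposed values to floating-point accuracy, which the test
  suite asserts at < 0.5% relative error.
* One value per participant and condition enters the statistics (each
  condition is walked once, as in the motivating protocol); with repeats,
  aggregate to means before `mixed_anova()`, which refuses duplicated
  cells.
* The trial count is reported explicitly by the pipeline accounting: 30
  cued walking trials per participant, of which the six hurdle-height
  trials are simulated but excluded from analysis.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(cohort_config(n_participants = 21, seed = 1))
bundle <- run_experiment(cfg)
bundle$tost[, c("task", "content", "modulation", "mean_diff", "equivalent")]
bundle$anovas$gait_speed
report(bundle, "results/run1")
```

With the default (unbiased) generator all nine step-length conditions come
out equivalent and the Modulation main effects are overwhelming; setting a
condition-specific `adherence_bias` near the 5 cm/s bound makes the slow
speed conditions flip to non-equivalence, mirroring how real walkers tend
to overshoot slow speed cues. Problem sizes used by the validation suite —
500 null replicates at 12 subjects for the type-I calibration, 100 cohorts
of 21 for the recovery checks — are the package's chosen compromise between
Monte-Carlo resolution and a test suite that runs in minutes.

## Known limitations

* The stance detector is validated against the generator's own truth, not
  against an external gold-standard event detector.
* Sequential (Type I) sums of squares are used; with unequal group sizes
  and non-orthogonal between-effects these differ from Type III for the
  between factor (within-effects are unaffected in these balanced-within
  designs).
* The generator's head pitch is constant per trial content; real walkers
  show modulation-dependent pitch that this version does not emulate.
* Real-data ingestion is limited to the documented trial-record CSV + JSON
  contract (`read_trial_record()`); adapters must supply the standing
  segment and fixation annotations the extractors rely on.
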