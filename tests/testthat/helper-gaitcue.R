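# shared fixtures and independent oracles

# noise-free simulator settings
nz_noise <- function(...) {
  noise_config(marker_noise_sd = 0, step_exec_sd = 0, speed_exec_sd = 0,
               pitch_noise_sd = 0, ...)
}

std_profile <- function(id = "P01", speed = 127, step = 68, eye = 1.60,
                        headset = "HL2", lead = "right") {
  participant_profile(id, speed, step, eye, headset, lead)
}

# pick one trial spec out of a design table
pick_spec <- function(design, task, modulation, content = NULL) {
  d <- design[design$task == task & design$modulation == modulation, ]
  if (!is.null(content)) d <- d[d$content == content, ]
  as.list(d[1L, ])
}

# independent brute-force split-plot sums of squares from explicit cell and
# marginal means; one between factor G, within factors A and B, balanced,
# one observation per subject x cell. Returns the per-effect SS.
brute_force_ss <- function(df, dv, subject, G, A, B) {
  y <- df[[dv]]
  m <- mean(y)
  avg <- function(...) ave(y, ..., FUN = mean)
  m_g <- avg(df[[G]]);  m_s <- avg(df[[subject]])
  m_a <- avg(df[[A]]);  m_b <- avg(df[[B]])
  m_ga <- avg(df[[G]], df[[A]]); m_gb <- avg(df[[G]], df[[B]])
  m_ab <- avg(df[[A]], df[[B]])
  m_gab <- avg(df[[G]], df[[A]], df[[B]])
  m_sa <- avg(df[[subject]], df[[A]]); m_sb <- avg(df[[subject]], df[[B]])
  eff <- list(
    G = m_g - m,
    subj_G = m_s - m_g,
    A = m_a - m,
    GA = m_ga - m_g - m_a + m,
    A_subj = m_sa - m_s - m_ga + m_g,
    B = m_b - m,
    GB = m_gb - m_g - m_b + m,
    B_subj = m_sb - m_s - m_gb + m_g,
    AB = m_ab - m_a - m_b + m,
    GAB = m_gab - m_ga - m_gb - m_ab + m_g + m_a + m_b - m)
  eff$AB_subj <- y - m - Reduce(`+`, eff)
  vapply(eff, function(e) sum(e^2), numeric(1))
}

# the published TOST table this analysis layout mirrors: per condition the
# printed conventional t, both one-sided t values and the rounded means
printed_tost_table <- function() {
  tab <- read.csv(text = '
task,content,modulation,imposed,executed,t,t_lower,t_upper,lower_sign_typo
gait_speed,real_world,low,107,112,3.85,7.87,-0.16,FALSE
gait_speed,real_world,mid,127,132,2.81,5.90,-0.28,FALSE
gait_speed,real_world,high,147,146,-0.36,1.49,-2.21,FALSE
gait_speed,ar,low,107,109,0.95,3.93,-2.03,FALSE
gait_speed,ar,mid,127,131,2.56,5.67,-0.54,FALSE
gait_speed,ar,high,147,142,-1.85,-0.19,-3.51,FALSE
gait_speed,ar_bird,low,107,111,3.66,7.82,-0.50,FALSE
gait_speed,ar_bird,mid,127,132,2.76,5.45,0.06,FALSE
gait_speed,ar_bird,high,147,147,-0.06,-1.51,-1.51,TRUE
step_length,real_world,low,52.8,52.5,-2.22,28.02,-32.46,FALSE
step_length,real_world,mid,68.0,67.8,-1.97,27.91,-31.85,FALSE
step_length,real_world,high,83.4,83.3,-1.75,20.69,-24.18,FALSE
step_length,ar,low,52.8,52.6,-0.93,16.37,-18.22,FALSE
step_length,ar,mid,68.0,67.8,-1.16,16.44,-18.76,FALSE
step_length,ar,high,82.8,82.5,-1.03,10.90,-12.96,FALSE
step_length,ar_sound,low,53.0,52.9,-0.34,19.42,-20.11,FALSE
step_length,ar_sound,mid,68.0,67.5,-2.30,14.15,-18.75,FALSE
step_length,ar_sound,high,82.9,82.7,-1.04,12.84,-14.92,FALSE
', stringsAsFactors = FALSE)
  tab$bound <- ifelse(tab$task == "gait_speed", 5, 3.75)
  tab
}
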