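#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate a healthy middle-aged population (ages 35-56, both
#' sexes) measured by calibrated carotid-type tonometry and Doppler-like
#' aortic flow. Hemodynamic parameters are drawn as independent truncated
#' normals with sex-specific means where population tables report a clear
#' sex difference (stroke volume, characteristic impedance); no
#' between-parameter covariance is imposed. Each `c(mean, sd)` pair below
#' is accompanied by `c(lo, hi)` truncation bounds in `trunc`.
#'
#' The forward model per subject is a 3-element Windkessel run in the
#' generative direction: a half-sine inflow of duration ED and area SV
#' drives `Ca dPwk/dt = Q - Pwk/Rp`, the forward pressure is
#' `Pwk + Zc * Q`, and a single reflected wave is added as a delayed,
#' scaled echo of the pulsatile forward pressure
#' (`P = Pf + gamma * shift(Pf - mean, tau_r)`). Ground-truth forward and
#' backward waves are defined in closed loop by wave separation of the
#' clean pressure/flow pair at the true Zc. Channels are then noised
#' (additive white Gaussian; flow noise restricted to the systolic lobe and
#' clamped non-negative) and the pressure re-calibrated to the clean
#' brachial mean/diastolic values, as a tonometer trace would be.
#'
#' @param n number of subjects.
#' @param seed integer master seed; per-subject substreams are derived by
#'   counter so subject `i` is identical whatever `n` is.
#' @param age_range inclusive integer age range (years).
#' @param male_frac probability that a subject is male.
#' @param fs waveform sampling rate (Hz).
#' @param hr_bpm,map_mmHg heart rate and mean pressure draws.
#' @param sv_ml_male,sv_ml_female stroke volume draws (ml).
#' @param zc_male,zc_female characteristic impedance draws (mmHg·s/ml).
#' @param ca_ml_mmhg arterial compliance draws (ml/mmHg).
#' @param gamma reflection coefficient draws (dimensionless, in [0, 1)).
#' @param tau_r_s reflection return-time draws (s).
#' @param height_cm_male,height_cm_female,bmi demographic draws.
#' @param noise_p_mmHg,noise_q_ml_s channel noise SDs.
#' @param ed_coef ejection duration scale: `ED = ed_coef * sqrt(T)`.
#' @param cfpwv reference-path carotid-femoral PWV emulation: generated as
#'   `intercept + slope * PWV_wh(Zc_true) + N(0, sd)` where `PWV_wh` is the
#'   water-hammer velocity at the true Zc (an arbitrary but plausible
#'   coupling; see the methods vignette).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n = 50L, seed = 1L,
                          age_range = c(35L, 56L), male_frac = 0.4775,
                          fs = 250,
                          hr_bpm = c(62, 8), map_mmHg = c(92, 9),
                          sv_ml_male = c(86, 14), sv_ml_female = c(69, 11),
                          zc_male = c(0.101, 0.030), zc_female = c(0.116, 0.035),
                          ca_ml_mmhg = c(1.7, 0.35),
                          gamma = c(0.30, 0.10), tau_r_s = c(0.080, 0.015),
                          height_cm_male = c(178, 7), height_cm_female = c(165, 6.5),
                          bmi = c(25.5, 3.8),
                          noise_p_mmHg = 1.0, noise_q_ml_s = 5.0,
                          ed_coef = 0.37,
                          cfpwv = list(intercept = 4.0, slope = 0.35, sd = 0.9)) {
  cfg <- list(
    n = as.integer(n), seed = as.integer(seed),
    age_range = as.integer(age_range), male_frac = male_frac, fs = fs,
    hr_bpm = hr_bpm, map_mmHg = map_mmHg,
    sv_ml_male = sv_ml_male, sv_ml_female = sv_ml_female,
    zc_male = zc_male, zc_female = zc_female,
    ca_ml_mmhg = ca_ml_mmhg, gamma = gamma, tau_r_s = tau_r_s,
    height_cm_male = height_cm_male, height_cm_female = height_cm_female,
    bmi = bmi,
    noise_p_mmHg = noise_p_mmHg, noise_q_ml_s = noise_q_ml_s,
    ed_coef = ed_coef, cfpwv = cfpwv,
    trunc = list(
      hr_bpm = c(45, 95), map_mmHg = c(70, 120),
      sv_ml_male = c(50, 130), sv_ml_female = c(40, 110),
      zc_male = c(0.04, 0.22), zc_female = c(0.04, 0.24),
      ca_ml_mmhg = c(0.9, 2.8), gamma = c(0.02, 0.60),
      tau_r_s = c(0.045, 0.130),
      height_cm_male = c(155, 200), height_cm_female = c(145, 190),
      bmi = c(17, 42)
    )
  )
  if (cfg$n < 1L) validation_error("n must be >= 1")
  if (noise_p_mmHg < 0 || noise_q_ml_s < 0)
    validation_error("noise SDs must be non-negative")
  if (gamma[1] < 0 || gamma[1] >= 1)
    validation_error("reflection coefficient mean must lie in [0, 1)")
  structure(cfg, class = "cohort_config")
}

# truncated-normal draw by rejection with a redraw cap
rtrunc_norm <- function(mean_sd, bounds, n = 1L) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:100) {
      x <- stats::rnorm(1, mean_sd[1], mean_sd[2])
      if (x >= bounds[1] && x <= bounds[2]) break
      if (try == 100)
        validation_error("infeasible parameter draw: redraw cap exceeded")
    }
    out[i] <- x
  }
  out
}

draw_param <- function(cfg, name) rtrunc_norm(cfg[[name]], cfg$trunc[[name]])

# counter-derived per-subject seed, independent of cohort size
subject_seed <- function(seed, i) {
  s <- (as.numeric(seed) * 48271 + as.numeric(i) * 2246822519) %% 2147483647
  as.integer(max(1, s))
}

#' Simulate one subject with known ground truth
#'
#' @param cfg a [cohort_config()].
#' @param i subject counter (1-based); determines the RNG substream.
#' @return A list with `subject` (a subject record: demographics, brachial
#'   pressures, `pressure` and `flow` beats, `cfpwv`) and `truth` (a
#'   one-row data.frame of generator ground truth: `zc`, `ca`, `rp`,
#'   `svr`, `sv`, `gamma`, `tau_r`, `ed`, `hr`, `map`, `pf_amp`, `pb_amp`,
#'   `rm` — the wave amplitudes from closed-loop wave separation of the
#'   clean channels at the true Zc).
#' @export
simulate_subject <- function(cfg, i = 1L) {
  set.seed(subject_seed(cfg$seed, i))
  sex <- if (stats::runif(1) < cfg$male_frac) "male" else "female"
  age <- sample(seq(cfg$age_range[1], cfg$age_range[2]), 1)
  hr <- draw_param(cfg, "hr_bpm")
  map_t <- draw_param(cfg, "map_mmHg")
  sv_t <- if (sex == "male") draw_param(cfg, "sv_ml_male")
          else draw_param(cfg, "sv_ml_female")
  zc_t <- if (sex == "male") draw_param(cfg, "zc_male")
          else draw_param(cfg, "zc_female")
  ca_t <- draw_param(cfg, "ca_ml_mmhg")
  gam <- draw_param(cfg, "gamma")
  tau_r <- draw_param(cfg, "tau_r_s")
  height <- if (sex == "male") draw_param(cfg, "height_cm_male")
            else draw_param(cfg, "height_cm_female")
  bmi <- draw_param(cfg, "bmi")

  per <- 60 / hr
  n <- round(per * cfg$fs)
  dt <- per / n  # snap dt so the grid covers exactly one period
  ed <- cfg$ed_coef * sqrt(per)

  # total resistance from the drawn steady state; peripheral = SVR - Zc
  qbar_t <- sv_t / per
  svr_t <- map_t / qbar_t
  rp_t <- svr_t - zc_t
  if (rp_t <= zc_t)
    validation_error("infeasible draw: peripheral resistance below Zc")

  t <- (seq_len(n) - 1) * dt
  qpk <- pi * sv_t / (2 * ed)
  q_clean <- ifelse(t < ed, qpk * sin(pi * t / ed), 0)

  ctrl <- wk_control()
  res <- wk_steady(function(w, keep)
    wk_cycle_forward(w, q_clean, dt, ca_t, rp_t, keep),
    map_t, ctrl)
  p_fwd <- res$pwk + zc_t * q_clean
  echo <- gam * (circshift(p_fwd, round(tau_r / dt)) - mean(p_fwd))
  p_clean <- p_fwd + echo

  map_emp <- mean(p_clean)   # brachial cuff readings = clean MAP / DBP
  dbp_emp <- min(p_clean)

  # closed-loop ground truth for the wave-separation parameters
  sv_emp <- mean(q_clean) * per
  ws <- separate_waves(pressure_beat(p_clean, dt, ed = ed),
                       flow_beat(q_clean, dt, ed = ed), zc_t)

  p_noisy <- p_clean + stats::rnorm(n, 0, cfg$noise_p_mmHg)
  q_noisy <- q_clean
  lobe <- q_clean > 0
  q_noisy[lobe] <- pmax(0, q_clean[lobe] + stats::rnorm(sum(lobe), 0, cfg$noise_q_ml_s))

  pwv_wh <- pwv_from_zc(zc_t, age, sex)
  cfpwv <- cfg$cfpwv$intercept + cfg$cfpwv$slope * pwv_wh +
    stats::rnorm(1, 0, cfg$cfpwv$sd)

  subject <- list(
    id = sprintf("S%04d", i), age = age, sex = sex,
    height_cm = height, bmi = bmi,
    map_mmHg = map_emp, dbp_mmHg = dbp_emp, hr_bpm = hr,
    cfpwv_ms = cfpwv,
    pressure = calibrate_pressure(p_noisy, map_emp, dbp_emp, dt = dt),
    flow = flow_beat(q_noisy, dt, ed = ed)
  )
  class(subject) <- "subject_record"
  truth <- data.frame(
    id = subject$id, age = age, sex = sex,
    zc = zc_t, ca = ca_t, rp = rp_t, svr = map_emp / (sv_emp / per),
    sv = sv_emp, gamma = gam, tau_r = tau_r, ed = ed, hr = hr,
    map = map_emp, dbp = dbp_emp,
    pf_amp = ws$pf_amp, pb_amp = ws$pb_amp, rm = ws$rm,
    cfpwv = cfpwv, pwv_wh = pwv_wh,
    stringsAsFactors = FALSE
  )
  list(subject = subject, truth = truth)
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s: %s, %d y, MAP %.0f / DBP %.0f mmHg, HR %.0f bpm%s\n",
              x$id, x$sex, x$age, x$map_mmHg, x$dbp_mmHg, x$hr_bpm,
              if (is.null(x$flow)) " (pressure only)" else ""))
  invisible(x)
}

#' Simulate a synthetic cohort
#'
#' Generates `cfg$n` subjects with ground truth; optionally writes the
#' cohort to disk in the plain-text interchange layout (per-beat waveform
#' CSVs with columns `t_s,value`, per-subject metadata JSON, a manifest
#' CSV and a ground-truth CSV) via [write_cohort()].
#'
#' @param cfg a [cohort_config()].
#' @param dir optional output directory.
#' @return An object of class `cohort`: list with `subjects` (list of
#'   subject records), `truth` (data.frame), `config`.
#' @export
simulate_cohort <- function(cfg = cohort_config(), dir = NULL) {
  sims <- lapply(seq_len(cfg$n), function(i) simulate_subject(cfg, i))
  cohort <- structure(
    list(subjects = lapply(sims, `[[`, "subject"),
         truth = do.call(rbind, lapply(sims, `[[`, "truth")),
         config = cfg),
    class = "cohort"
  )
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  n <- length(x$subjects)
  cat(sprintf("<cohort> %d subjects (%d male / %d female), ages %d-%d\n",
              n, sum(x$truth$sex == "male"), sum(x$truth$sex == "female"),
              min(x$truth$age), max(x$truth$age)))
  invisible(x)
}
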