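#' Measured-arm analysis of one subject
#'
#' The reference pathway: requires paired pressure and flow. Both beats are
#' resampled to the canonical 128-sample grid, the pressure is (re-)
#' calibrated to the brachial mean/diastolic values, and the harmonic
#' impedance spectrum yields SVR (0 Hz), the characteristic impedance
#' (mean modulus of harmonics 3-10 after outlier exclusion) and the wave
#' separation parameters.
#'
#' @param subject a subject record (see [simulate_subject()] /
#'   [read_cohort()]) with a non-null `flow`.
#' @param n_harm harmonics carried in the impedance spectrum.
#' @param n_grid canonical samples per cycle.
#' @return One-row data.frame: `id`, `sv`, `svr`, `zc`, `pf_amp`,
#'   `pb_amp`, `rm`, `pp`, `hr`, `n_excluded`.
#' @export
analyze_measured <- function(subject, n_harm = 10L, n_grid = 128L) {
  if (is.null(subject$flow))
    validation_error("measured arm needs a flow beat")
  p <- resample_beat(
    calibrate_pressure(subject$pressure, subject$map_mmHg, subject$dbp_mmHg),
    n_grid)
  q <- resample_beat(subject$flow, n_grid)
  per <- beat_period(p)
  qbar <- mean(q$samples)
  sv <- qbar * per
  ps <- harmonic_decompose(p, n_harm)
  qs <- harmonic_decompose(q, n_harm)
  z <- input_impedance(ps, qs)
  zc <- characteristic_impedance(z)
  ws <- separate_waves(p, q, zc$zc)
  data.frame(
    id = subject$id, sv = sv, svr = svr(beat_map(p), qbar), zc = zc$zc,
    pf_amp = ws$pf_amp, pb_amp = ws$pb_amp, rm = ws$rm,
    pp = beat_pp(p), hr = 60 / per, n_excluded = length(zc$excluded),
    stringsAsFactors = FALSE
  )
}

#' Model-arm (pressure-only) analysis of one subject
#'
#' Synthesizes the aortic flow from the calibrated pressure beat via the
#' Windkessel inversion of [synthesize_flow()], then derives the same
#' parameter set as the measured arm plus the Zc-derived pulse wave
#' velocity.
#'
#' @param subject a subject record; only its pressure, brachial pressures,
#'   age and sex are used.
#' @param control a [wk_control()].
#' @param pwv_cfg a [pwv_config()].
#' @return One-row data.frame: `id`, `sv`, `svr`, `zc`, `ca`, `pf_amp`,
#'   `pb_amp`, `rm`, `pwv`, `pp`, `hr`, `converged`.
#' @export
analyze_model <- function(subject, control = wk_control(),
                          pwv_cfg = pwv_config()) {
  p <- resample_beat(
    calibrate_pressure(subject$pressure, subject$map_mmHg, subject$dbp_mmHg),
    control$n_grid)
  fit <- synthesize_flow(p, priors = wk_priors(subject$sex),
                         control = control)
  ws <- model_wsa(p, fit)
  data.frame(
    id = subject$id, sv = fit$sv, svr = fit$r, zc = fit$zc, ca = fit$ca,
    pf_amp = ws$pf_amp, pb_amp = ws$pb_amp, rm = ws$rm,
    pwv = pwv_from_zc(fit$zc, subject$age, subject$sex, pwv_cfg),
    pp = beat_pp(p), hr = 60 / beat_period(p), converged = fit$converged,
    stringsAsFactors = FALSE
  )
}

#' Run one analysis arm over a cohort
#'
#' @param cohort a `cohort` object.
#' @param arm `"measured"` or `"model"`.
#' @param ... passed on to [analyze_measured()] / [analyze_model()].
#' @return A data.frame with one row per subject, plus the subjects'
#'   `age` and `sex` columns for subgroup and determinant analyses.
#' @export
analyze_cohort <- function(cohort, arm = c("measured", "model"), ...) {
  arm <- match.arg(arm)
  f <- if (arm == "measured") analyze_measured else analyze_model
  rows <- lapply(cohort$subjects, f, ...)
  out <- do.call(rbind, rows)
  out$age <- vapply(cohort$subjects, `[[`, numeric(1), "age")
  out$sex <- vapply(cohort$subjects, `[[`, character(1), "sex")
  out
}
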