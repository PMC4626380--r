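make_decay_beat <- function(tau = 1.4, per = 1, ed = 0.3, n = 128,
                            p_ed = 100) {
  t <- (seq_len(n) - 1) * per / n
  sys <- t < ed
  p <- numeric(n)
  p[!sys] <- p_ed * exp(-(t[!sys] - ed) / tau)
  # smooth systolic ramp from the end-diastolic value up to p_ed
  p0 <- p_ed * exp(-(per - ed) / tau)
  p[sys] <- p0 + (p_ed - p0) * (1 - cos(pi * t[sys] / ed)) / 2
  pressure_beat(p, per / n, ed = ed)
}

test_that("diastolic decay fit recovers the time constant", {
  b <- make_decay_beat(tau = 1.4)
  expect_equal(fit_diastolic_decay(b), 1.4, tolerance = 0.01)
  expect_equal(fit_diastolic_decay(b, fit_asymptote = FALSE), 1.4,
               tolerance = 0.01)

  # invariant to positive rescaling of the pressure
  b2 <- pressure_beat(3.7 * b$samples, b$dt, ed = b$ed)
  expect_equal(fit_diastolic_decay(b2), fit_diastolic_decay(b),
               tolerance = 1e-6)

  # constant diastole cannot be fitted
  flat <- pressure_beat(c(make_lobe(38, 0.3, 0.3, 30) + 70, rep(70, 90)),
                        1 / 128, ed = 0.3)
  expect_error(fit_diastolic_decay(flat), class = "hemowave_quality")

  # a reflection-like constant offset on the tail is absorbed by the
  # profiled asymptote but biases the zero-asymptote fit
  b3 <- pressure_beat(b$samples - 12 * (beat_time(b) >= b$ed), b$dt, ed = b$ed)
  expect_equal(fit_diastolic_decay(b3), 1.4, tolerance = 0.03)
  expect_lt(fit_diastolic_decay(b3, fit_asymptote = FALSE), 1.2)
})

test_that("steady-state stroke volume follows SV = MAP * T / SVR", {
  expect_equal(steady_state_sv(99, 1.0, 1.0), 99)
  expect_equal(steady_state_sv(99, 1.8, 1.0), 55)
  expect_equal(steady_state_sv(0, 1.3, 0.9), 0)
  expect_error(steady_state_sv(90, 0, 1), class = "hemowave_validation")
})

test_that("flow synthesis recovers a matched 3-element Windkessel subject", {
  # forward truth: Zc = 0.1, Ca = 1.0, Rp = 1.2, half-sine inflow
  cfg <- pinned_config(zc = 0.1, ca = 1.0, sv = 77, hr = 65, gamma = 0)
  cfg$map_mmHg <- c(77 / (60 / 65) * 1.3, 0)   # MAP = Qbar * (Rp + Zc) with Rp = 1.2
  sim <- simulate_subject(cfg, 1)
  expect_equal(sim$truth$rp, 1.2, tolerance = 1e-6)
  s <- sim$subject

  fit <- synthesize_flow(resample_beat(s$pressure, 128))
  q_true <- resample_beat(s$flow, 128)
  expect_gt(cor(fit$q_model$samples, q_true$samples), 0.95)
  expect_equal(fit$sv, sim$truth$sv, tolerance = 0.10 * sim$truth$sv)
  expect_true(fit$converged)

  # degenerate input: no pulsatility
  expect_error(synthesize_flow(pressure_beat(rep(90, 128), 1 / 128)),
               class = "hemowave_degenerate")
})

test_that("the fitted model satisfies its steady-state mass balance and flow invariants", {
  coh <- noiseless_cohort(n = 8, seed = 3)
  for (s in coh$subjects) {
    p <- resample_beat(calibrate_pressure(s$pressure, s$map_mmHg, s$dbp_mmHg), 128)
    fit <- synthesize_flow(p, priors = wk_priors(s$sex))
    # SV * R = MAP * T within 1% (R = total input resistance = fitted SVR)
    expect_lt(abs(fit$sv * fit$r - fit$map * fit$period) /
                (fit$map * fit$period), 0.01)
    expect_true(all(fit$q_model$samples >= 0))
    tgrid <- beat_time(fit$q_model)
    expect_true(all(fit$q_model$samples[tgrid > fit$ed] == 0))
    expect_gt(fit$zc, 0); expect_gt(fit$ca, 0); expect_gt(fit$r, fit$zc)
  }
})

test_that("flow synthesis is deterministic", {
  cfg <- pinned_config(gamma = 0.3)
  s <- simulate_subject(cfg, 1)$subject
  p <- resample_beat(s$pressure, 128)
  f1 <- synthesize_flow(p)
  f2 <- synthesize_flow(p)
  expect_identical(f1$zc, f2$zc)
  expect_identical(f1$q_model$samples, f2$q_model$samples)
})

test_that("stroke volume falls and the flow shape changes along the compliance/resistance family", {
  # sweep (Ca, R) over the three-case family at one fixed pressure beat
  cfg <- pinned_config(gamma = 0.3)
  s <- simulate_subject(cfg, 1)$subject
  p <- resample_beat(s$pressure, 128)
  cases <- list(A = c(ca = 0.8, rp = 1.0), B = c(ca = 1.0, rp = 1.4),
                C = c(ca = 1.2, rp = 1.8))
  fits <- lapply(cases, function(cs)
    synthesize_flow(p, params = list(zc = 0.1, ca = cs[["ca"]], rp = cs[["rp"]])))
  svs <- vapply(fits, `[[`, numeric(1), "sv")
  expect_true(all(diff(svs) < 0))   # SV strictly decreasing A -> B -> C
  norm_shape <- function(f) f$q_model$samples / max(f$q_model$samples)
  d_ac <- sqrt(mean((norm_shape(fits$A) - norm_shape(fits$C))^2))
  expect_gt(d_ac, 0.01)
})

test_that("model-arm wave separation reconstructs pressure and tracks the measured arm", {
  cfg <- pinned_config(gamma = 0.5, seed = 21)
  s <- simulate_subject(cfg, 1)$subject
  p <- resample_beat(calibrate_pressure(s$pressure, s$map_mmHg, s$dbp_mmHg), 128)
  fit <- synthesize_flow(p, priors = wk_priors(s$sex))
  ws_model <- model_wsa(p, fit)
  expect_equal(ws_model$pf_t + ws_model$pb_t, p$samples, tolerance = 1e-12)
  ws_meas <- analyze_measured(s)
  expect_equal(ws_model$rm, ws_meas$rm, tolerance = 0.1)
})

test_that("PWV follows the water-hammer relation", {
  # hand-computed: Zc = 0.1 mmHg s/ml, A = 4.52e-4 m^2, rho = 1050
  cfg <- pwv_config(rho = 1050, area_model = function(age, sex) 4.52e-4)
  expect_equal(pwv_from_zc(0.1, 45, "male", cfg), 5.74, tolerance = 0.01)
  expect_equal(pwv_from_zc(0, 45, "male"), 0)
  # linear in the area at fixed Zc
  cfg2 <- pwv_config(area_model = function(age, sex) 2 * 4.52e-4)
  expect_equal(pwv_from_zc(0.1, 45, "male", cfg2),
               2 * pwv_from_zc(0.1, 45, "male", cfg), tolerance = 1e-10)
  # default area model: women smaller than men, growing with age
  expect_lt(default_aortic_area(45, "female"), default_aortic_area(45, "male"))
  expect_gt(default_aortic_area(56, "male"), default_aortic_area(35, "male"))
  expect_error(pwv_from_zc(-1, 45, "male"), class = "hemowave_validation")
})
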