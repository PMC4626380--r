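#' Control settings for the Windkessel flow synthesis
#'
#' @param n_grid samples per cycle used for the integration grid.
#' @param min_cycles,max_cycles cycle bounds for reaching the periodic
#'   steady state.
#' @param steady_tol absolute cycle-to-cycle change in the Windkessel
#'   pressure (mmHg) below which the limit cycle is accepted.
#' @param zc_ref reference characteristic impedance (mmHg·s/ml) at which
#'   the scale-invariant inversion is computed before the scale is fixed;
#'   any positive value gives the same fit (see [synthesize_flow()]).
#' @param r_tol relative tolerance of the inner resistance solve.
#' @param reflection model the measured pressure as forward wave plus a
#'   single delayed reflection and estimate (gamma, tau_r) by grid search
#'   on the valve-consistency objective before inverting (default `TRUE`);
#'   with `FALSE` the pressure is inverted as-is.
#' @param gamma_max upper bound of the reflection-coefficient search.
#' @param tau_r_range bounds (s) of the reflection return-time search.
#' @return A list of control settings.
#' @export
wk_control <- function(n_grid = 128L, min_cycles = 5L, max_cycles = 400L,
                       steady_tol = 1e-6, zc_ref = 0.1, r_tol = 1e-6,
                       reflection = TRUE,
                       gamma_max = 0.6, tau_r_range = c(0.045, 0.125)) {
  list(n_grid = as.integer(n_grid), min_cycles = as.integer(min_cycles),
       max_cycles = as.integer(max_cycles), steady_tol = steady_tol,
       zc_ref = zc_ref, r_tol = r_tol, reflection = reflection,
       gamma_max = gamma_max, tau_r_range = tau_r_range)
}

# Undo a single-reflection transmission model in the frequency domain:
# measured P = (1 + gamma * delay(tau_r)) applied to the forward pressure,
# so each pulsatile harmonic is divided by 1 + gamma * exp(-i w tau_r).
# The mean (0 Hz) is untouched: the echo of the mean-centered forward wave
# carries no DC.
echo_deconvolve <- function(p, gamma, tau_r, dt) {
  if (gamma == 0) return(p)
  n <- length(p)
  X <- stats::fft(p)
  k <- 0:(n - 1)
  ktil <- ifelse(k <= n / 2, k, k - n)
  om <- 2 * pi * ktil / (n * dt)
  D <- 1 + gamma * exp(-1i * om * tau_r)
  D[1] <- 1
  Re(stats::fft(X / D, inverse = TRUE)) / n
}

#' Population priors that fix the flow scale of the pressure-only fit
#'
#' From pressure alone the 3-element Windkessel constrains only the
#' *ratios* of its parameters: the transformation
#' `(Zc, Ca, Rp, Q) -> (k Zc, Ca/k, k Rp, Q/k)` leaves the pressure, the
#' diastolic time constant and every mass-balance constraint unchanged, so
#' the absolute flow scale must come from population knowledge — as it
#' does in any pressure-only device, which is calibrated on a reference
#' population. The scale is selected by maximum a posteriori estimation
#' under independent log-normal priors on Zc, Ca, stroke volume and
#' peripheral resistance (closed form in log-scale; see the methods
#' vignette). Defaults are sex-specific where population tables report a
#' clear sex difference and match the envelopes of
#' [cohort_config()]; for real data they would be recalibrated.
#'
#' @param sex `"male"`, `"female"`, or `NA` for pooled priors.
#' @return A list with vectors `meanlog` and `sdlog` over the anchored
#'   quantities `zc`, `ca`, `sv`, `rp`.
#' @export
wk_priors <- function(sex = NA_character_) {
  mu <- switch(
    as.character(sex),
    male = c(zc = 0.101, ca = 1.7, sv = 86, rp = 0.93),
    female = c(zc = 0.116, ca = 1.7, sv = 69, rp = 1.17),
    c(zc = 0.108, ca = 1.7, sv = 77, rp = 1.05)
  )
  list(meanlog = log(mu),
       sdlog = c(zc = 0.30, ca = 0.20, sv = 0.16, rp = 0.22))
}

# One cycle of the inverse Windkessel: given measured pressure P on the grid,
# integrate Ca * dPwk/dt = Q - Pwk/Rp with Q = max(0, (P - Pwk)/Zc) during
# systole (t < ed) and Q = 0 in diastole. Classical RK4 on the sample grid;
# P at half-steps by linear interpolation. Returns the end state and, when
# asked, the Pwk and Q trajectories at the sample points.
wk_cycle_inverse <- function(pwk0, p, dt, ed, zc, ca, rp, keep = FALSE) {
  n <- length(p)
  pnext <- c(p[-1], p[1])
  t0 <- (seq_len(n) - 1) * dt
  inv_zc <- 1 / zc
  inv_ca <- 1 / ca
  inv_rp <- 1 / rp
  # sub-step so the fastest (systolic charging) time constant stays well
  # resolved; keeps the explicit scheme stable for extreme trial parameters
  theta <- ca * zc * rp / (zc + rp)
  nsub <- max(1L, min(40L, ceiling(dt / theta)))
  h <- dt / nsub
  w <- pwk0
  if (keep) traj <- numeric(n)
  for (i in seq_len(n)) {
    if (keep) traj[i] <- w
    pa <- p[i]
    slope <- (pnext[i] - pa) / dt
    tb <- t0[i]
    for (j in seq_len(nsub)) {
      toff <- (j - 1) * h
      pj0 <- pa + slope * toff
      pjm <- pa + slope * (toff + h / 2)
      pj1 <- pa + slope * (toff + h)
      s0 <- (tb + toff) < ed
      sm <- (tb + toff + h / 2) < ed
      s1 <- (tb + toff + h) < ed
      q1 <- if (s0) max(0, (pj0 - w) * inv_zc) else 0
      k1 <- (q1 - w * inv_rp) * inv_ca
      w2 <- w + h / 2 * k1
      q2 <- if (sm) max(0, (pjm - w2) * inv_zc) else 0
      k2 <- (q2 - w2 * inv_rp) * inv_ca
      w3 <- w + h / 2 * k2
      q3 <- if (sm) max(0, (pjm - w3) * inv_zc) else 0
      k3 <- (q3 - w3 * inv_rp) * inv_ca
      w4 <- w + h * k3
      q4 <- if (s1) max(0, (pj1 - w4) * inv_zc) else 0
      k4 <- (q4 - w4 * inv_rp) * inv_ca
      w <- w + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  }
  if (keep) {
    q <- ifelse(t0 < ed, pmax(0, (p - traj) * inv_zc), 0)
    list(end = w, pwk = traj, q = q)
  } else {
    list(end = w)
  }
}

# One cycle of the forward (generative) Windkessel: inflow Q(t) prescribed,
# Ca * dPwk/dt = Q - Pwk/Rp.
wk_cycle_forward <- function(pwk0, q, dt, ca, rp, keep = FALSE) {
  n <- length(q)
  qnext <- c(q[-1], q[1])
  qmid <- (q + qnext) / 2
  inv_ca <- 1 / ca
  inv_rp <- 1 / rp
  w <- pwk0
  if (keep) traj <- numeric(n)
  for (i in seq_len(n)) {
    if (keep) traj[i] <- w
    k1 <- (q[i] - w * inv_rp) * inv_ca
    k2 <- (qmid[i] - (w + dt / 2 * k1) * inv_rp) * inv_ca
    k3 <- (qmid[i] - (w + dt / 2 * k2) * inv_rp) * inv_ca
    k4 <- (qnext[i] - (w + dt * k3) * inv_rp) * inv_ca
    w <- w + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  if (keep) list(end = w, pwk = traj) else list(end = w)
}

# Iterate a cycle map to its periodic steady state. The map is affine
# wherever the valve clamp pattern is unchanged, so every pair of cycles a
# fixed-point (Aitken-type) extrapolation is applied; this converges in a
# few rounds even when the per-cycle contraction is weak (long diastolic
# time constants).
wk_steady <- function(cycle_fun, pwk0, control) {
  w <- pwk0
  cycles <- 0L
  repeat {
    e0 <- cycle_fun(w, FALSE)$end
    e1 <- cycle_fun(e0, FALSE)$end
    cycles <- cycles + 2L
    if (cycles >= control$min_cycles && abs(e1 - e0) < control$steady_tol) {
      w <- e1
      break
    }
    if (cycles >= control$max_cycles)
      convergence_error("periodic steady state not reached within the cycle cap")
    a <- if (abs(e0 - w) > 1e-14) (e1 - e0) / (e0 - w) else 0
    w <- if (is.finite(a) && a > -0.5 && a < 0.999) (e0 - a * w) / (1 - a) else e1
  }
  res <- cycle_fun(w, TRUE)
  res$cycles <- cycles
  res
}

#' Time constant of the diastolic pressure decay
#'
#' Fits the mono-exponential decay
#' `P(t) = P_inf + A * exp(-(t - ED)/tau)` to the diastolic limb. In a
#' 2-element Windkessel view of diastole, `tau = R * Ca`. By default the
#' asymptote `P_inf` is profiled out by a 1-D search over non-positive
#' values (for each candidate asymptote the remaining fit is log-linear
#' least squares). Reflected waves superimpose a quasi-constant
#' *negative* offset on the diastolic tail (a delayed scaled copy of the
#' mean-centered forward wave), so pinning the asymptote at 0 mmHg biases
#' `tau` low; set `fit_asymptote = FALSE` to force `P_inf = 0`. The fit
#' window starts at `ED + 0.15 T`, past the incisura transit of any
#' physiological reflection delay, where the tail is cleanly exponential.
#' The estimate is invariant to positive rescaling of the pressure.
#'
#' @param beat a calibrated [pressure_beat()] whose diastole spans at least
#'   20% of the cycle (ED detected if absent).
#' @param fit_asymptote profile the (non-positive) decay asymptote instead
#'   of fixing it at 0 mmHg (default `TRUE`).
#' @return `tau` in seconds.
#' @export
fit_diastolic_decay <- function(beat, fit_asymptote = TRUE) {
  beat <- with_ed(beat)
  per <- beat_period(beat)
  if (per - beat$ed < 0.2 * per)
    validation_error("diastole must span at least 20% of the cycle")
  t <- beat_time(beat)
  sel <- t >= beat$ed + 0.15 * per
  y <- beat$samples[sel]
  tt <- t[sel]
  if (length(y) < 8L)
    validation_error("too few diastolic samples for the decay fit")
  if (max(y) - min(y) <= 1e-9 * max(1, abs(mean(y))))
    quality_error("diastolic pressure does not decay")

  tau_given_c <- function(c) {
    z <- y - c
    if (any(z <= 0)) return(NULL)
    fit <- stats::lm.fit(cbind(1, tt), log(z))
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope >= -1e-12) return(NULL)
    list(tau = unname(-1 / slope), a = exp(fit$coefficients[1]))
  }
  rss_c <- function(c) {
    f <- tau_given_c(c)
    if (is.null(f)) return(Inf)
    sum((y - c - f$a * exp(-tt / f$tau))^2)
  }

  c_hat <- 0
  if (fit_asymptote) {
    span <- max(y) - min(y)
    opt <- stats::optimize(rss_c, c(-3 * max(abs(y)), 0))
    if (is.finite(opt$objective) && opt$objective < rss_c(0)) c_hat <- opt$minimum
  }
  f <- tau_given_c(c_hat)
  if (is.null(f) && fit_asymptote) f <- tau_given_c(0)
  if (is.null(f))
    quality_error("diastolic pressure does not decay")
  f$tau
}

# Solve the peripheral resistance at the reference Zc from the steady-state
# mass balance: at the limit cycle mean(Q) = mean(Pwk)/Rp, and the inlet
# balance mean(Pwk) + Zc*mean(Q) = MAP (zero venous pressure) makes
# SV * (Rp + Zc) = MAP * T hold exactly, i.e. the model's total resistance
# equals MAP / mean flow, matching the SVR definition. Ca is pinned by the
# diastolic time constant, Ca = tau / Rp. The balance residual depends on
# (Zc, Ca, Rp) only through Rp/Zc and tau, so the solved ratio is the
# scale-invariant core of the identification.
wk_solve_rp <- function(p, dt, ed, zc, tau, map, control, state) {
  g <- function(rp) {
    res <- wk_steady(function(w, keep)
      wk_cycle_inverse(w, p, dt, ed, zc, tau / rp, rp, keep),
      state$pwk0, control)
    state$pwk0 <- res$end
    mean(res$pwk) + zc * mean(res$q) - map
  }
  lo <- 0.02 * zc / control$zc_ref; hi <- 6 * zc / control$zc_ref
  flo <- g(lo)
  tries <- 0L
  while (flo > 0 && tries < 6L) {
    lo <- lo / 4; flo <- g(lo); tries <- tries + 1L
  }
  if (flo > 0) quality_error("mass balance infeasible at the resistance floor")
  fhi <- g(hi)
  tries <- 0L
  while (fhi < 0 && tries < 6L) {
    hi <- hi * 2; fhi <- g(hi); tries <- tries + 1L
  }
  if (fhi < 0) quality_error("mass balance infeasible for this Zc")
  stats::uniroot(g, c(lo, hi), f.lower = flo, f.upper = fhi,
                 tol = control$r_tol * hi)$root
}

#' Synthesize an aortic flow waveform from a pressure beat (model arm)
#'
#' Inverts a modified 3-element Windkessel to obtain the left-ventricular
#' outflow compatible with a measured, calibrated pressure beat. For a
#' parameter set (Zc, Ca, Rp) the Windkessel state equation
#' `Ca dPwk/dt = Q - Pwk/Rp` with `Q = max(0, (P - Pwk)/Zc)` during
#' systole and `Q = 0` during diastole (the one-way aortic valve) is
#' integrated to its periodic steady state by classical fixed-step
#' 4th-order Runge-Kutta on the 128-sample grid.
#'
#' Identification proceeds in three stages.
#'
#' The *reflection* stage (the transmission-line part of the model;
#' disable with `wk_control(reflection = FALSE)`) treats the measured
#' pressure as a forward wave plus one delayed, scaled reflection,
#' `P = (1 + gamma * delay(tau_r)) P_fwd`, and estimates `(gamma, tau_r)`
#' by a deterministic two-level grid search minimizing a valve-consistency
#' objective: after deconvolving the candidate echo and inverting the
#' Windkessel, a correct forward pressure yields a flow that never needs
#' clamping during systole and falls to zero smoothly at end-ejection.
#' Both criteria are invariant to the flow scale.
#'
#' The *scale-invariant* stage then uses two constraints: the diastolic
#' time constant pins `Rp * Ca = tau` (from [fit_diastolic_decay()],
#' applied to the forward pressure) and the steady-state mass balance with
#' zero venous pressure pins `SV * R = MAP * T`, where `R = Rp + Zc` is
#' the total input resistance — so the fitted SVR equals mean pressure
#' over mean flow by construction. These determine the ratio `Rp/Zc`, the
#' Windkessel pressure trajectory and the *shape* of the flow wave, but
#' not its scale: the model is exactly invariant under
#' `(Zc, Ca, Rp, Q) -> (k Zc, Ca/k, k Rp, Q/k)`, so pressure alone cannot
#' fix absolute flow (the left-ventricular work `W = integral(P Q dt)` is
#' proportional to `1/Zc` along the family, so a raw least-work criterion
#' degenerates). The *scale* stage fixes the remaining degree of freedom
#' by maximum a posteriori selection under the log-normal population
#' priors of [wk_priors()] — closed form in `log(Zc)`.
#'
#' @param beat a calibrated [pressure_beat()]; ED is detected if absent.
#' @param params optional list/vector with named entries `zc`, `ca`, `rp`:
#'   when supplied, identification is skipped and the Windkessel is simply
#'   inverted at those parameters (used e.g. for parameter-sweep studies).
#' @param priors a [wk_priors()] list fixing the flow scale.
#' @param control a [wk_control()] list.
#' @return An object of class `windkessel_fit`: list with `zc`, `ca`, `rp`
#'   (peripheral resistance), `r` (total resistance = fitted SVR), `tau`,
#'   `gamma`, `tau_r` (estimated reflection), `q_model` (a [flow_beat()]),
#'   `pwk_t`, `p_fwd` (deconvolved forward pressure), `sv` (ml), `w` (LV
#'   work, mmHg·ml), `map`, `period`, `ed`, `converged`, `cycles`.
#' @export
synthesize_flow <- function(beat, params = NULL, priors = wk_priors(),
                            control = wk_control()) {
  if (beat_pp(beat) < 1e-6)
    degenerate_error("pressure beat has no pulsatility")
  beat <- resample_beat(with_ed(beat), control$n_grid)
  p <- beat$samples
  dt <- beat$dt
  ed <- beat$ed
  per <- beat_period(beat)
  state <- new.env(parent = emptyenv())
  state$pwk0 <- beat_dbp(beat)

  if (!is.null(params)) {
    params <- as.list(params)
    zc <- params$zc; ca <- params$ca; rp <- params$rp
    if (any(!is.finite(c(zc, ca, rp))) || any(c(zc, ca, rp) <= 0))
      validation_error("params must supply positive zc, ca, rp")
    res <- wk_steady(function(w, keep)
      wk_cycle_inverse(w, p, dt, ed, zc, ca, rp, keep), state$pwk0, control)
    return(wk_build_fit(beat, res, zc, ca, rp, tau = ca * rp,
                        gamma = NA_real_, tau_r = NA_real_,
                        p_fwd = p, converged = TRUE))
  }

  zc_ref <- control$zc_ref
  n_sys <- max(which((seq_len(length(p)) - 1) * dt < ed))

  # scale-invariant inversion of a candidate forward pressure; returns the
  # identified invariants and the valve-consistency objective
  invariant_fit <- function(pf) {
    b <- pressure_beat(pf, dt, ed = ed)
    tau <- fit_diastolic_decay(b, fit_asymptote = FALSE)
    rp_ref <- wk_solve_rp(pf, dt, ed, zc_ref, tau, mean(pf), control, state)
    res <- wk_steady(function(w, keep)
      wk_cycle_inverse(w, pf, dt, ed, zc_ref, tau / rp_ref, rp_ref, keep),
      state$pwk0, control)
    state$pwk0 <- res$end
    qbar <- mean(res$q)
    graw <- (pf[1:n_sys] - res$pwk[1:n_sys]) / zc_ref  # unclamped flow
    j <- (mean(pmin(0, graw)^2) + graw[n_sys]^2 / 4) / qbar^2
    list(tau = tau, rho = rp_ref / zc_ref, res = res,
         sv_ref = qbar * per, j = j)
  }
  safe_fit <- function(gamma, tau_r) {
    tryCatch(invariant_fit(echo_deconvolve(p, gamma, tau_r, dt)),
             error = function(e) list(j = Inf))
  }

  gamma_hat <- 0; tau_r_hat <- mean(control$tau_r_range)
  if (control$reflection) {
    best <- list(j = Inf)
    for (g in seq(0, control$gamma_max, by = 0.1))
      for (trr in seq(control$tau_r_range[1], control$tau_r_range[2],
                      by = 0.02)) {
        f <- safe_fit(g, trr)
        if (f$j < best$j) { best <- f; gamma_hat <- g; tau_r_hat <- trr }
      }
    if (!is.finite(best$j))
      quality_error("no valve-consistent inversion found")
    for (g in seq(max(0, gamma_hat - 0.08), gamma_hat + 0.08, by = 0.02))
      for (trr in seq(max(control$tau_r_range[1], tau_r_hat - 0.015),
                      min(control$tau_r_range[2], tau_r_hat + 0.015),
                      by = 0.005)) {
        f <- safe_fit(g, trr)
        if (f$j < best$j) { best <- f; gamma_hat <- g; tau_r_hat <- trr }
      }
    fit0 <- best
    if (gamma_hat == 0) tau_r_hat <- NA_real_
  } else {
    fit0 <- invariant_fit(p)
    gamma_hat <- NA_real_; tau_r_hat <- NA_real_
  }

  # MAP gauge fixing: each prior proposes a log(Zc); combine by precision
  rho <- fit0$rho; tau <- fit0$tau; res <- fit0$res
  m <- priors$meanlog; s2 <- priors$sdlog^2
  u <- c(zc = m[["zc"]],
         rp = m[["rp"]] - log(rho),
         ca = log(tau) - log(rho) - m[["ca"]],
         sv = log(fit0$sv_ref * zc_ref) - m[["sv"]])
  w <- 1 / s2[names(u)]
  zc_hat <- exp(sum(w * u) / sum(w))

  k <- zc_hat / zc_ref
  res$q <- res$q / k  # gauge transform of the reference trajectory
  pf <- echo_deconvolve(p, if (is.na(gamma_hat)) 0 else gamma_hat,
                        if (is.na(tau_r_hat)) 0 else tau_r_hat, dt)
  wk_build_fit(beat, res, zc_hat, tau / (rho * zc_hat), rho * zc_hat, tau,
               gamma = gamma_hat, tau_r = tau_r_hat, p_fwd = pf,
               converged = TRUE)
}

wk_build_fit <- function(beat, res, zc, ca, rp, tau, gamma, tau_r, p_fwd,
                         converged) {
  per <- beat_period(beat)
  sv <- mean(res$q) * per
  structure(
    list(zc = zc, ca = ca, rp = rp, r = rp + zc, tau = tau,
         gamma = gamma, tau_r = tau_r,
         q_model = flow_beat(res$q, beat$dt, ed = beat$ed),
         pwk_t = res$pwk, p_fwd = p_fwd,
         sv = sv,
         w = sum(beat$samples * res$q) * beat$dt,
         map = beat_map(beat), period = per, ed = beat$ed,
         converged = converged, cycles = res$cycles),
    class = "windkessel_fit"
  )
}

#' @export
print.windkessel_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<windkessel_fit> Zc %.4f, Ca %.3f ml/mmHg, Rp %.3f ",
           "(SVR %.3f mmHg·s/ml)\n  SV %.1f ml, LV work %.0f mmHg·ml, ",
           "tau %.2f s, %s (%d cycles)\n"),
    x$zc, x$ca, x$rp, x$r, x$sv, x$w, x$tau,
    if (x$converged) "converged" else "NOT converged", x$cycles))
  invisible(x)
}

#' Stroke volume from the periodic steady-state mass balance
#'
#' With zero venous pressure the mean flow through the total resistance is
#' `MAP / SVR`, so the volume ejected per cycle is `SV = MAP * T / SVR`.
#'
#' @param map_mmHg mean arterial pressure (mmHg).
#' @param svr systemic vascular resistance (mmHg·s/ml), positive.
#' @param period cycle length T (s), positive.
#' @return Stroke volume in ml.
#' @export
steady_state_sv <- function(map_mmHg, svr, period) {
  if (!is.finite(svr) || svr <= 0) validation_error("SVR must be positive")
  if (!is.finite(period) || period <= 0) validation_error("period must be positive")
  map_mmHg * period / svr
}

#' Wave separation of the model arm
#'
#' Applies [separate_waves()] to the measured pressure beat using the
#' model-synthesized flow and the fitted characteristic impedance. Note
#' that the product `Zc * Q` is invariant under the model's scale gauge,
#' so the model-arm separation does not depend on how the flow scale was
#' fixed.
#'
#' @param beat the calibrated [pressure_beat()] the fit was computed from.
#' @param fit a converged [synthesize_flow()] result.
#' @return A `wave_separation` object.
#' @export
model_wsa <- function(beat, fit) {
  if (!inherits(fit, "windkessel_fit"))
    validation_error("fit must be a windkessel_fit")
  beat <- resample_beat(beat, length(fit$q_model$samples))
  separate_waves(beat, fit$q_model, fit$zc)
}
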