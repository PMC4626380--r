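---
title: "Model-based central hemodynamics from pressure waveforms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based central hemodynamics from pressure waveforms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemowave)
```

## The two-arm analysis

`hemowave` implements two parallel routes from non-invasive waveforms to
central hemodynamic parameters, plus the statistical machinery to compare
them.

The **measured arm** is the classical reference pathway. It needs one
averaged carotid-type pressure beat \(P(t)\) — calibrated so that its
minimum equals the brachial diastolic pressure and its time average the
brachial mean pressure — and one averaged aortic-root flow beat \(Q(t)\)
(ml/s, zero throughout diastole). Both are decomposed into their Fourier
harmonics and divided to give the input impedance spectrum
\(Z_n = P_n / Q_n\) (mmHg·s/ml). Its 0 Hz value is the systemic vascular
resistance, \(\mathrm{SVR} = \bar P / \bar Q\); the characteristic
impedance \(Z_c\) is the mean modulus over harmonics 3–10 after outlier
exclusion, the band where the 3-element input impedance has flattened onto
\(Z_c\). Wave separation then splits the pressure linearly into forward
and backward components,
\[
P_f = \bar P + \tfrac{1}{2}(\tilde P + Z_c \tilde Q), \qquad
P_b = \tfrac{1}{2}(\tilde P - Z_c \tilde Q),
\]
(tildes are mean-centered pulsatile parts), with amplitudes taken as
max − min over the cycle and the reflection magnitude
\(\mathrm{RM} = P_b^{\mathrm{amp}} / P_f^{\mathrm{amp}}\).

The **model arm** uses the pressure beat alone. A modified 3-element
Windkessel — characteristic impedance \(Z_c\) in series with a compliance
\(C_a\) (ml/mmHg) and peripheral resistance \(R_p\) in parallel — is
driven by the measured pressure through a one-way valve:
\[
C_a \frac{dP_{wk}}{dt} = Q - \frac{P_{wk}}{R_p}, \qquad
Q = \max\!\Big(0, \frac{P - P_{wk}}{Z_c}\Big) \text{ in systole}, \quad
Q = 0 \text{ in diastole.}
\]
Integrated to its periodic steady state, this yields a synthesized flow
wave, hence SV, SVR, model-arm wave separation, and a pulse wave velocity
from the water-hammer relation \(\mathrm{PWV} = Z_c^{SI} A / \rho\).

## Identification: what pressure alone can and cannot determine

Two constraints reduce the parameter identification. The diastolic
pressure tail decays with the Windkessel time constant, pinning
\(R_p C_a = \tau\); and at the limit cycle the cycle-averaged state
equation gives \(\bar Q = \overline{P_{wk}}/R_p\), so requiring the inlet
balance \(\overline{P_{wk}} + Z_c \bar Q = \bar P\) (zero venous
pressure) is equivalent to \(\mathrm{SV}\cdot R = \bar P \, T\) with
\(R = R_p + Z_c\) the *total* input resistance. The fitted SVR therefore
equals mean pressure over mean flow exactly, matching the definition used
in the measured arm. (We deliberately attach the mass balance to the
total resistance: attaching it to \(R_p\) would make the fitted SVR differ
from \(\bar P/\bar Q\) by \(Z_c\).)

These constraints determine a lot — but not everything. The inverse model
is *exactly* invariant under
\[
(Z_c, C_a, R_p, Q) \;\longmapsto\; (k Z_c,\; C_a/k,\; k R_p,\; Q/k),
\]
which leaves \(P\), \(\tau\) and every mass balance unchanged. Pressure
alone therefore determines the ratio \(R_p/Z_c\), the Windkessel pressure
trajectory, and the *shape* of the flow wave, but carries no information
about the absolute flow scale. One practical consequence: the
left-ventricular work \(W = \int P\,Q\,dt\) scales exactly as \(1/Z_c\)
along this family, so "choose the least-work member" cannot by itself
select \(Z_c\) — any bracketed minimization simply runs to the boundary,
and a bracket defined in multiples of \(R\) is itself gauge-degenerate
because \(Z_c/R_p\) is constant along the family. The work integral is
still computed and reported on every fit, but it is not the closing
condition.

The scale must come from outside the waveform, as it does in any
pressure-only device, which is calibrated on a reference population.
`hemowave` makes that explicit: the remaining degree of freedom is fixed
by **maximum a posteriori selection under log-normal population priors**
on \(Z_c\), \(C_a\), SV and \(R_p\) (`wk_priors()`). Because all four
quantities are power functions of the gauge coordinate, the posterior
mode has a closed form — each prior proposes a value of \(\log Z_c\), and
the proposals are combined by precision weighting. The default priors are
sex-specific where population tables report a clear sex difference (SV,
\(Z_c\)) and match the envelopes of the synthetic generator; on real data
they would be recalibrated. A visible signature of this design, shared
with published pressure-only devices, is *shrinkage*: model-arm SDs of
\(Z_c\) and SV across a cohort are smaller than the measured arm's,
because part of each estimate comes from the population prior.

### The reflection stage

Measured central pressure is not a pure forward wave. The identification
therefore starts by modelling the beat as a forward wave plus one
delayed, scaled reflection,
\(P = (1 + \gamma\, \mathcal{D}_{\tau_r}) P_{fwd}\), where
\(\mathcal{D}_{\tau_r}\) is a periodic delay. For a candidate
\((\gamma, \tau_r)\) the echo is removed harmonic-by-harmonic (division by
\(1 + \gamma e^{-i\omega\tau_r}\)) and the Windkessel inverted on the
result. The candidate is scored by a **valve-consistency objective**:
when the forward pressure is right, the inferred flow (i) never needs the
\(\max(0,\cdot)\) clamp during systole and (ii) returns to zero smoothly
at end-ejection rather than being cut off. Both criteria are invariant to
the flow scale, so this stage commutes with the gauge fixing. The search
is a deterministic two-level grid (\(\gamma\) to 0.02, \(\tau_r\) to
5 ms). Skipping this stage (`wk_control(reflection = FALSE)`) attributes
the echo's systolic pressure boost to extra flow and biases the
scale-invariant quantities by roughly \(+\gamma\); with it, the identified
\(R_p/Z_c\) and \(\mathrm{SV}\cdot Z_c\) are nearly unbiased on generated
data. The individual \((\gamma, \tau_r)\) estimates are less reliable
than the invariants they protect and are reported for diagnostics only.

### Diastolic time constant

`fit_diastolic_decay()` fits \(P(t) = P_\infty + A e^{-(t-ED)/\tau}\) to
the diastolic limb, starting at \(ED + 0.15\,T\) so that the incisura
transit of any physiological reflection delay has passed. The asymptote
is profiled over non-positive values by a 1-D search wrapping a
log-linear fit. A reflected wave superimposes a quasi-constant *negative*
offset on the tail (a delayed copy of the mean-centered forward wave), so
pinning \(P_\infty = 0\) biases \(\tau\) low by tens of percent on
strongly reflective beats — we measured ~30% with the generator's echo —
which in turn can make the mass balance infeasible. The zero-asymptote
variant remains available (`fit_asymptote = FALSE`).

## Numerical choices

* **Canonical grid.** Every beat is resampled to 128 samples per cycle by
  Fourier (band-limited periodic) interpolation before analysis: a power
  of two for the harmonic decomposition, and ≥ 10 well-resolved harmonics
  at any heart rate in 40–120 bpm. Time averages use the periodic
  trapezoidal rule, which on a uniform one-cycle grid equals the sample
  mean.
* **Integration.** Classical fixed-step RK4 on the 128-sample grid, with
  linear interpolation of \(P\) at half-steps. When a trial parameter set
  makes the systolic charging time constant
  \(\theta = C_a Z_c R_p/(Z_c + R_p)\) shorter than the step, the step is
  subdivided (\(\lceil dt/\theta \rceil\) sub-steps, capped at 40) to keep
  the explicit scheme stable.
* **Periodic steady state.** The cycle map is affine wherever the valve
  clamp pattern is unchanged, so an Aitken-type fixed-point extrapolation
  is applied every two cycles; convergence is declared when the
  cycle-to-cycle change of \(P_{wk}\) falls below \(10^{-6}\) mmHg (at
  least 5, at most 400 cycles).
* **Fiducial detection.** Runs on a lightly low-passed copy (harmonics
  above ~20 removed) so noise cannot masquerade as an upstroke; the foot
  is then refined on the raw samples (ties broken toward the upstroke).
  The incisura is the maximum of the second derivative in a window from
  \(0.15\,T\) (but after the systolic peak) to \(0.45\,T\), motivated by
  physiological ejection fractions of the cycle; the window never widens
  beyond \(0.45\,T\), so a noise artifact cannot push ED into diastole.
* **Degenerate inputs.** Constant signals, non-decaying diastoles,
  near-zero flow harmonics and infeasible mass balances raise classed
  conditions (`hemowave_validation`, `hemowave_degenerate`,
  `hemowave_quality`, `hemowave_convergence`) rather than propagating
  NaNs.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `n_grid` | 128 | samples/cycle | power of two; resolves ≥ 10 harmonics at any physiological HR |
| Zc band | harmonics 3–10 | — | below 3 the reservoir term dominates; above 10 flow harmonics vanish |
| outlier rule | 3 × MAD (scaled) | — | robust, parameter-free stand-in for the historical criterion; configurable |
| flagged-harmonic floor | 1e−6 | ml/s | flow harmonics below it are unusable, flagged not divided |
| amplitude convention | max − min | mmHg | foot-to-peak available via `amplitude = "foot_to_peak"` |
| LoA multiplier | 1.96 | — | conventional 95% limits of agreement |
| stepwise thresholds | enter < 0.05, remove > 0.10 | — | forward/backward p-value selection; removal > entry guarantees termination |
| `rho` | 1050 | kg/m³ | blood density |
| area model | d = 28 mm + 0.05 mm/y (men), −2 mm (women) | — | anthropometric stand-in, fully swappable via `pwv_config()` |
| `wk_priors()` | sex-specific population values | — | the flow-scale calibration; see above |
| `zc_ref` | 0.1 | mmHg·s/ml | reference point of the scale-invariant stage; the fit is independent of it |
| reflection grid | γ ≤ 0.6, τ_r 45–125 ms | — | physiological reflection strengths and return times |

## The synthetic cohort generator

Because no raw cohort data are deposited anywhere this package can reach,
every pipeline stage is exercised on `simulate_cohort()`, which produces
subjects with *known* ground truth. Per subject: demographics and
hemodynamic parameters are drawn from independent truncated normals
(sex-specific means for SV and \(Z_c\)); a half-sine inflow of duration
\(ED = 0.37\sqrt{T}\) and area SV drives the forward Windkessel to its
limit cycle; the forward pressure \(P_{wk} + Z_c Q\) receives one delayed
scaled echo (\(\gamma\), \(\tau_r\)); channels are noised (white Gaussian;
flow noise restricted to the systolic lobe and clamped non-negative) and
the pressure re-calibrated to the clean brachial mean/diastolic values,
exactly as a tonometer trace would be.

Defaults were chosen once, as the population a mid-life cardiovascular
screening study would show: HR 62 (8) bpm, MAP 92 (9) mmHg, SV 86 (14) /
69 (11) ml and \(Z_c\) 0.101 (0.030) / 0.116 (0.035) mmHg·s/ml for men /
women, \(C_a\) 1.7 (0.35) ml/mmHg — the total compliance implied by
SV/PP ≈ 77/45 — reflection coefficient 0.30 (0.10) with return time
80 (15) ms. Diastolic pressure is *emergent* (the minimum the Windkessel
dynamics produce), not independently drawable: the cuff DBP metadata
records it.

Ground-truth forward/backward amplitudes and RM are defined **in closed
loop**: wave separation of the clean pressure/flow pair at the true
\(Z_c\). This is deliberate. Even with no echo at all, separating a
3-element Windkessel's pressure assigns the pulsatile reservoir pressure
\(\tilde P_{wk}/2\) to the backward wave — the textbook behavior of WSA
on a lumped compliant load — so "RM at \(\gamma = 0\)" is ~0.3–0.4, not
0. The matched-load identity (RM = 0) holds for transmission-line pairs
\(Q = (P_f - P_b)/Z_c\), and is tested on exactly that construction.

**What the generator does not emulate**, and hence what passing tests do
not establish about real data: no between-parameter covariances (real
\(Z_c\) falls with age and differs with body size; here age enters only
the PWV area model); a single discrete echo rather than distributed
reflections; a fixed half-sine inflow shape; no operator or repeatability
variability; and a deliberately loose, arbitrary coupling between the
simulated carotid-femoral PWV reference and the true \(Z_c\), which is
there to exercise the comparison and grading machinery, not to reproduce
any published agreement level.

## Known limitations

* The band-average \(Z_c\) estimator of the measured arm carries a
  reflection-interference factor \(|1 + \gamma e^{-i\omega_n \tau_r}|\)
  across harmonics 3–10. With the generator's defaults the band phases
  cluster near \(\pi\) and the estimator reads ~5% low on average; on
  echo-free Windkessel pairs the same estimator recovers \(Z_c\) to ~1%.
  This is a property of the estimator under reflective conditions, not of
  the implementation.
* Model-arm absolute scale (hence SV, \(Z_c\), PWV) is prior-driven by
  construction; per-subject errors are bounded by the population
  dispersion of the priors (~7–10% median on generated cohorts) and
  cannot shrink further without subject-specific flow information.
* The PWV area model is a stand-in; absolute PWV values move linearly
  with it.

## Problem sizes used in the checks

The packaged tests run the full two-arm pipeline on a noiseless cohort of
n = 50 (recovery tolerances), a 3-level noise sweep at n = 16 (agreement
monotonicity), and assorted single-subject constructions; the analysis
scripts under `analysis/` use n = 120 with default noise. These sizes give
stable medians while keeping the whole suite in a few minutes on one CPU.
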