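# Shared builders for synthetic test inputs. Fixtures are constructed in
# code; nothing is read from disk.

# a smooth positive systolic lobe with flat diastole (raised cosine)
make_lobe <- function(n = 128, per = 1, ed = 0.3, amp = 1) {
  t <- (seq_len(n) - 1) * per / n
  ifelse(t < ed, amp * 0.5 * (1 - cos(2 * pi * t / ed)), 0)
}

# half-sine flow beat of given stroke volume and ejection duration
make_half_sine_flow <- function(sv = 77, per = 60 / 65, ed = 0.37 * sqrt(per),
                                n = 128) {
  t <- (seq_len(n) - 1) * per / n
  qpk <- pi * sv / (2 * ed)
  flow_beat(ifelse(t < ed, qpk * sin(pi * t / ed), 0), per / n, ed = ed)
}

# transmission-line pressure/flow pair with known reflection coefficient:
# P = MAP + Pf + Pb, Q = (Pf - Pb)/Zc (+ offset to stay positive), where
# Pb is a delayed scaled copy of the forward lobe. Wave separation at the
# true Zc recovers RM = gamma exactly.
make_tl_pair <- function(gamma, zc = 0.1, per = 1, n = 128, delay_s = 0.1,
                         map = 93, pf_amp = 40) {
  pf <- make_lobe(n, per, ed = 0.35, amp = pf_amp)
  pf <- pf - mean(pf)
  pb <- gamma * circshift_test(pf, round(delay_s * n / per))
  p <- pressure_beat(map + pf + pb, per / n)
  qraw <- (pf - pb) / zc
  q <- flow_beat(qraw - min(qraw), per / n)
  list(p = p, q = q, pf = pf, pb = pb)
}

circshift_test <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

# cohort config with all hemodynamic draws pinned to fixed values
# (zero-SD truncated normals), used to build matched Windkessel subjects
pinned_config <- function(zc = 0.1, ca = 1.0, sv = 77, hr = 65, map = 93,
                          gamma = 0, tau_r = 0.08, noise_p = 0, noise_q = 0,
                          n = 1L, seed = 11L, male_frac = 1) {
  cfg <- cohort_config(
    n = n, seed = seed, male_frac = male_frac,
    hr_bpm = c(hr, 0), map_mmHg = c(map, 0),
    sv_ml_male = c(sv, 0), sv_ml_female = c(sv, 0),
    zc_male = c(zc, 0), zc_female = c(zc, 0),
    ca_ml_mmhg = c(ca, 0), gamma = c(max(gamma, 1e-6), 0),
    tau_r_s = c(tau_r, 0),
    noise_p_mmHg = noise_p, noise_q_ml_s = noise_q
  )
  cfg$trunc$gamma <- c(-1, 1)
  cfg$trunc$zc_male <- cfg$trunc$zc_female <- c(0.001, 1)
  cfg$trunc$ca_ml_mmhg <- c(0.01, 10)
  cfg$trunc$sv_ml_male <- cfg$trunc$sv_ml_female <- c(1, 500)
  cfg
}

# memoised noiseless default cohort shared by the heavier tests
test_cache <- new.env(parent = emptyenv())

noiseless_cohort <- function(n = 50L, seed = 1L) {
  key <- sprintf("coh_%d_%d", n, seed)
  if (is.null(test_cache[[key]])) {
    cfg <- cohort_config(n = n, seed = seed,
                         noise_p_mmHg = 0, noise_q_ml_s = 0)
    test_cache[[key]] <- simulate_cohort(cfg)
  }
  test_cache[[key]]
}

cohort_arm <- function(arm, n = 50L, seed = 1L) {
  key <- sprintf("%s_%d_%d", arm, n, seed)
  if (is.null(test_cache[[key]])) {
    test_cache[[key]] <- analyze_cohort(noiseless_cohort(n, seed), arm)
  }
  test_cache[[key]]
}

median_rel_err <- function(est, truth) stats::median(abs(est - truth) / abs(truth))
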