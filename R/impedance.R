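#' Harmonic (Fourier-series) decomposition of a beat
#'
#' Decomposes one periodic cycle into its discrete Fourier series. The
#' convention is one-sided: coefficient 0 is the (real) time average, and
#' for `k >= 1` the complex coefficient `a_k` satisfies
#' `x(t) = a_0 + sum_k Re(a_k * exp(2i*pi*k*t/T))`, so `Mod(a_k)` is the
#' peak amplitude of the k-th sinusoid. Parseval's identity holds under
#' this scaling as `var-like sum = sum(Mod(a_k)^2)/2`.
#'
#' @param beat a beat object (uniformly sampled, one full period).
#' @param n_harm number of harmonics to return (must stay below Nyquist).
#' @return An object of class `harmonic_spectrum`: list with `f0` (Hz),
#'   `coefficients` (complex, harmonics `0..n_harm`), `n_harm`.
#' @export
harmonic_decompose <- function(beat, n_harm = 10L) {
  x <- beat$samples
  n <- length(x)
  n_harm <- as.integer(n_harm)
  if (n_harm < 1L || n_harm >= n / 2)
    validation_error("n_harm must be >= 1 and below the Nyquist harmonic")
  X <- stats::fft(x)
  coef <- complex(length.out = n_harm + 1L)
  coef[1] <- Re(X[1]) / n
  coef[2:(n_harm + 1L)] <- 2 * X[2:(n_harm + 1L)] / n
  structure(
    list(f0 = 1 / beat_period(beat), coefficients = coef, n_harm = n_harm),
    class = "harmonic_spectrum"
  )
}

#' Input impedance spectrum from pressure and flow harmonics
#'
#' The arterial input impedance is the ratio of corresponding pressure and
#' flow harmonics; its 0 Hz value is the systemic vascular resistance
#' (mean pressure over mean flow). Flow harmonics whose modulus falls below
#' `q_floor` are flagged as unusable rather than divided through; flagged
#' harmonics are excluded from downstream characteristic-impedance
#' averaging.
#'
#' @param p_spec,q_spec [harmonic_decompose()] spectra of the pressure
#'   (mmHg) and flow (ml/s) beats; must share `f0` and `n_harm`.
#' @param q_floor flow-harmonic modulus floor (ml/s) below which a harmonic
#'   is flagged.
#' @return An object of class `impedance_spectrum`: list with `z`
#'   (complex, harmonics `0..n_harm`, mmHg·s/ml), `modulus`, `phase`,
#'   `flagged` (integer harmonic numbers), `f0`.
#' @export
input_impedance <- function(p_spec, q_spec, q_floor = 1e-6) {
  if (!inherits(p_spec, "harmonic_spectrum") || !inherits(q_spec, "harmonic_spectrum"))
    validation_error("inputs must be harmonic_spectrum objects")
  if (p_spec$n_harm != q_spec$n_harm)
    validation_error("pressure and flow spectra must have the same number of harmonics")
  if (abs(p_spec$f0 - q_spec$f0) > 1e-6 * p_spec$f0)
    validation_error("pressure and flow spectra must share the fundamental frequency")
  qc <- q_spec$coefficients
  if (Mod(qc[1]) <= q_floor)
    validation_error("mean flow is (near-)zero: input impedance undefined")
  z <- p_spec$coefficients / qc
  z[1] <- complex(real = Re(p_spec$coefficients[1]) / Re(qc[1]))
  flagged <- which(Mod(qc[-1]) < q_floor)  # harmonic numbers 1..n_harm
  z[flagged + 1L] <- NA_complex_
  structure(
    list(z = z, modulus = Mod(z), phase = Arg(z),
         flagged = as.integer(flagged), f0 = p_spec$f0,
         n_harm = p_spec$n_harm),
    class = "impedance_spectrum"
  )
}

#' Characteristic impedance from the high-harmonic impedance moduli
#'
#' Averages the input-impedance moduli over harmonics 3 to 10 after
#' excluding outliers. The default exclusion rule drops any harmonic whose
#' modulus deviates from the median of the band by more than
#' `mad_mult` times the median absolute deviation (scaled by the usual
#' 1.4826 normal-consistency constant); the rule is configurable since
#' the historical criterion it stands in for is not fully specified.
#'
#' @param zspec an [input_impedance()] spectrum with >= 10 harmonics.
#' @param harmonics integer harmonic band to average (default `3:10`).
#' @param mad_mult MAD multiplier of the exclusion rule (default 3).
#' @return A list with `zc` (mmHg·s/ml), `used` and `excluded` harmonic
#'   numbers (excluded = flagged plus outliers).
#' @export
characteristic_impedance <- function(zspec, harmonics = 3:10, mad_mult = 3) {
  if (!inherits(zspec, "impedance_spectrum"))
    validation_error("zspec must be an impedance_spectrum")
  if (zspec$n_harm < max(harmonics))
    validation_error("impedance spectrum has too few harmonics")
  m <- zspec$modulus[harmonics + 1L]
  names(m) <- harmonics
  ok <- is.finite(m)
  if (sum(ok) < 4L)
    quality_error("fewer than 4 usable harmonics in the averaging band")
  med <- stats::median(m[ok])
  madv <- stats::mad(m[ok])
  out <- ok & (abs(m - med) > mad_mult * madv + 1e-15)
  keep <- ok & !out
  n_lost <- length(harmonics) - sum(keep)
  if (n_lost > length(harmonics) %/% 2)
    quality_error("more than half of the averaging-band harmonics excluded")
  list(
    zc = mean(m[keep]),
    used = as.integer(harmonics[keep]),
    excluded = as.integer(harmonics[!keep])
  )
}

#' Systemic vascular resistance
#'
#' SVR is the 0 Hz input impedance: mean arterial pressure divided by mean
#' flow (cardiac output), in mmHg·s/ml. Mean flow from a beat equals
#' `SV * HR / 60`.
#'
#' @param map_mmHg mean arterial pressure (mmHg).
#' @param mean_flow mean flow (ml/s), must be positive.
#' @return SVR in mmHg·s/ml.
#' @export
svr <- function(map_mmHg, mean_flow) {
  if (!is.finite(mean_flow) || mean_flow <= 0)
    validation_error("mean flow must be positive")
  map_mmHg / mean_flow
}

#' Reconstruct a signal from its harmonic spectrum
#'
#' Evaluates the truncated Fourier series on `n` uniform sample points;
#' used for diagnostics and reconstruction-quality checks.
#'
#' @param spec a [harmonic_decompose()] spectrum.
#' @param n number of output samples per cycle.
#' @return Numeric vector of length `n`.
#' @export
harmonic_reconstruct <- function(spec, n = 128L) {
  t <- (seq_len(n) - 1) / n
  out <- rep(Re(spec$coefficients[1]), n)
  for (k in seq_len(spec$n_harm)) {
    out <- out + Re(spec$coefficients[k + 1L] * exp(2i * pi * k * t))
  }
  out
}
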