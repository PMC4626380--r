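#' Single-beat waveform containers
#'
#' A beat holds one averaged cardiac cycle sampled uniformly at interval
#' `dt` (s); the samples cover exactly one period `T = length(samples) * dt`
#' with time measured from the wave foot (sample 1 sits at `t = 0`).
#' Pressure is in mmHg, volumetric flow in ml/s; these units are fixed
#' package-wide so impedances come out in mmHg·s/ml.
#'
#' Derived quantities are computed on demand rather than stored: diastolic
#' pressure is the cycle minimum, mean pressure the time average (for a
#' uniformly sampled periodic signal the trapezoidal rule over one full
#' period equals the plain sample mean), pulse pressure the range.
#'
#' @param samples numeric vector, one full cycle.
#' @param dt sampling interval (s).
#' @param ed ejection duration (s), optional; detected later if absent.
#' @param foot_index sample index of the wave foot (default 1: foot-aligned).
#' @return An object of class `pressure_beat` or `flow_beat` (both inherit
#'   from `beat`).
#' @seealso [calibrate_pressure()], [detect_fiducials()], [resample_beat()]
#' @export
pressure_beat <- function(samples, dt, ed = NULL, foot_index = 1L) {
  samples <- as.numeric(samples)
  check_beat_args(samples, dt)
  if (!is.null(ed)) {
    per <- length(samples) * dt
    if (ed <= 0 || ed >= per)
      validation_error("ejection duration must lie strictly inside the cycle")
  }
  structure(
    list(samples = samples, dt = dt, ed = ed,
         foot_index = as.integer(foot_index)),
    class = c("pressure_beat", "beat")
  )
}

#' @rdname pressure_beat
#' @export
flow_beat <- function(samples, dt, ed = NULL) {
  samples <- as.numeric(samples)
  check_beat_args(samples, dt)
  tol <- 1e-9 * max(1, max(abs(samples)))
  if (min(samples) < -tol)
    validation_error("flow samples must be non-negative (no retrograde flow in this model)")
  samples <- pmax(samples, 0)
  structure(
    list(samples = samples, dt = dt, ed = ed, foot_index = 1L),
    class = c("flow_beat", "beat")
  )
}

check_beat_args <- function(samples, dt) {
  if (length(samples) < 16L)
    validation_error("a beat needs at least 16 samples")
  if (anyNA(samples) || !all(is.finite(samples)))
    validation_error("beat samples must be finite and non-missing")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    validation_error("dt must be a single positive number")
  invisible(TRUE)
}

#' Beat accessors
#'
#' @param beat a [pressure_beat()] or [flow_beat()].
#' @return `beat_period` the cycle length T (s); `beat_time` the sample time
#'   axis; `beat_map` the time-averaged pressure (mmHg); `beat_dbp` the
#'   minimum (diastolic) pressure; `beat_pp` the pulse pressure (max - min).
#' @export
beat_period <- function(beat) length(beat$samples) * beat$dt

#' @rdname beat_period
#' @export
beat_time <- function(beat) (seq_along(beat$samples) - 1) * beat$dt

#' @rdname beat_period
#' @export
beat_map <- function(beat) mean(beat$samples)

#' @rdname beat_period
#' @export
beat_dbp <- function(beat) min(beat$samples)

#' @rdname beat_period
#' @export
beat_pp <- function(beat) max(beat$samples) - min(beat$samples)

#' @export
print.pressure_beat <- function(x, ...) {
  cat(sprintf(
    "<pressure_beat> %d samples, T = %.3f s (HR %.1f bpm)\n  MAP %.1f / DBP %.1f / PP %.1f mmHg%s\n",
    length(x$samples), beat_period(x), 60 / beat_period(x),
    beat_map(x), beat_dbp(x), beat_pp(x),
    if (is.null(x$ed)) "" else sprintf(", ED %.3f s", x$ed)
  ))
  invisible(x)
}

#' @export
print.flow_beat <- function(x, ...) {
  cat(sprintf(
    "<flow_beat> %d samples, T = %.3f s, peak %.1f ml/s, SV %.1f ml%s\n",
    length(x$samples), beat_period(x), max(x$samples),
    mean(x$samples) * beat_period(x),
    if (is.null(x$ed)) "" else sprintf(", ED %.3f s", x$ed)
  ))
  invisible(x)
}

#' Calibrate a raw pressure waveform to brachial mean and diastolic pressure
#'
#' Applies the unique affine transform `a * raw + b` whose minimum equals the
#' brachial diastolic pressure and whose time average equals the brachial
#' mean pressure, mirroring how an uncalibrated tonometer trace is anchored
#' to cuff readings. The normalized waveform shape is unchanged, and the
#' operation is idempotent.
#'
#' @param raw numeric vector (>= 32 samples) or a `pressure_beat`.
#' @param map_mmHg brachial mean arterial pressure (mmHg).
#' @param dbp_mmHg brachial diastolic pressure (mmHg); must be below `map_mmHg`.
#' @param dt sampling interval (s); taken from `raw` when it is a beat.
#' @return A calibrated [pressure_beat()].
#' @export
calibrate_pressure <- function(raw, map_mmHg, dbp_mmHg, dt = NULL) {
  ed <- NULL
  if (inherits(raw, "beat")) {
    dt <- raw$dt
    ed <- raw$ed
    raw <- raw$samples
  }
  raw <- as.numeric(raw)
  if (is.null(dt)) validation_error("dt is required when raw is a bare vector")
  if (length(raw) < 32L)
    validation_error("calibration needs at least 32 samples")
  if (!is.finite(map_mmHg) || !is.finite(dbp_mmHg) || map_mmHg <= dbp_mmHg)
    validation_error("brachial MAP must exceed brachial DBP")
  lo <- min(raw); mu <- mean(raw)
  if (mu - lo <= 1e-12 * max(1, abs(mu)))
    degenerate_error("raw signal is (near-)constant: cannot calibrate")
  a <- (map_mmHg - dbp_mmHg) / (mu - lo)
  b <- dbp_mmHg - a * lo
  pressure_beat(a * raw + b, dt, ed = ed)
}

#' Resample a beat by band-limited periodic interpolation
#'
#' Fourier resampling of the one-cycle periodic signal: the discrete
#' spectrum is truncated or zero-padded to the target length and inverted.
#' The mean (DC component) is preserved exactly; for band-limited signals
#' every retained harmonic is preserved with its amplitude.
#'
#' @param beat a beat object.
#' @param n target sample count (>= 32).
#' @return A beat of the same class with `n` samples over the same period.
#' @export
resample_beat <- function(beat, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 32L) validation_error("target sample count must be >= 32")
  y <- resample_fft(beat$samples, n)
  dt_new <- beat_period(beat) / n
  if (inherits(beat, "flow_beat")) {
    # interpolation ripple can dip marginally below zero
    flow_beat(pmax(y, 0), dt_new, ed = beat$ed)
  } else {
    pressure_beat(y, dt_new, ed = beat$ed, foot_index = beat$foot_index)
  }
}

# FFT-based resampling of a real periodic signal from n to m points
resample_fft <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x) / n
  Y <- complex(length.out = m)
  keep <- floor((min(n, m) - 1) / 2)  # harmonics strictly below both Nyquists
  Y[1] <- X[1]
  if (keep >= 1) {
    Y[2:(keep + 1)] <- X[2:(keep + 1)]
    Y[(m - keep + 1):m] <- X[(n - keep + 1):n]
  }
  if (m > n && n %% 2 == 0) {
    # split the source Nyquist bin symmetrically to keep the output real
    k <- n / 2
    Y[k + 1] <- X[k + 1] / 2
    Y[m - k + 1] <- X[k + 1] / 2
  }
  Re(stats::fft(Y, inverse = TRUE))
}

#' Ensemble-average a set of beats
#'
#' Beats are resampled to a common length, foot-aligned by circular shift,
#' and averaged pointwise; the result is assigned the median period of the
#' inputs (duration normalization). With a single beat this is the identity.
#'
#' @param beats list of beats (all pressure or all flow).
#' @param n common sample count used for the average (default 128).
#' @return An averaged beat of the same class as the inputs.
#' @export
ensemble_average <- function(beats, n = 128L) {
  if (!is.list(beats) || length(beats) == 0L)
    validation_error("need at least one beat to average")
  per_med <- stats::median(vapply(beats, beat_period, numeric(1)))
  rs <- lapply(beats, resample_beat, n = n)
  feet <- vapply(rs, function(b) detect_fiducials(b)$foot_index, integer(1))
  # align every beat's foot onto the first beat's frame
  mat <- vapply(seq_along(rs), function(i) {
    circshift(rs[[i]]$samples, -(feet[i] - feet[1]))
  }, numeric(n))
  avg <- rowMeans(mat)
  dt <- per_med / n
  if (inherits(beats[[1]], "flow_beat")) flow_beat(pmax(avg, 0), dt)
  else pressure_beat(avg, dt)
}
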