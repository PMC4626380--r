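#' Detect wave foot, systolic peak and ejection duration
#'
#' The foot is the cycle minimum immediately preceding the steepest upstroke
#' (searched circularly). For a pressure beat the end of ejection is marked
#' by the incisura, located as the maximum of the second time derivative in
#' a search window from `0.15 T` (but after the systolic peak) to `0.45 T`
#' — a fraction-of-cycle window consistent with physiological ejection
#' times on smooth averaged beats. For a flow beat the ejection duration is
#' the end of the positive systolic lobe (last sample above 2% of peak
#' flow).
#'
#' @param beat a [pressure_beat()] or [flow_beat()].
#' Detection operates on a lightly low-passed copy of the beat (harmonics
#' above ~20 removed) so that measurement noise does not masquerade as an
#' upstroke or incisura; all indices refer to the original sampling.
#'
#' @return A list with `foot_index`, `peak_index`, and `ed` (s, measured
#'   from the foot).
#' @export
detect_fiducials <- function(beat) {
  x_raw <- beat$samples
  n <- length(x_raw)
  dt <- beat$dt
  per <- n * dt
  rng <- max(x_raw) - min(x_raw)
  if (rng <= 1e-12 * max(1, abs(mean(x_raw))))
    degenerate_error("flat signal: no detectable upstroke")
  x <- lowpass_harmonics(x_raw, min(20L, n %/% 5L))

  d <- (circshift(x, -1L) - x) / dt            # forward difference
  up <- which.max(d)
  if (d[up] <= 0) degenerate_error("no rising edge found")

  # walk circularly backwards from the steepest upstroke while the signal
  # keeps falling; ties (flat diastole) stop the walk at the rise onset
  foot <- up
  for (step in seq_len(n)) {
    prev <- ((foot - 2L) %% n) + 1L
    if (x[prev] >= x[foot] - 1e-12 * rng) break
    foot <- prev
    if (step == n) break
  }
  # refine on the raw samples: smoothing ripple can displace a flat minimum
  nb <- ((foot - 4L):(foot + 2L)) %% n + 1L
  vmin <- min(x_raw[nb])
  cand <- nb[x_raw[nb] <= vmin + 1e-12 * rng]
  foot <- cand[which.min(((up - cand) %% n))]

  xa <- circshift(x, -(foot - 1L))             # foot-aligned view
  peak_rel <- which.max(xa)

  if (inherits(beat, "flow_beat")) {
    # threshold crossing on the raw lobe (diastole is exactly zero there)
    xr <- circshift(x_raw, -(foot - 1L))
    thr <- 0.02 * max(xr)
    above <- which(xr > thr)
    end_rel <- if (length(above)) max(above) else peak_rel
    ed <- end_rel * dt
  } else {
    d2 <- (circshift(xa, -1L) - 2 * xa + circshift(xa, 1L)) / dt^2
    lo <- ceiling(0.15 * n)
    hi <- floor(0.45 * n)
    if (peak_rel < hi) lo <- max(lo, peak_rel + 1L)
    win <- lo:hi
    ed <- (win[which.max(d2[win])] - 1L) * dt
  }
  if (ed <= 0 || ed >= per)
    degenerate_error("ejection duration detection failed")

  list(foot_index = foot,
       peak_index = ((foot - 1L + peak_rel - 1L) %% n) + 1L,
       ed = ed)
}

# zero out harmonics above kmax (detection-time denoising)
lowpass_harmonics <- function(x, kmax) {
  n <- length(x)
  if (kmax >= (n - 1) %/% 2) return(x)
  X <- stats::fft(x)
  keep <- c(seq_len(kmax + 1L), seq(n - kmax + 1L, n))
  X[-keep] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Fill in the ejection duration of a beat, detecting it if absent
#' @param beat a beat object.
#' @return The beat with its `ed` field set.
#' @export
with_ed <- function(beat) {
  if (is.null(beat$ed)) beat$ed <- detect_fiducials(beat)$ed
  beat
}
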