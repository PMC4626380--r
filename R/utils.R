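# internal helpers shared across modules

# circular shift: positive k moves samples later in time (x[i] -> x[i+k])
circshift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(x)
  c(x[(n - k + 1L):n], x[1L:(n - k)])
}

# linear periodic interpolation of one-cycle samples at arbitrary times
interp_periodic <- function(x, dt, t) {
  n <- length(x)
  per <- n * dt
  tt <- t %% per
  i0 <- floor(tt / dt)
  frac <- tt / dt - i0
  ia <- (i0 %% n) + 1L
  ib <- ((i0 + 1L) %% n) + 1L
  x[ia] * (1 - frac) + x[ib] * frac
}

stop_hw <- function(kind, msg) {
  cond <- structure(
    class = c(paste0("hemowave_", kind), "hemowave_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

validation_error <- function(msg) stop_hw("validation", msg)
degenerate_error <- function(msg) stop_hw("degenerate", msg)
quality_error <- function(msg) stop_hw("quality", msg)
convergence_error <- function(msg) stop_hw("convergence", msg)
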