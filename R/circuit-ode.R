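#' Carrier-level response of the full series circuit
#'
#' Independent second-order model of the coil: integrates the series RLC
#' circuit equation `L di/dt + R i + q/C = V(t)` with
#' `V(t) = a(t) * cos(2*pi*drive_hz*t)`, where `a(t)` is the signed
#' piecewise-constant train amplitude (the sign flip implements the 180-degree
#' phase inversion). Integration uses the classical fixed-step 4th-order
#' Runge-Kutta scheme (via [deSolve::rk4()]) on an internal grid of at least
#' 40 steps per carrier cycle, starting from zero current and charge; the
#' returned trace is subsampled to `rate`. The waveform is `R * i(t)`, so that
#' at resonance the steady-state envelope equals the drive amplitude, matching
#' the normalized-gain convention of [envelope_response()]. This model is the
#' validation oracle for the first-order envelope engine.
#'
#' @param train A [pulse_train()].
#' @param circuit An [circuit_params()] object.
#' @param rate Output sampling rate in samples/s; must be at least
#'   `20 * f_r` to resolve the carrier.
#' @param tail_s Extra zero-drive time appended after the train (s), to
#'   observe the ring-down.
#' @param drive_hz Carrier frequency of the drive (Hz); defaults to the
#'   circuit resonance frequency.
#'
#' @return An [rf_trace()] of `R * i(t)` sampled at `rate`.
#' @export
full_circuit_response <- function(train, circuit, rate, tail_s = 0,
                                  drive_hz = circuit$f_r) {
  stopifnot(inherits(train, "pulse_train"), inherits(circuit, "rf_circuit"),
            is.numeric(rate), length(rate) == 1L, is.finite(rate))
  if (rate < 20 * circuit$f_r)
    stop(sprintf("rate too low to resolve the carrier: need >= %.6g samples/s (20 * f_r)",
                 20 * circuit$f_r))
  total <- train_duration(train) + tail_s
  if (total <= 0) stop("train (plus tail) has zero duration")

  nsub <- max(1L, ceiling(40 * circuit$f_r / rate))
  dt <- 1 / (rate * nsub)
  times <- seq(0, total, by = dt)

  omega_d <- 2 * pi * drive_hz
  amp <- train$amplitude
  starts <- c(0, cumsum(train$duration_s))
  n_seg <- nrow(train)
  deriv <- function(t, y, p) {
    k <- findInterval(t, starts)
    a <- if (k >= 1 && k <= n_seg) amp[k] else 0
    V <- a * cos(omega_d * t)
    list(c((V - p$R * y[1L] - y[2L] / p$C) / p$L, y[1L]))
  }
  out <- deSolve::rk4(c(i = 0, q = 0), times, deriv,
                      parms = circuit[c("L", "R", "C")])
  keep <- seq(1L, length(times), by = nsub)
  rf_trace(t = times[keep], v = circuit$R * out[keep, "i"], rate = rate)
}
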