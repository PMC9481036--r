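#' Synthetic ring-down trace
#'
#' Generates an oscilloscope-style record of a coil ringing down from
#' amplitude `A0` at `t = 0`:
#' `v(t) = A0 * exp(-t/T) * cos(2*pi*f_hz*t) + noise`, with `T = 2Q/omega`
#' and additive white Gaussian noise. These traces stand in for sniffer-loop
#' measurements so the Q estimators can be exercised offline; the generating
#' `Q` is recorded in the trace's `q_true` attribute for recovery tests.
#'
#' @param f_hz Carrier frequency (Hz).
#' @param Q Generating quality factor (> 0); `Inf` gives a constant-amplitude
#'   cosine.
#' @param duration_s Record length in seconds.
#' @param A0 Initial envelope amplitude (default 1).
#' @param rate Sampling rate in samples/s (default 50e6, oscilloscope-class:
#'   50 samples per cycle at 1 MHz); must be at least `20 * f_hz`.
#' @param noise_sd Standard deviation of additive Gaussian noise (same units
#'   as `v`; default 0).
#' @param seed Optional integer seed for reproducible noise.
#' @return An [rf_trace()] with attribute `q_true`.
#' @examples
#' tr <- gen_ringdown_trace(1e6, 49.83, duration_s = 40e-6)
#' @export
gen_ringdown_trace <- function(f_hz, Q, duration_s, A0 = 1, rate = 50e6,
                               noise_sd = 0, seed = NULL) {
  stopifnot(is.numeric(f_hz), f_hz > 0, is.numeric(Q), Q > 0,
            is.numeric(duration_s), duration_s > 0, noise_sd >= 0)
  if (rate < 20 * f_hz)
    stop(sprintf("rate too low: need >= %.6g samples/s (20 * f_hz)", 20 * f_hz))
  t <- seq.int(0L, floor(duration_s * rate)) / rate
  Tc <- 2 * Q / (2 * pi * f_hz)
  env <- if (is.finite(Q)) A0 * exp(-t / Tc) else rep(A0, length(t))
  v <- env * cos(2 * pi * f_hz * t)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + stats::rnorm(length(v), sd = noise_sd)
  }
  out <- rf_trace(t, v, rate)
  attr(out, "q_true") <- Q
  out
}

#' Synthetic carrier-level trace of a driven coil
#'
#' The "actual signal" a sniffer loop would record while a pulse train drives
#' the coil: the first-order model envelope ([envelope_response()]) modulating
#' the carrier, `v(t) = A(t) * cos(2*pi*f_r*t)` (signed envelope values carry
#' the 180-degree phase flips), plus optional additive Gaussian noise.
#'
#' @param train A [pulse_train()].
#' @param coil An [coil_params()] object.
#' @param rate Sampling rate in samples/s (default 50e6); at least
#'   `20 * f_r`.
#' @param tail_s Extra zero-drive time after the train, to capture ring-down
#'   (default `6 * coil$T`).
#' @param noise_sd Additive Gaussian noise standard deviation (default 0).
#' @param seed Optional integer seed.
#' @return An [rf_trace()].
#' @export
gen_pulse_trace <- function(train, coil, rate = 50e6, tail_s = 6 * coil$T,
                            noise_sd = 0, seed = NULL) {
  stopifnot(inherits(train, "pulse_train"), inherits(coil, "rf_coil"),
            noise_sd >= 0, tail_s >= 0)
  if (rate < 20 * coil$f_r)
    stop(sprintf("rate too low: need >= %.6g samples/s (20 * f_r)", 20 * coil$f_r))
  total <- train_duration(train) + tail_s
  if (total <= 0) stop("train (plus tail) has zero duration")
  t <- seq.int(0L, floor(total * rate)) / rate
  env <- envelope_response(train, coil, t)
  v <- env * cos(2 * pi * coil$f_r * t)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + stats::rnorm(length(v), sd = noise_sd)
  }
  rf_trace(t, v, rate)
}
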