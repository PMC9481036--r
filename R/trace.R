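#' Uniformly sampled voltage trace
#'
#' Oscilloscope-style record: sample times `t` on a uniform grid, instantaneous
#' voltages `v`, and the sampling rate. Traces are produced by the synthetic
#' generators ([gen_ringdown_trace()], [gen_pulse_trace()]), by the circuit
#' simulator ([full_circuit_response()]) and by [read_trace()].
#'
#' @param t Sample times in seconds, strictly increasing on a uniform grid.
#' @param v Voltages, same length as `t`.
#' @param rate Sampling rate in samples/s; must satisfy
#'   `rate * diff(t) == 1` within a relative tolerance of 1e-6.
#'
#' @return An object of class `rf_trace`: a list with elements `t`, `v`,
#'   `rate`.
#' @export
rf_trace <- function(t, v, rate) {
  stopifnot(is.numeric(t), is.numeric(v), length(t) == length(v),
            is.numeric(rate), length(rate) == 1L, rate > 0)
  if (length(t) < 2L) stop("a trace needs at least 2 samples")
  dt <- diff(t)
  if (any(dt <= 0)) stop("trace time column must be strictly increasing")
  if (any(abs(rate * dt - 1) > 1e-6))
    stop("non-uniform time grid: rate * diff(t) must equal 1")
  structure(list(t = as.numeric(t), v = as.numeric(v), rate = rate),
            class = "rf_trace")
}

#' @export
print.rf_trace <- function(x, ...) {
  cat(sprintf("RF trace: %d samples at %.4g MS/s, span %.4g us, peak |v| = %.4g\n",
              length(x$t), x$rate / 1e6,
              (x$t[length(x$t)] - x$t[1]) * 1e6, max(abs(x$v))))
  invisible(x)
}

#' @param x An `rf_trace`.
#' @param time_unit Scale factor for the time axis (default microseconds).
#' @param ... Passed to [graphics::plot()].
#' @rdname rf_trace
#' @export
plot.rf_trace <- function(x, time_unit = 1e6, ...) {
  graphics::plot(x$t * time_unit, x$v, type = "l",
                 xlab = "time", ylab = "voltage", ...)
  invisible(x)
}
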