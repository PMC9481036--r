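#' Envelope response of a coil to a pulse train
#'
#' Exact rotating-frame envelope of a first-order resonant coil driven by a
#' piecewise-constant train. The envelope obeys
#' `dA/dt = (omega / 2Q) * (V(t) - A)`, `A(0) = 0`, i.e. relaxation toward the
#' instantaneous drive level with time constant `T = 2Q/omega`. Because the
#' drive is piecewise constant the solution is propagated analytically across
#' segment boundaries (no numerical integration):
#' within a segment of amplitude `V`,
#' `A(t0 + s) = V + (A(t0) - V) * exp(-s/T)`. Under constant drive `V` the
#' equilibrium envelope equals `V` (normalized unit gain; apply `gain` for
#' dimensional traces). After the last segment the drive is zero and the
#' envelope rings down exponentially.
#'
#' Signed amplitudes represent the carrier phase: a negative segment (180
#' degrees out of phase) pulls the envelope through zero, which is how a
#' damping lobe cancels stored energy.
#'
#' @param train A [pulse_train()].
#' @param coil An [coil_params()] object.
#' @param times Sorted numeric vector of non-negative times (s).
#' @param gain Optional scalar gain applied to the result (default 1).
#'
#' @return Numeric vector of signed envelope amplitudes, one per time.
#' @examples
#' coil <- coil_params(1e6, 49.83)
#' tr <- pulse_train(1, 40e-6)
#' envelope_response(tr, coil, coil$T)  # 1 - exp(-1)
#' @export
envelope_response <- function(train, coil, times, gain = 1) {
  stopifnot(inherits(train, "pulse_train"), inherits(coil, "rf_coil"),
            is.numeric(times))
  if (length(times) == 0L) return(numeric(0))
  if (!all(is.finite(times))) stop("`times` must be finite")
  if (is.unsorted(times)) stop("`times` must be sorted increasing")
  if (any(times < 0)) stop("negative times are not in the model domain")

  n <- nrow(train)
  if (n == 0L) return(numeric(length(times)))
  Tc <- coil$T
  amp <- train$amplitude
  dur <- train$duration_s

  # envelope at segment boundaries, propagated exactly
  bound <- numeric(n + 1L)
  decay <- exp(-dur / Tc)
  for (j in seq_len(n))
    bound[j + 1L] <- amp[j] + (bound[j] - amp[j]) * decay[j]

  starts <- c(0, cumsum(dur))
  idx <- findInterval(times, starts)          # n+1 => past the end of the train
  v_seg <- c(amp, 0)[idx]
  a0 <- bound[idx]
  elapsed <- times - starts[idx]
  gain * (v_seg + (a0 - v_seg) * exp(-elapsed / Tc))
}
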