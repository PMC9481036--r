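#' Transmit-coil parameters
#'
#' A resonant RF transmit coil is characterized by its resonance frequency
#' `f_r` and quality factor `Q`. In the rotating frame the coil envelope obeys
#' a first-order relaxation with time constant `T = 2Q/omega`
#' (`omega = 2*pi*f_r`): the same constant governs both the rise toward the
#' drive level and the ring-down after switch-off. For a narrow-band coil
#' (high `Q`, low `f_r`) `T` is long compared to typical pulse durations,
#' which is the distortion this package compensates.
#'
#' @param f_r Resonance (carrier) frequency in Hz; must be positive.
#' @param Q Quality factor (dimensionless); must be positive.
#'
#' @return An object of class `rf_coil`: a list with elements `f_r`, `Q`,
#'   `omega` (angular frequency, rad/s) and `T` (envelope time constant, s).
#'
#' @examples
#' coil <- coil_params(f_r = 1e6, Q = 49.83)
#' coil$T  # 2Q/omega, about 15.9 microseconds
#' @export
coil_params <- function(f_r, Q) {
  stopifnot(is.numeric(f_r), length(f_r) == 1L, is.finite(f_r),
            is.numeric(Q), length(Q) == 1L, is.finite(Q))
  if (f_r <= 0) stop("`f_r` must be positive (Hz)")
  if (Q <= 0) stop("`Q` must be positive")
  omega <- 2 * pi * f_r
  structure(list(f_r = f_r, Q = Q, omega = omega, T = 2 * Q / omega),
            class = "rf_coil")
}

#' @export
print.rf_coil <- function(x, ...) {
  cat(sprintf("RF coil: f_r = %g Hz, Q = %g (T = 2Q/omega = %.4g us)\n",
              x$f_r, x$Q, x$T * 1e6))
  invisible(x)
}

#' Series-circuit parameters of a coil
#'
#' Lumped-element description of the coil as a series RLC circuit driven by a
#' voltage source. Used by the second-order simulator
#' [full_circuit_response()], which serves as an independent check on the
#' first-order envelope model.
#'
#' @param L Inductance in henry.
#' @param R Resistance in ohm.
#' @param C Capacitance in farad.
#'
#' @return An object of class `rf_circuit` with elements `L`, `R`, `C`,
#'   `omega` (resonance angular frequency `1/sqrt(LC)`), `f_r` and `Q`
#'   (`omega * L / R`).
#' @examples
#' circ <- circuit_params(L = 10e-6, R = 1.26, C = 2.533e-9)
#' q_from_circuit(circ)  # about 49.9
#' @export
circuit_params <- function(L, R, C) {
  for (nm in c("L", "R", "C")) {
    val <- get(nm)
    stopifnot(is.numeric(val), length(val) == 1L, is.finite(val))
    if (val <= 0) stop(sprintf("`%s` must be positive", nm))
  }
  omega <- 1 / sqrt(L * C)
  structure(list(L = L, R = R, C = C, omega = omega,
                 f_r = omega / (2 * pi), Q = omega * L / R),
            class = "rf_circuit")
}

#' @export
print.rf_circuit <- function(x, ...) {
  cat(sprintf(
    "Series RLC circuit: L = %g H, R = %g ohm, C = %g F (f_r = %.6g Hz, Q = %.4g)\n",
    x$L, x$R, x$C, x$f_r, x$Q))
  invisible(x)
}

#' Quality factor of a series circuit
#'
#' `Q = omega * L / R` with `omega = 1/sqrt(LC)`.
#'
#' @param circuit An [circuit_params()] object.
#' @return The quality factor (dimensionless).
#' @examples
#' q_from_circuit(circuit_params(L = 10e-6, R = 1.26, C = 2.533e-9))
#' @export
q_from_circuit <- function(circuit) {
  stopifnot(inherits(circuit, "rf_circuit"))
  circuit$omega * circuit$L / circuit$R
}

#' First-order coil parameters implied by a series circuit
#'
#' @param circuit An [circuit_params()] object.
#' @return An [coil_params()] object with the circuit's `f_r` and `Q`.
#' @export
coil_from_circuit <- function(circuit) {
  stopifnot(inherits(circuit, "rf_circuit"))
  coil_params(circuit$f_r, q_from_circuit(circuit))
}
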