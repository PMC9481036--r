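#' Estimate the quality factor from a ring-down trace
#'
#' After the drive is switched off, the coil envelope decays as
#' `exp(-t/T)` with `T = 2Q/omega`, so the number of carrier cycles `N` it
#' takes the envelope to halve measures `Q` directly:
#' `Q = pi * N / ln 2` (approximately `4.53 N`).
#'
#' Switch-off is detected as the global envelope maximum of the trace; the
#' ring-down is everything after it. The trace is partitioned into carrier
#' cycles and the envelope of each cycle is the maximum of `|v|` within it
#' (robust to sampling-phase offsets). The first post-switch-off cycle's peak
#' is the reference amplitude.
#'
#' Two estimators are available:
#' \describe{
#'   \item{`"integer-count"`}{`N` is the first whole cycle at which the peak
#'     envelope has dropped to half the reference (counting cycles, the way
#'     one reads an oscilloscope screen).}
#'   \item{`"decimal-fit"`}{a straight line is fit to `log(peak)` versus cycle
#'     index and `N = ln 2 / |slope|`; fractional, and considerably more
#'     precise than counting whole cycles. Peaks below `fit_floor` times the
#'     reference are excluded so the fit stays above the noise floor.}
#' }
#'
#' @param trace An [rf_trace()] containing a decaying oscillation.
#' @param carrier_hz Carrier frequency in Hz (defines the cycle length).
#' @param method `"decimal-fit"` (default) or `"integer-count"`.
#' @param rounded_constant If `TRUE`, use the two-decimal constant 4.53 in
#'   place of the exact `pi/ln 2 = 4.5324...` — the hand-calculation
#'   convention `Q = 4.53 N`.
#' @param fit_floor Fraction of the reference peak below which cycles are
#'   excluded from the decimal fit (default 0.15).
#'
#' @return An object of class `ringdown_fit`: list with `N` (cycles to
#'   halve), `Q`, `fit_points`, `residual` (residual standard error of the
#'   log-linear fit; `NA` for integer counting), `method`, `constant`.
#' @examples
#' coil <- coil_params(1e6, 49.83)
#' tr <- gen_ringdown_trace(1e6, 49.83, duration_s = 60e-6, rate = 5e7)
#' q_from_ringdown(tr, 1e6)
#' @export
q_from_ringdown <- function(trace, carrier_hz,
                            method = c("decimal-fit", "integer-count"),
                            rounded_constant = FALSE, fit_floor = 0.15) {
  stopifnot(inherits(trace, "rf_trace"), is.numeric(carrier_hz),
            length(carrier_hz) == 1L, carrier_hz > 0)
  method <- match.arg(method)

  k0 <- which.max(abs(trace$v))
  tt <- trace$t[k0:length(trace$t)] - trace$t[k0]
  vv <- abs(trace$v[k0:length(trace$v)])

  # per-cycle peak envelope over complete carrier cycles
  n_full <- floor(max(tt) * carrier_hz)
  if (n_full < 3L)
    stop("fewer than 3 carrier cycles after switch-off; cannot estimate Q")
  cyc <- floor(tt * carrier_hz + 1e-9)
  in_range <- cyc < n_full
  peaks <- as.numeric(tapply(vv[in_range], cyc[in_range], max))
  if (length(peaks) < 3L)
    stop("fewer than 3 ring-down peaks detected")
  if (peaks[length(peaks)] >= peaks[1L])
    stop("trace does not decay after the detected switch-off")
  ref <- peaks[1L]

  if (method == "integer-count") {
    below <- which(peaks <= ref / 2 * (1 + 1e-6)) - 1L  # 0-based cycle index
    below <- below[below >= 1L]
    if (!length(below))
      stop("envelope never halves within the trace; record a longer ring-down")
    N <- as.numeric(below[1L])
    fit_points <- below[1L] + 1L
    residual <- NA_real_
  } else {
    keep <- which(peaks >= fit_floor * ref)
    if (length(keep) < 3L)
      stop("fewer than 3 peaks above the fit floor")
    k <- keep - 1L
    fit <- stats::lm(log(peaks[keep]) ~ k)
    slope <- unname(stats::coef(fit)[2L])
    if (!is.finite(slope) || slope >= 0)
      stop("log-peak fit has non-negative slope; trace does not decay")
    N <- log(2) / (-slope)
    fit_points <- length(keep)
    r <- stats::residuals(fit)
    df <- length(r) - 2L
    residual <- if (df > 0L) sqrt(sum(r^2) / df) else 0
  }

  constant <- if (rounded_constant) 4.53 else pi / log(2)
  structure(list(N = N, Q = constant * N, fit_points = fit_points,
                 residual = residual, method = method, constant = constant),
            class = "ringdown_fit")
}

#' @export
print.ringdown_fit <- function(x, ...) {
  cat(sprintf("Ring-down Q estimate (%s): N = %.4g cycles to halve, Q = %.4g\n",
              x$method, x$N, x$Q))
  cat(sprintf("  %d peak(s) used; constant %.4f%s\n", x$fit_points, x$constant,
              if (is.na(x$residual)) ""
              else sprintf("; log-fit residual SE %.3g", x$residual)))
  invisible(x)
}

#' @export
coef.ringdown_fit <- function(object, ...) {
  c(N = object$N, Q = object$Q)
}

#' Quality factor from a -3 dB bandwidth measurement
#'
#' `Q = f_r / (f_H - f_L)`: the ratio of the resonance frequency to the
#' half-power bandwidth, as measured with sniffer loops or from return loss.
#'
#' @param f_r Resonance frequency (Hz).
#' @param f_lo Lower -3 dB frequency (Hz).
#' @param f_hi Upper -3 dB frequency (Hz).
#' @return Quality factor.
#' @examples
#' q_from_bandwidth(1e6, 0.99e6, 1.01e6)  # 50
#' @export
q_from_bandwidth <- function(f_r, f_lo, f_hi) {
  stopifnot(is.numeric(f_r), is.numeric(f_lo), is.numeric(f_hi))
  if (f_hi <= f_lo) stop("`f_hi` must exceed `f_lo`")
  if (f_r <= f_lo || f_r >= f_hi)
    stop("resonance frequency must lie inside (f_lo, f_hi)")
  f_r / (f_hi - f_lo)
}

#' Half-power bandwidth implied by a quality factor
#'
#' Inverse of [q_from_bandwidth()]: `BW = f_r / Q`.
#'
#' @param Q Quality factor.
#' @param f_r Resonance frequency (Hz).
#' @return Bandwidth `f_H - f_L` in Hz.
#' @export
bandwidth_from_q <- function(Q, f_r) {
  stopifnot(Q > 0, f_r > 0)
  f_r / Q
}

#' Carrier cycles for the ring-down envelope to halve
#'
#' Inverse of the cycle-counting relation: `N = Q * ln 2 / pi`.
#'
#' @param Q Quality factor (> 0).
#' @return Number of carrier cycles (possibly fractional).
#' @examples
#' cycles_to_halve(49.83)  # about 11
#' @export
cycles_to_halve <- function(Q) {
  stopifnot(is.numeric(Q), all(Q > 0))
  Q * log(2) / pi
}
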