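#' Extract the signed envelope from a carrier-level trace
#'
#' Demodulates an oscilloscope-style trace: the trace is partitioned into
#' carrier cycles, the envelope of each cycle is the maximum of `|v|` within
#' it, and the sign is recovered by correlating each cycle against the
#' in-phase carrier `cos(2*pi*carrier_hz*t)` so that 180-degree
#' (phase-inverted) lobes come out negative. The per-cycle values are then
#' linearly interpolated back onto the trace's own time grid.
#'
#' @param trace An [rf_trace()].
#' @param carrier_hz Carrier frequency (Hz); the sampling rate must be at
#'   least `4 * carrier_hz`.
#' @return An [rf_trace()] holding the signed envelope on the same grid.
#' @export
envelope_extract <- function(trace, carrier_hz) {
  stopifnot(inherits(trace, "rf_trace"), is.numeric(carrier_hz),
            length(carrier_hz) == 1L, carrier_hz > 0)
  if (trace$rate < 4 * carrier_hz)
    stop(sprintf("rate too low for envelope extraction: need >= %.6g samples/s (4 * carrier)",
                 4 * carrier_hz))
  t0 <- trace$t[1L]
  cyc <- floor((trace$t - t0) * carrier_hz + 1e-9)
  ref <- cos(2 * pi * carrier_hz * (trace$t - t0))
  groups <- split(seq_along(trace$t), cyc)
  # anchor each cycle's envelope value at the sample that attains it, so a
  # rising or falling envelope is not biased toward the cycle center
  at <- vapply(groups, function(ix) ix[which.max(abs(trace$v[ix]))], 0L)
  peak <- abs(trace$v[at])
  sgn <- vapply(groups, function(ix) sign(sum(trace$v[ix] * ref[ix])), 0)
  env <- stats::approx(trace$t[at], sgn * peak, xout = trace$t,
                       rule = 2, ties = "ordered")$y
  rf_trace(trace$t, env, trace$rate)
}

#' Magnitude spectrum of a trace or envelope
#'
#' Zero-padded discrete Fourier magnitude spectrum, two-sided (negative and
#' positive frequencies) and normalized to peak 1. Zero padding to at least
#' `pad_factor` times the input length gives a smooth sampling of the
#' continuous spectrum so the in-band flatness metric does not depend on the
#' record length. The pre-normalization scale is kept in the `scale` element.
#'
#' @param x An [rf_trace()] (carrier trace or extracted envelope), or a
#'   numeric vector (then `rate` is required).
#' @param rate Sampling rate in samples/s when `x` is a bare numeric vector.
#' @param pad_factor Minimum zero-padding factor (default 16); the FFT length
#'   is the next power of two of `pad_factor * length(x)`.
#' @param pad_to Explicit FFT length, overriding `pad_factor`.
#' @param center Band center frequency in Hz: the carrier frequency for an RF
#'   trace, 0 for a baseband envelope (default 0).
#' @param bw Optional bandwidth in Hz; sets the evaluation band
#'   `center +- bw/2` used by [relative_error()].
#'
#' @return An object of class `rf_spectrum`: list with `f` (Hz, uniform,
#'   increasing), `mag` (normalized to max 1), `center`, `band` (length-2 or
#'   `NULL`), `scale` (pre-normalization peak magnitude) and `nfft`.
#' @export
magnitude_spectrum <- function(x, rate = NULL, pad_factor = 16, pad_to = NULL,
                               center = 0, bw = NULL) {
  if (inherits(x, "rf_trace")) {
    v <- x$v
    rate <- x$rate
  } else {
    stopifnot(is.numeric(x), !is.null(rate))
    v <- as.numeric(x)
  }
  n <- length(v)
  if (n < 1L) stop("empty input")
  nfft <- if (!is.null(pad_to)) as.integer(pad_to) else
    2L^ceiling(log2(max(pad_factor * n, 2)))
  if (nfft < n) stop("`pad_to` must be at least the input length")

  mag <- Mod(stats::fft(c(v, numeric(nfft - n))))
  k <- seq_len(nfft) - 1L
  freq <- k / nfft * rate
  hi <- k >= nfft / 2
  freq[hi] <- freq[hi] - rate
  o <- order(freq)
  scale <- max(mag)
  if (scale == 0) scale <- 1       # all-zero input stays all-zero
  band <- if (!is.null(bw)) center + c(-0.5, 0.5) * bw else NULL
  structure(list(f = freq[o], mag = mag[o] / scale, center = center,
                 band = band, scale = scale, nfft = nfft),
            class = "rf_spectrum")
}

#' Construct a spectrum from frequency/magnitude pairs
#'
#' Mostly useful for testing the flatness metric on hand-built spectra.
#'
#' @param f Frequency grid (Hz), uniform and increasing.
#' @param mag Magnitudes in `[0, 1]`, same length as `f`.
#' @param center Band center (Hz).
#' @param band Optional length-2 evaluation band (Hz).
#' @return An `rf_spectrum` object.
#' @export
rf_spectrum <- function(f, mag, center = 0, band = NULL) {
  stopifnot(is.numeric(f), is.numeric(mag), length(f) == length(mag))
  if (any(mag < 0 | mag > 1)) stop("`mag` must lie in [0, 1]")
  if (is.unsorted(f, strictly = TRUE)) stop("`f` must be strictly increasing")
  if (!is.null(band)) {
    stopifnot(length(band) == 2L, band[1L] < band[2L])
    if (band[1L] < min(f) || band[2L] > max(f))
      stop("`band` must lie within the frequency range")
  }
  structure(list(f = as.numeric(f), mag = as.numeric(mag), center = center,
                 band = band, scale = 1, nfft = length(f)),
            class = "rf_spectrum")
}

#' @export
print.rf_spectrum <- function(x, ...) {
  cat(sprintf("Spectrum: %d points, %.4g to %.4g Hz, center %.4g Hz",
              length(x$f), min(x$f), max(x$f), x$center))
  if (!is.null(x$band))
    cat(sprintf(", band [%.4g, %.4g] Hz", x$band[1L], x$band[2L]))
  cat("\n")
  invisible(x)
}

#' @param x An `rf_spectrum`.
#' @param ... Passed to [graphics::plot()].
#' @rdname magnitude_spectrum
#' @export
plot.rf_spectrum <- function(x, ...) {
  graphics::plot(x$f, x$mag, type = "l", xlab = "frequency (Hz)",
                 ylab = "normalized magnitude", ...)
  if (!is.null(x$band)) graphics::abline(v = x$band, lty = 2, col = "grey50")
  invisible(x)
}

#' In-band spectral flatness (relative error)
#'
#' Mean absolute deviation of the normalized in-band magnitude from its
#' in-band mean:
#' `relative_error = mean(|mag - mean(mag)|)` over the points inside the
#' evaluation band. A perfectly rectangular (flat) excitation profile scores
#' 0; distortion — droop, ripple, ring-down leakage — raises the score. The
#' divisor is the number of in-band points, so the metric is invariant both
#' to global magnitude scaling and to the zero-padding resolution.
#'
#' @param spec An `rf_spectrum`.
#' @param band Optional length-2 band (Hz) overriding `spec$band`.
#' @return An object of class `flatness_report`: list with `relative_error`,
#'   `n_points_in_band`, `band_mean`.
#' @examples
#' s <- rf_spectrum(f = 0:10, mag = rep(0.8, 11), band = c(2, 8))
#' relative_error(s)$relative_error  # 0: perfectly flat
#' @export
relative_error <- function(spec, band = NULL) {
  stopifnot(inherits(spec, "rf_spectrum"))
  band <- if (!is.null(band)) band else spec$band
  if (is.null(band)) stop("no evaluation band: supply `band` or set it on the spectrum")
  stopifnot(length(band) == 2L, band[1L] < band[2L])
  sel <- spec$f >= band[1L] & spec$f <= band[2L]
  if (!any(sel)) stop("evaluation band contains no spectrum points")
  m <- spec$mag[sel]
  structure(list(relative_error = mean(abs(m - mean(m))),
                 n_points_in_band = sum(sel),
                 band_mean = mean(m)),
            class = "flatness_report")
}

#' @export
print.flatness_report <- function(x, ...) {
  cat(sprintf("In-band flatness: relative error %.4g over %d points (band mean %.4g)\n",
              x$relative_error, x$n_points_in_band, x$band_mean))
  invisible(x)
}
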