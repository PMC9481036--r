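#' Piecewise-constant RF pulse train
#'
#' The universal drive representation in this package: an ordered sequence of
#' square segments, each with a signed amplitude (normalized volts; the sign
#' encodes 0 vs 180 degree carrier phase, so damping lobes are negative) and a
#' duration in seconds. Time starts at 0 at the first segment; segment `n`
#' occupies the half-open interval `[t_{n-1}, t_n)`. After the last segment
#' the drive is zero. An empty train is legal and means no drive at all.
#'
#' @param amplitude Numeric vector of signed segment amplitudes.
#' @param duration_s Numeric vector of segment durations in seconds
#'   (non-negative), same length as `amplitude`.
#'
#' @return An object of class `pulse_train` (a data frame with columns
#'   `amplitude` and `duration_s`).
#' @examples
#' # square pulse with a 180-degree damping lobe
#' pulse_train(amplitude = c(1, -3), duration_s = c(40e-6, 4e-6))
#' @export
pulse_train <- function(amplitude = numeric(), duration_s = numeric()) {
  stopifnot(is.numeric(amplitude), is.numeric(duration_s),
            length(amplitude) == length(duration_s))
  if (length(amplitude) && (!all(is.finite(amplitude)) || !all(is.finite(duration_s))))
    stop("segment amplitudes and durations must be finite")
  if (any(duration_s < 0)) stop("segment durations must be non-negative")
  structure(data.frame(amplitude = as.numeric(amplitude),
                       duration_s = as.numeric(duration_s)),
            class = c("pulse_train", "data.frame"))
}

#' Total duration of a pulse train
#'
#' @param train A [pulse_train()].
#' @return Total duration in seconds (0 for an empty train).
#' @export
train_duration <- function(train) {
  stopifnot(inherits(train, "pulse_train"))
  sum(train$duration_s)
}

#' Drive amplitude at given times
#'
#' Evaluates the piecewise-constant drive of a pulse train. Times before 0 or
#' at/after the end of the train give 0. Segment boundaries follow the
#' half-open convention `[t_{n-1}, t_n)`.
#'
#' @param train A [pulse_train()].
#' @param times Numeric vector of times in seconds.
#' @return Numeric vector of signed drive amplitudes.
#' @export
drive_amplitude <- function(train, times) {
  stopifnot(inherits(train, "pulse_train"), is.numeric(times))
  n <- nrow(train)
  out <- numeric(length(times))
  if (n == 0L) return(out)
  starts <- c(0, cumsum(train$duration_s))
  idx <- findInterval(times, starts)
  live <- idx >= 1L & idx <= n & times >= 0
  out[live] <- train$amplitude[idx[live]]
  out
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("Pulse train: %d segment(s), total %.4g us\n",
              nrow(x), train_duration(x) * 1e6))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

#' @param x A `pulse_train`.
#' @param time_unit Scale factor applied to the time axis for display
#'   (default `1e6`: microseconds).
#' @param ... Passed to [graphics::plot()].
#' @rdname pulse_train
#' @export
plot.pulse_train <- function(x, time_unit = 1e6, ...) {
  tb <- c(0, cumsum(x$duration_s))
  graphics::plot(tb * time_unit, c(x$amplitude, 0), type = "s",
                 xlab = "time", ylab = "drive amplitude", ...)
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}
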