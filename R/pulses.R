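# Pulse and pulse-train containers. A pulse train is stored column-wise as a
# data.frame so long trains stay cheap to build and slice.

#' Construct a voltage pulse
#'
#' @param amplitude pulse amplitude in volts (0 for an unstimulated slot).
#' @param duration pulse width in seconds; must be positive.
#' @param gap_after idle time before the next pulse, seconds.
#' @return an object of class `fibrc_pulse`.
#' @export
pulse <- function(amplitude, duration = 0.2, gap_after = 0.05) {
  assert_scalar_num(amplitude, "amplitude")
  assert_scalar_num(duration, "duration")
  assert_scalar_num(gap_after, "gap_after")
  if (duration <= 0) stop_input("pulse duration must be > 0")
  if (gap_after < 0) stop_input("gap_after must be >= 0")
  structure(list(amplitude = amplitude, duration = duration, gap_after = gap_after),
            class = "fibrc_pulse")
}

#' Construct a pulse train
#'
#' @param amplitude numeric vector of pulse amplitudes (volts).
#' @param duration scalar or vector of pulse widths (seconds).
#' @param gap_after scalar or vector of inter-pulse gaps (seconds).
#' @return an object of class `fibrc_pulse_train` with fields `amplitude`,
#'   `duration`, `gap_after` (equal-length numeric vectors).
#' @export
pulse_train <- function(amplitude, duration = 0.2, gap_after = 0.05) {
  n <- length(amplitude)
  duration <- rep_len(duration, n)
  gap_after <- rep_len(gap_after, n)
  if (n > 0 && (any(!is.finite(amplitude)) || any(duration <= 0) || any(gap_after < 0)))
    stop_input("invalid pulse train: amplitudes must be finite, durations > 0, gaps >= 0")
  structure(list(amplitude = as.numeric(amplitude),
                 duration = as.numeric(duration),
                 gap_after = as.numeric(gap_after)),
            class = "fibrc_pulse_train")
}

#' @export
length.fibrc_pulse_train <- function(x) length(x$amplitude)

#' Total duration of a pulse train (pulses plus gaps), seconds
#' @param train a `fibrc_pulse_train`.
#' @export
train_duration <- function(train) sum(train$duration + train$gap_after)

#' @export
print.fibrc_pulse_train <- function(x, ...) {
  cat(sprintf("<pulse train: %d pulses, %.3f s, amplitudes [%g, %g] V>\n",
              length(x), train_duration(x),
              if (length(x)) min(x$amplitude) else NA, if (length(x)) max(x$amplitude) else NA))
  invisible(x)
}

#' @export
print.fibrc_pulse <- function(x, ...) {
  cat(sprintf("<pulse: %g V for %g s, gap %g s>\n", x$amplitude, x$duration, x$gap_after))
  invisible(x)
}
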