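#' Centered moving average with shrinking end windows
#'
#' Smooths with a centered window of `span` samples. Near the ends the
#' window shrinks symmetrically (1, 3, 5, ... samples) so the output has
#' the same length as the input and stays centered. An even `span` is
#' decremented to the next odd value, with a message.
#'
#' @param series a [resp_ts()].
#' @param span total window length in samples (>= 1).
#' @return A smoothed [resp_ts()] of the same length.
#' @export
moving_average <- function(series, span) {
  stopifnot(inherits(series, "resp_ts"), span >= 1)
  span <- as.integer(span)
  if (span %% 2L == 0L) {
    message("moving_average: even span ", span, " reduced to ", span - 1L,
            " for a centered window")
    span <- span - 1L
  }
  if (span == 1L) return(series)
  v <- series$values
  n <- length(v)
  h <- (span - 1L) %/% 2L
  idx <- seq_len(n)
  w <- pmin(h, idx - 1L, n - idx)
  cs <- cumsum(c(0, v))
  out <- (cs[idx + w + 1L] - cs[idx - w]) / (2 * w + 1)
  resp_ts(out, dt = series$dt, t0 = series$t0)
}

#' Noise floor of a recovery method
#'
#' Every recovery method amplifies sensor noise. Applying the method to a
#' stretch of recording with no gas release yields pure recovered noise;
#' its root-mean-square, times a safety factor (default 2), defines the
#' threshold below which recovered values are treated as noise.
#'
#' @param recovered_quiet a [resp_ts()]: the recovery output on a
#'   baseline-only segment (>= 50 samples).
#' @param factor threshold multiplier on the RMS (default 2).
#' @return An object of class `noise_floor` with fields `rms` and
#'   `threshold = factor * rms`.
#' @export
estimate_noise_floor <- function(recovered_quiet, factor = 2) {
  stopifnot(inherits(recovered_quiet, "resp_ts"), factor >= 0)
  if (length(recovered_quiet$values) < 50L) {
    stop("quiet segment too short (< 50 samples) for a stable RMS",
         call. = FALSE)
  }
  rms <- sqrt(mean(recovered_quiet$values^2))
  structure(list(rms = rms, threshold = factor * rms, factor = factor),
            class = "noise_floor")
}

#' @export
print.noise_floor <- function(x, ...) {
  cat(sprintf("<noise_floor> rms = %g, threshold = %g (factor %g)\n",
              x$rms, x$threshold, x$factor))
  invisible(x)
}

#' Adaptive weak-signal filter
#'
#' Samples whose magnitude is below the noise threshold are replaced by a
#' strong moving average (default span 50); samples at or above the
#' threshold pass through unchanged. The comparison uses the absolute
#' value, so recovery undershoot below minus the threshold is treated as
#' signal rather than over-smoothed.
#'
#' @param recovered a [resp_ts()] recovery output.
#' @param floor a [estimate_noise_floor()] result.
#' @param weak_span moving-average span applied in sub-threshold regions.
#' @return A [resp_ts()] of the same length.
#' @export
adaptive_filter <- function(recovered, floor, weak_span = 50) {
  stopifnot(inherits(recovered, "resp_ts"), inherits(floor, "noise_floor"),
            weak_span >= 1)
  strong <- abs(recovered$values) >= floor$threshold
  sm <- suppressMessages(moving_average(recovered, weak_span))
  out <- ifelse(strong, recovered$values, sm$values)
  resp_ts(out, dt = recovered$dt, t0 = recovered$t0)
}

#' Subtract the baseline estimated from a quiet segment
#'
#' The recovery equations assume the recorded concentration measures the
#' change due to the animal; any analyzer offset must be removed first.
#' The mean over a user-designated quiet (gas-free) time window is
#' subtracted from the whole trace.
#'
#' @param series a [resp_ts()].
#' @param quiet_start_s,quiet_end_s window (seconds) known to contain no
#'   signal.
#' @return A baseline-corrected [resp_ts()].
#' @export
subtract_baseline <- function(series, quiet_start_s, quiet_end_s) {
  stopifnot(inherits(series, "resp_ts"))
  quiet <- ts_window(series, quiet_start_s, quiet_end_s)
  resp_ts(series$values - mean(quiet$values), dt = series$dt,
          t0 = series$t0)
}
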