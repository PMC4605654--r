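#' Convert a recovered dimensionless input to a CO2 release rate
#'
#' The recovered input `u` is the gas exchange rate divided by the flow
#' rate, so the volumetric release rate is `F * u`. With `u` in ppm the
#' result is `u * 1e-6 * F` mL/min, reported in uL/min.
#'
#' @param u recovered input as a [resp_ts()].
#' @param flow_ml_min flow rate F in mL/min.
#' @param unit concentration unit of `u`: `"ppm"` or `"fraction"`.
#' @return A [resp_ts()] of V_dot_CO2 in uL/min.
#' @examples
#' v <- vco2_from_u(resp_ts(rep(100, 5), dt = 0.1), 500, "ppm")
#' v$values[1]  # 50 uL/min
#' @export
vco2_from_u <- function(u, flow_ml_min, unit = c("ppm", "fraction")) {
  stopifnot(inherits(u, "resp_ts"), flow_ml_min > 0)
  unit <- match.arg(unit)
  to_fraction <- switch(unit, ppm = 1e-6, fraction = 1)
  # fraction * mL/min = mL/min; * 1e3 -> uL/min
  resp_ts(u$values * to_fraction * flow_ml_min * 1e3,
          dt = u$dt, t0 = u$t0)
}

#' Spiracle-opening threshold from a hyperoxic recording
#'
#' Under hyperoxia the spiracles stay closed for long stretches, so the
#' quietest part of the hyperoxic V_dot_CO2 trace estimates the
#' closed-spiracle release floor. The threshold is the mean of the
#' contiguous window of length `window_s` with the lowest mean,
#' multiplied by `factor`.
#'
#' @param vco2_hyperoxic V_dot_CO2 under hyperoxia as a [resp_ts()]
#'   (uL/min), at least `window_s` long.
#' @param window_s window length in seconds (default 120, a two-minute
#'   trial).
#' @param factor multiplier on the window mean (default 4).
#' @return Threshold in uL/min. Ties between equal-mean windows resolve
#'   to the earliest.
#' @export
hyperoxia_threshold <- function(vco2_hyperoxic, window_s = 120,
                                factor = 4) {
  stopifnot(inherits(vco2_hyperoxic, "resp_ts"), window_s > 0, factor > 0)
  v <- vco2_hyperoxic$values
  wn <- max(1L, round(window_s / vco2_hyperoxic$dt))
  if (wn > length(v)) {
    stop(sprintf("trace (%d samples) shorter than the %g s window",
                 length(v), window_s), call. = FALSE)
  }
  cs <- cumsum(c(0, v))
  means <- (cs[(wn + 1L):(length(v) + 1L)] - cs[1:(length(v) - wn + 1L)]) / wn
  factor * means[which.min(means)]
}

#' Classify open and closed spiracle phases
#'
#' A sample is "open" when V_dot_CO2 is strictly above the threshold
#' (values equal to the threshold count as closed).
#'
#' @param vco2 V_dot_CO2 as a [resp_ts()] (uL/min).
#' @param threshold cutoff in uL/min (>= 0).
#' @return An object of class `phase_result`: `threshold`, `open_mask`
#'   (logical vector on the V_dot_CO2 grid), `open_percent` (0..100).
#' @export
classify_phases <- function(vco2, threshold) {
  stopifnot(inherits(vco2, "resp_ts"), threshold >= 0)
  mask <- vco2$values > threshold
  structure(list(threshold = threshold, open_mask = mask,
                 open_percent = 100 * mean(mask),
                 dt = vco2$dt, t0 = vco2$t0),
            class = "phase_result")
}

#' @export
print.phase_result <- function(x, ...) {
  cat(sprintf(
    "<phase_result> threshold = %g uL/min; spiracles open %.1f%% of %d samples\n",
    x$threshold, x$open_percent, length(x$open_mask)))
  invisible(x)
}
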