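#' Respirometry chamber configuration
#'
#' Physical parameters of the well-mixed chamber model. Flow rates are
#' accepted in mL/min (the usual respirometry convention) and converted to
#' mL/s internally, so all derived rates are in 1/s.
#'
#' @param volume_ml chamber volume V in mL (> 0).
#' @param flow_ml_min flow rate F in mL/min (> 0).
#' @param sample_dt_s sampling period T in seconds (> 0).
#' @return An object of class `chamber_config` with the derived washout
#'   rate `rate_per_s = F/V` in 1/s and the time constant `tau_s = V/F`
#'   in seconds.
#' @examples
#' chamber_config(28, 250, 0.1)$tau_s  # 6.72 s
#' @export
chamber_config <- function(volume_ml, flow_ml_min, sample_dt_s) {
  stopifnot(is.numeric(volume_ml), volume_ml > 0,
            is.numeric(flow_ml_min), flow_ml_min > 0,
            is.numeric(sample_dt_s), sample_dt_s > 0)
  flow_ml_s <- flow_ml_min / 60
  structure(list(volume_ml = volume_ml, flow_ml_min = flow_ml_min,
                 sample_dt_s = sample_dt_s,
                 rate_per_s = flow_ml_s / volume_ml,
                 tau_s = volume_ml / flow_ml_s),
            class = "chamber_config")
}

#' @export
print.chamber_config <- function(x, ...) {
  cat(sprintf(
    "<chamber_config> V = %g mL, F = %g mL/min, T = %g s (tau = %g s)\n",
    x$volume_ml, x$flow_ml_min, x$sample_dt_s, x$tau_s))
  invisible(x)
}

#' Rectangular pulse-train specification
#'
#' Describes the benchmark input: a train of rectangular gas pulses, as
#' produced by switching the inlet between scrubbed air and a CO2 source.
#'
#' @param amplitude input level during a pulse (same unit as the recorded
#'   concentration, e.g. ppm).
#' @param pulse_duration_s duration of each pulse in seconds.
#' @param period_s time between pulse onsets (1/frequency), >=
#'   `pulse_duration_s`.
#' @param n_pulses number of pulses (>= 1).
#' @param pre_pad_s,post_pad_s zero-signal margins before the first pulse
#'   and after the last pulse ends, in seconds.
#' @return An object of class `pulse_train_spec`.
#' @export
pulse_train_spec <- function(amplitude, pulse_duration_s, period_s,
                             n_pulses = 3L, pre_pad_s = 0, post_pad_s = 0) {
  stopifnot(amplitude >= 0, pulse_duration_s > 0,
            period_s >= pulse_duration_s, n_pulses >= 1,
            pre_pad_s >= 0, post_pad_s >= 0)
  structure(list(amplitude = amplitude, pulse_duration_s = pulse_duration_s,
                 period_s = period_s, n_pulses = as.integer(n_pulses),
                 pre_pad_s = pre_pad_s, post_pad_s = post_pad_s),
            class = "pulse_train_spec")
}

#' Generate a rectangular pulse train
#'
#' @param spec a [pulse_train_spec()].
#' @param dt sampling period in seconds. Pulse duration and period should
#'   be whole multiples of `dt`; otherwise they are rounded to whole
#'   samples with a warning.
#' @return A [resp_ts()] with value `amplitude` during pulses, 0 elsewhere.
#' @examples
#' u <- generate_pulse_train(
#'   pulse_train_spec(100, 0.2, 2, n_pulses = 3), dt = 0.1)
#' sum(u$values) * u$dt  # total area 60
#' @export
generate_pulse_train <- function(spec, dt) {
  stopifnot(inherits(spec, "pulse_train_spec"), dt > 0)
  n_on <- spec$pulse_duration_s / dt
  n_per <- spec$period_s / dt
  if (abs(n_on - round(n_on)) > 1e-9 || abs(n_per - round(n_per)) > 1e-9) {
    warning("pulse duration/period are not whole multiples of dt; ",
            "rounding to whole samples", call. = FALSE)
  }
  n_on <- max(1L, round(n_on))
  n_per <- max(n_on, round(n_per))
  n_pre <- round(spec$pre_pad_s / dt)
  n_post <- round(spec$post_pad_s / dt)
  core <- rep(0, (spec$n_pulses - 1L) * n_per + n_on)
  for (p in seq_len(spec$n_pulses)) {
    i0 <- (p - 1L) * n_per
    core[i0 + seq_len(n_on)] <- spec$amplitude
  }
  resp_ts(c(rep(0, n_pre), core, rep(0, n_post)), dt = dt, t0 = 0)
}

#' Simulate a perfectly mixed chamber (first-order ODE)
#'
#' Integrates the mass-balance ODE `c' = (F/V)(u - c)` with the exact
#' exponential-integrator update for piecewise-constant input:
#' `c[k+1] = u[k] + (c[k] - u[k]) * exp(-(F/V) T)`. The update is exact at
#' the grid points whenever the input is constant over each sampling
#' interval, independent of `T`.
#'
#' @param u input signal as a [resp_ts()] (held constant over each step).
#' @param chamber a [chamber_config()].
#' @param c0 initial chamber concentration (default 0).
#' @return A [resp_ts()] with the outlet concentration on the same grid.
#' @export
simulate_well_mixed <- function(u, chamber, c0 = 0) {
  stopifnot(inherits(u, "resp_ts"), inherits(chamber, "chamber_config"))
  r <- exp(-chamber$rate_per_s * u$dt)
  n <- length(u$values)
  if (n == 1L) return(resp_ts(c0, dt = u$dt, t0 = u$t0))
  drive <- (1 - r) * u$values[-n]
  cc <- stats::filter(drive, r, method = "recursive", init = c0)
  resp_ts(c(c0, as.numeric(cc)), dt = u$dt, t0 = u$t0)
}

#' Simulate an LTI chamber by convolution with an impulse response
#'
#' Discretizes the convolution `c(t) = integral of u(tau) h(t - tau)` by
#' sampling the delay-free part of the impulse response pointwise on the
#' grid, convolving with the input scaled by `dt`, and shifting the result
#' by the pure delay rounded to whole samples. The kernel is truncated
#' where its density falls below 1e-6 of its peak. Pointwise sampling makes
#' the response to a discrete unit impulse exactly `ir_evaluate()` on the
#' grid; for kernels with `m >= 1` it also conserves signal area to
#' O((beta dt)^2) (for `m = 0` kernels, whose density steps at the origin,
#' the area error is O(beta dt) and shrinks under grid refinement).
#'
#' @param u input signal as a [resp_ts()].
#' @param ir a [gamma_ir()].
#' @return A [resp_ts()] starting at `u$t0`, covering the input span plus
#'   the delay and the washout tail.
#' @export
simulate_convolution <- function(u, ir) {
  stopifnot(inherits(u, "resp_ts"), inherits(ir, "gamma_ir"))
  dt <- u$dt
  t_cut <- ir_support_length(ir)
  kern <- ir_evaluate(gamma_ir(ir$m, ir$beta, 0), seq(0, t_cut, by = dt))
  nd_raw <- ir$delay / dt
  nd <- round(nd_raw)
  if (abs(nd_raw - nd) > 1e-6) {
    warning(sprintf(
      "delay %g s is not a whole number of samples at dt = %g s; %s",
      ir$delay, dt, "rounding to the nearest sample"), call. = FALSE)
  }
  cc <- dt * stats::convolve(u$values, rev(kern), type = "open")
  resp_ts(c(rep(0, nd), cc), dt = dt, t0 = u$t0)
}

#' Additive Gaussian sensor noise
#'
#' @param series a [resp_ts()].
#' @param sigma noise standard deviation (same unit as the values; >= 0).
#' @param seed integer seed; the perturbation is deterministic given the
#'   seed and does not disturb the caller's RNG state.
#' @return A [resp_ts()] with i.i.d. N(0, sigma^2) noise added.
#' @export
add_noise <- function(series, sigma, seed) {
  stopifnot(inherits(series, "resp_ts"), sigma >= 0)
  if (sigma == 0) return(series)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  resp_ts(series$values + stats::rnorm(length(series$values), 0, sigma),
          dt = series$dt, t0 = series$t0)
}
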