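#' Parameters of the Z-transform recovery
#'
#' The classic correction for a perfectly mixed chamber is governed by a
#' single constant, expressed either as the dimensionless `Z` (discrete
#' form) or as the time constant `tau = V/F` in seconds (continuous form).
#' The two are linked by `Z = 1 - exp(-T / tau)` at sampling period `T`.
#' Exactly one of `tau_s` or `z` must be given; the other is derived.
#'
#' @param tau_s time constant V/F in seconds.
#' @param z dimensionless Z in (0, 1).
#' @param dt sampling period in seconds (needed to convert between forms).
#' @return An object of class `zt_params` with fields `z`, `tau_s`, `dt`.
#' @seealso [compute_z()] for the analytic value from chamber geometry;
#'   tuned values (fit to a calibration recording) typically differ from
#'   the analytic ones and can be supplied here directly.
#' @export
zt_params <- function(tau_s = NULL, z = NULL, dt) {
  stopifnot(is.numeric(dt), dt > 0)
  if (is.null(tau_s) == is.null(z)) {
    stop("supply exactly one of 'tau_s' or 'z'", call. = FALSE)
  }
  if (is.null(z)) {
    stopifnot(tau_s > 0)
    z <- 1 - exp(-dt / tau_s)
  } else {
    stopifnot(z > 0, z < 1)
    tau_s <- -dt / log(1 - z)
  }
  structure(list(z = z, tau_s = tau_s, dt = dt), class = "zt_params")
}

#' @export
print.zt_params <- function(x, ...) {
  cat(sprintf("<zt_params> Z = %g, tau = %g s at dt = %g s\n",
              x$z, x$tau_s, x$dt))
  invisible(x)
}

#' Analytic Z-transform parameters from chamber geometry
#'
#' `Z = 1 - exp(-(F/V) T)` with the flow rate converted to mL/s, and
#' `tau = V/F` in seconds.
#'
#' @param chamber a [chamber_config()].
#' @return A [zt_params()] object.
#' @examples
#' compute_z(chamber_config(28, 250, 0.1))$tau_s  # 6.72
#' @export
compute_z <- function(chamber) {
  stopifnot(inherits(chamber, "chamber_config"))
  zt_params(tau_s = chamber$tau_s, dt = chamber$sample_dt_s)
}

#' Discrete Z-transform recovery
#'
#' Inverts the perfectly mixed chamber sample-by-sample:
#' `u(k) = c(k+1)/Z - (1-Z) c(k)/Z`. This is the exact algebraic inverse
#' of the exponential-integrator chamber update, so on data simulated from
#' the well-mixed model with zero initial concentration it reproduces a
#' piecewise-constant input exactly.
#'
#' @param c_series recorded concentration as a [resp_ts()] (>= 2 samples).
#' @param params a [zt_params()].
#' @return A [resp_ts()] one sample shorter than the input (the last
#'   sample has no successor); `u(k)` is timestamped at sample `k`.
#' @export
recover_zt_discrete <- function(c_series, params) {
  stopifnot(inherits(c_series, "resp_ts"), inherits(params, "zt_params"))
  v <- c_series$values
  n <- length(v)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  z <- params$z
  u <- (v[-1L] - (1 - z) * v[-n]) / z
  resp_ts(u, dt = c_series$dt, t0 = c_series$t0)
}

#' Continuous-form Z-transform recovery
#'
#' `u(t) = c(t) + tau * dc/dt`, with the derivative taken by the shared
#' smoothed finite-difference operator. This is the `m = 0` special case
#' of the derivative-based recovery ([recover_ezt()]) and shares its code
#' path, including delay removal and optional noise handling; use it when
#' an experimentally tuned time constant is available instead of `V/F`.
#'
#' @param c_series recorded concentration as a [resp_ts()] (>= 3 samples).
#' @param params a [zt_params()].
#' @param settings a [recovery_settings()].
#' @param delay_s pure delay removed (shift earlier, rounded to whole
#'   samples) before recovery; default 0.
#' @return The recovered input as a [resp_ts()].
#' @export
recover_zt_continuous <- function(c_series, params,
                                  settings = recovery_settings(),
                                  delay_s = 0) {
  stopifnot(inherits(params, "zt_params"))
  ir <- gamma_ir(m = 0, beta = 1 / params$tau_s, delay = delay_s)
  recover_ezt(c_series, ir, settings)
}
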