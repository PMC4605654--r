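#' Derivative weights of the extended recovery
#'
#' For a chamber whose impulse response is the gamma-shaped model with
#' integer shape `m`, the input is an exact linear combination of the
#' recorded trace and its first `m + 1` derivatives,
#' `u(t) = sum_k a_k c^(k)(t)`, with binomial weights
#' \deqn{a_k = \binom{m+1}{k} / \beta^k, \quad k = 0, \dots, m+1.}
#' `a_0` is always 1, and `m = 0` gives `(1, 1/beta)`: the continuous
#' Z-transform form.
#'
#' @param m integer shape parameter (>= 0).
#' @param beta decay rate in 1/s (> 0).
#' @return An object of class `ezt_coefficients`: list with `a` (length
#'   `m + 2`, units s^k for `a[k+1]`), `m`, `beta`.
#' @examples
#' compute_ezt_coefficients(1, 0.249)$a  # c(1, 8.03, 16.13) to 2 dp
#' @export
compute_ezt_coefficients <- function(m, beta) {
  if (!is.numeric(m) || length(m) != 1L || abs(m - round(m)) > 1e-9 ||
      m < 0) {
    stop("'m' must be a non-negative integer; for non-integer shapes, ",
         "refit the impulse response with mode 'integer_m' or 'reduced_m'",
         call. = FALSE)
  }
  stopifnot(is.numeric(beta), beta > 0)
  m <- as.integer(round(m))
  k <- 0:(m + 1L)
  structure(list(a = choose(m + 1L, k) / beta^k, m = m, beta = beta),
            class = "ezt_coefficients")
}

#' @export
print.ezt_coefficients <- function(x, ...) {
  cat(sprintf("<ezt_coefficients> m = %d, beta = %g 1/s\n", x$m, x$beta))
  cat("  a:", paste(signif(x$a, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Settings shared by the derivative-based recoveries
#'
#' @param smooth_span moving-average window (samples) applied to the raw
#'   trace before recovery and, when `post_derivative_smooth` is on, after
#'   each differentiation (default 10; even spans are reduced to odd).
#' @param pre_smooth smooth the recorded trace before differentiating
#'   (default TRUE).
#' @param post_derivative_smooth smooth after each derivative
#'   (default TRUE).
#' @param weak_signal_span moving-average span for sub-threshold regions
#'   in the adaptive filter (default 50).
#' @param noise_threshold_factor multiplier on the recovered-noise RMS
#'   defining the weak-signal threshold (default 2).
#' @param quiet_idx optional integer vector of sample indices (in the
#'   recovery output) known to contain no signal; when supplied (>= 50
#'   indices) the noise floor is estimated there and the adaptive
#'   weak-signal filter is applied. NULL disables adaptive filtering.
#' @return An object of class `recovery_settings`.
#' @export
recovery_settings <- function(smooth_span = 10, pre_smooth = TRUE,
                              post_derivative_smooth = TRUE,
                              weak_signal_span = 50,
                              noise_threshold_factor = 2,
                              quiet_idx = NULL) {
  stopifnot(smooth_span >= 1, weak_signal_span >= 1,
            noise_threshold_factor >= 0)
  structure(list(smooth_span = as.integer(smooth_span),
                 pre_smooth = isTRUE(pre_smooth),
                 post_derivative_smooth = isTRUE(post_derivative_smooth),
                 weak_signal_span = as.integer(weak_signal_span),
                 noise_threshold_factor = noise_threshold_factor,
                 quiet_idx = quiet_idx),
            class = "recovery_settings")
}

#' Noise-robust numerical derivative
#'
#' Central finite difference (one-sided at the ends) divided by the
#' sampling period, optionally followed by a centered moving average —
#' differentiate first, then smooth, once per derivative order.
#'
#' @param series a [resp_ts()] (>= 3 samples).
#' @param settings a [recovery_settings()]; `smooth_span` and
#'   `post_derivative_smooth` control the smoothing step.
#' @return A [resp_ts()] of the same length.
#' @export
smoothed_derivative <- function(series, settings = recovery_settings()) {
  stopifnot(inherits(series, "resp_ts"))
  v <- series$values
  n <- length(v)
  if (n < 3L) stop("need at least 3 samples to differentiate", call. = FALSE)
  dt <- series$dt
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  out <- resp_ts(d, dt = dt, t0 = series$t0)
  if (isTRUE(settings$post_derivative_smooth) && settings$smooth_span > 1) {
    out <- suppressMessages(moving_average(out, settings$smooth_span))
  }
  out
}

#' Extended Z-transform recovery (derivative form)
#'
#' Recovers the input from a recorded trace using the gamma impulse-
#' response model with integer shape `m`: the trace is shifted earlier by
#' the pure delay (rounded to whole samples), optionally pre-smoothed,
#' differentiated `m + 1` times with smoothing after each derivative, and
#' combined with the binomial weights of [compute_ezt_coefficients()].
#' When `settings$quiet_idx` designates a baseline-only region, the
#' noise floor is estimated there and the adaptive weak-signal filter is
#' applied to the result.
#'
#' @param c_series recorded concentration as a [resp_ts()].
#' @param ir a [gamma_ir()] with integer `m` (fit with mode `integer_m` or
#'   `reduced_m` for non-integer shapes).
#' @param settings a [recovery_settings()].
#' @return The recovered input as a [resp_ts()]; after delay removal,
#'   sample `k` of the output estimates the input at time `t0 + k dt`.
#' @export
recover_ezt <- function(c_series, ir, settings = recovery_settings()) {
  stopifnot(inherits(c_series, "resp_ts"), inherits(ir, "gamma_ir"),
            inherits(settings, "recovery_settings"))
  coefs <- compute_ezt_coefficients(ir$m, ir$beta)
  m <- coefs$m
  dt <- c_series$dt
  v <- c_series$values
  nd_raw <- ir$delay / dt
  nd <- round(nd_raw)
  if (abs(nd_raw - nd) > 1e-6) {
    warning("delay is not a whole number of samples; rounding",
            call. = FALSE)
  }
  if (nd > 0) {
    if (nd >= length(v)) stop("delay exceeds the record length",
                              call. = FALSE)
    v <- v[-seq_len(nd)]
  }
  if (m + 2L >= length(v) / 4) {
    stop("record too short for ", m + 1L, " derivatives", call. = FALSE)
  }
  x <- resp_ts(v, dt = dt, t0 = c_series$t0)
  if (isTRUE(settings$pre_smooth) && settings$smooth_span > 1) {
    x <- suppressMessages(moving_average(x, settings$smooth_span))
  }
  acc <- coefs$a[1] * x$values
  cur <- x
  for (k in seq_len(m + 1L)) {
    cur <- smoothed_derivative(cur, settings)
    acc <- acc + coefs$a[k + 1L] * cur$values
  }
  u <- resp_ts(acc, dt = dt, t0 = c_series$t0)
  qi <- settings$quiet_idx
  if (!is.null(qi)) {
    qi <- qi[qi >= 1 & qi <= length(u$values)]
    floor_est <- estimate_noise_floor(
      resp_ts(u$values[qi], dt = dt),
      factor = settings$noise_threshold_factor)
    u <- adaptive_filter(u, floor_est, settings$weak_signal_span)
  }
  u
}
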