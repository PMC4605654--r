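#' Calibrate the generalized (FIR inverse filter) recovery
#'
#' The generalized method estimates the input at each sample as a linear
#' combination of the next `N + 1` recorded output samples,
#' `u(k) = sum_{j=0}^{N} a_j c(k+j)`. The coefficients are calibration
#' constants of the whole measurement chain and are found from one
#' recording of a known injected input: each row of the design matrix `C`
#' is a window `(c(j), ..., c(j+N))` and the least-squares problem
#' `C a ~ u` is solved. An SVD-based solve is used (mathematically the
#' normal-equations solution `(C'C)^{-1} C'u`, but stable for the nearly
#' collinear rows a washout trace produces); rank deficiency falls back to
#' the pseudo-inverse with a condition-number warning.
#'
#' @param u_known the known injected input as a [resp_ts()].
#' @param c_recorded the recorded output, same `dt` and start time,
#'   at least as long as `u_known` (ideally longer by the washout tail).
#' @param n_taps filter order N; must satisfy
#'   `n_taps <= length(c_recorded) - length(u_known)` is not required, but
#'   only the first `length(c_recorded) - n_taps` input samples can be
#'   used as regression targets.
#' @return An object of class `gzt_calibration`: `a` (length N+1),
#'   `n_taps`, `dt`, `training_itae` (normalized ITAE on the calibration
#'   pair).
#' @export
calibrate_gzt <- function(u_known, c_recorded, n_taps) {
  stopifnot(inherits(u_known, "resp_ts"), inherits(c_recorded, "resp_ts"),
            n_taps >= 0)
  n_taps <- as.integer(n_taps)
  if (abs(u_known$dt - c_recorded$dt) > 1e-9 * u_known$dt) {
    stop("input and output sampling periods differ", call. = FALSE)
  }
  if (abs(u_known$t0 - c_recorded$t0) > 1e-9) {
    stop("input and output must be time-aligned (same t0)", call. = FALSE)
  }
  cv <- c_recorded$values
  if (length(cv) <= n_taps) {
    stop("recorded trace shorter than the filter order", call. = FALSE)
  }
  n_rows <- min(length(u_known$values), length(cv) - n_taps)
  if (n_rows < n_taps + 1L) {
    warning("fewer calibration rows (", n_rows, ") than coefficients (",
            n_taps + 1L, "); system is underdetermined", call. = FALSE)
  }
  C <- gzt_design_matrix(cv, n_taps, n_rows)
  u <- u_known$values[seq_len(n_rows)]
  sv <- svd(C)
  tol <- max(dim(C)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  if (!all(pos)) {
    warning(sprintf(
      "design matrix is rank deficient (rank %d of %d, condition ~ %.3g); %s",
      sum(pos), length(sv$d), sv$d[1] / min(sv$d[sv$d > 0]),
      "using the pseudo-inverse"), call. = FALSE)
  }
  a <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], u)) / sv$d[pos])
  a <- as.numeric(a)
  uhat <- as.numeric(C %*% a)
  est <- resp_ts(uhat, dt = u_known$dt, t0 = u_known$t0)
  tru <- resp_ts(u, dt = u_known$dt, t0 = u_known$t0)
  # absolute ITAE if the calibration input has no net area to normalize by
  tr_itae <- tryCatch(normalized_itae(est, tru),
                      error = function(e) itae(est, tru))
  structure(list(a = a, n_taps = n_taps, dt = u_known$dt,
                 training_itae = tr_itae),
            class = "gzt_calibration")
}

# Rows j = 0..n_rows-1: (c(j), ..., c(j+N)); built from embed(), whose rows
# come out time-reversed.
gzt_design_matrix <- function(cv, n_taps, n_rows) {
  E <- stats::embed(cv, n_taps + 1L)
  E <- E[, ncol(E):1L, drop = FALSE]
  E[seq_len(n_rows), , drop = FALSE]
}

#' @export
print.gzt_calibration <- function(x, ...) {
  cat(sprintf(
    "<gzt_calibration> N = %d taps at dt = %g s; training ITAE = %.4f\n",
    x$n_taps, x$dt, x$training_itae))
  invisible(x)
}

#' Choose the filter order N by split validation
#'
#' For each candidate N, calibrates on the first half of the pair and
#' scores the normalized ITAE of the recovery on the second half, then
#' returns the N with the smallest validation error (ties broken toward
#' the smaller N). Scoring on held-out data, rather than on the
#' calibration stretch itself, penalizes overfitting of large filters.
#'
#' The calibration pair should contain signal activity in both halves; if
#' the held-out half has zero signal area the score falls back to the
#' absolute (unnormalized) ITAE, which then measures pure recovered noise.
#'
#' @param u_known,c_recorded calibration pair as for [calibrate_gzt()].
#' @param n_grid integer vector of candidate N values.
#' @return List with `best_n` and `table` (data.frame of N, training and
#'   validation ITAE).
#' @export
select_n <- function(u_known, c_recorded, n_grid) {
  if (length(n_grid) == 0L) stop("empty N grid", call. = FALSE)
  n_grid <- sort(unique(as.integer(n_grid)))
  half <- length(u_known$values) %/% 2L
  t_split <- u_known$t0 + half * u_known$dt
  u1 <- resp_ts(u_known$values[seq_len(half)], dt = u_known$dt,
                t0 = u_known$t0)
  c1 <- resp_ts(c_recorded$values[seq_len(half)], dt = c_recorded$dt,
                t0 = c_recorded$t0)
  u2 <- resp_ts(u_known$values[-seq_len(half)], dt = u_known$dt,
                t0 = t_split)
  c2 <- resp_ts(c_recorded$values[-seq_len(half)], dt = c_recorded$dt,
                t0 = t_split)
  rows <- lapply(n_grid, function(N) {
    cal <- tryCatch(suppressWarnings(calibrate_gzt(u1, c1, N)),
                    error = function(e) NULL)
    if (is.null(cal)) {
      return(data.frame(n_taps = N, training_itae = NA_real_,
                        validation_itae = NA_real_))
    }
    est <- recover_gzt(c2, cal)
    # plain ITAE if the held-out half happens to contain no signal
    score <- tryCatch(normalized_itae(est, u2),
                      error = function(e) itae(est, u2))
    data.frame(n_taps = N, training_itae = cal$training_itae,
               validation_itae = score)
  })
  tab <- do.call(rbind, rows)
  ok <- which(is.finite(tab$validation_itae))
  if (length(ok) == 0L) stop("no candidate N could be calibrated",
                             call. = FALSE)
  # strict improvement keeps the smallest N on ties
  best <- ok[1]
  for (i in ok[-1]) {
    if (tab$validation_itae[i] < tab$validation_itae[best] - 1e-12) best <- i
  }
  list(best_n = tab$n_taps[best], table = tab)
}

#' Apply a calibrated FIR recovery
#'
#' `u(k) = sum_{j=0}^{N} a_j c(k+j)`: a linear, time-invariant filter on
#' future output samples. The output is `N` samples shorter than the
#' input, because the last samples lack the future data the filter needs.
#'
#' @param c_series recorded concentration as a [resp_ts()]; its `dt` must
#'   match the calibration's (coefficients are specific to the sampling
#'   period).
#' @param calib a [calibrate_gzt()] result.
#' @return The recovered input as a [resp_ts()] starting at `c_series$t0`.
#' @export
recover_gzt <- function(c_series, calib) {
  stopifnot(inherits(c_series, "resp_ts"), inherits(calib, "gzt_calibration"))
  if (abs(c_series$dt - calib$dt) > 1e-9 * calib$dt) {
    stop(sprintf(
      "sampling period %g s does not match calibration dt %g s",
      c_series$dt, calib$dt), call. = FALSE)
  }
  N <- calib$n_taps
  if (length(c_series$values) <= N) {
    stop("trace shorter than the filter order", call. = FALSE)
  }
  E <- stats::embed(c_series$values, N + 1L)
  u <- as.numeric(E %*% rev(calib$a))
  resp_ts(u, dt = c_series$dt, t0 = c_series$t0)
}
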