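#' Uniformly sampled time series
#'
#' The universal carrier for recorded concentration traces `c(t)`, known or
#' recovered input signals `u(t)`, and derived rate signals. Only the start
#' time and the sampling period are stored, so the grid is uniform by
#' construction; non-uniform data must be rejected at read time.
#'
#' @param values numeric vector of samples (concentration as a dimensionless
#'   fraction or ppm, or a rate for recovered signals). Length >= 1, finite.
#' @param dt sampling period T in seconds (> 0).
#' @param t0 time of the first sample in seconds (default 0).
#' @return An object of class `resp_ts`: a list with elements `t0`, `dt`,
#'   `values`.
#' @examples
#' x <- resp_ts(c(0, 1, 0), dt = 0.1)
#' ts_times(x)
#' @export
resp_ts <- function(values, dt, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("'values' must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("'values' must be finite", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("'dt' must be a single positive number (seconds)", call. = FALSE)
  }
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0)) {
    stop("'t0' must be a single finite number (seconds)", call. = FALSE)
  }
  structure(list(t0 = as.numeric(t0), dt = as.numeric(dt), values = values),
            class = "resp_ts")
}

#' Sample times of a time series
#'
#' @param x a [resp_ts()] object.
#' @return Numeric vector `t0 + (0:(n-1)) * dt` in seconds.
#' @export
ts_times <- function(x) {
  stopifnot(inherits(x, "resp_ts"))
  x$t0 + (seq_along(x$values) - 1) * x$dt
}

#' @export
length.resp_ts <- function(x) length(x$values)

#' @export
print.resp_ts <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<resp_ts> %d samples, dt = %g s, span [%g, %g] s\n",
              n, x$dt, x$t0, x$t0 + (n - 1) * x$dt))
  cat(sprintf("  values: min %.4g, max %.4g\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.resp_ts <- function(x, ...) {
  data.frame(time = ts_times(x), value = x$values)
}

#' Extract a time window from a series
#'
#' @param x a [resp_ts()] object.
#' @param from,to window limits in seconds (inclusive).
#' @return A `resp_ts` covering the samples whose times fall in `[from, to]`.
#' @export
ts_window <- function(x, from = -Inf, to = Inf) {
  stopifnot(inherits(x, "resp_ts"))
  tt <- ts_times(x)
  keep <- tt >= from - 1e-12 & tt <= to + 1e-12
  if (!any(keep)) stop("window contains no samples", call. = FALSE)
  resp_ts(x$values[keep], dt = x$dt, t0 = tt[which(keep)[1]])
}

#' Read a uniformly sampled time series from CSV
#'
#' Reads a two-column CSV (header required) and checks that the time stamps
#' form a strictly uniform grid: the sampling period is taken as the median
#' increment and any increment deviating from it by more than `rel_tol`
#' (relative) is an error, because the container cannot represent
#' non-uniform sampling.
#'
#' @param path path to a CSV file.
#' @param time_col,value_col column names holding time (seconds) and value.
#' @param rel_tol maximum relative deviation of any time increment from the
#'   median increment (default `1e-6`).
#' @return A [resp_ts()].
#' @export
read_timeseries <- function(path, time_col = "time", value_col = "value",
                            rel_tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  for (col in c(time_col, value_col)) {
    if (!col %in% names(df)) {
      stop(sprintf("column '%s' not found; available columns: %s",
                   col, paste(names(df), collapse = ", ")), call. = FALSE)
    }
  }
  tt <- as.numeric(df[[time_col]])
  vv <- as.numeric(df[[value_col]])
  if (length(tt) < 2L) {
    stop("need at least 2 rows to establish a sampling period", call. = FALSE)
  }
  inc <- diff(tt)
  if (any(inc <= 0)) {
    k <- which(inc <= 0)[1]
    stop(sprintf("time column is not strictly increasing at row %d", k + 1L),
         call. = FALSE)
  }
  dt <- stats::median(inc)
  bad <- abs(inc - dt) > rel_tol * dt
  if (any(bad)) {
    k <- which(bad)[1]
    stop(sprintf(paste0("non-uniform sampling: increment %g at row %d ",
                        "deviates from median period %g"),
                 inc[k], k + 1L, dt), call. = FALSE)
  }
  resp_ts(vv, dt = dt, t0 = tt[1])
}

#' Write a time series to CSV
#'
#' Writes a `time,value` CSV at full precision, so that
#' `read_timeseries(write_timeseries(x))` reproduces `x` (exactly for
#' decimal-representable values, to within 1 ulp otherwise).
#'
#' @param x a [resp_ts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  stopifnot(inherits(x, "resp_ts"))
  df <- as.data.frame(x)
  # format() would truncate; write full double precision explicitly
  lines <- c("time,value",
             paste(sprintf("%.17g", df$time), sprintf("%.17g", df$value),
                   sep = ","))
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write to ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}
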