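#' Integral of time-wise absolute error (ITAE)
#'
#' Trapezoidal integral of `|estimate - truth|` over the common time
#' support. Both series must share the sampling period and be on the same
#' sample grid (offset by a whole number of samples); a recovery output
#' shorter than the truth is scored on its own support.
#'
#' @param estimate,truth [resp_ts()] objects with equal `dt`.
#' @return ITAE in value-units times seconds (>= 0).
#' @export
itae <- function(estimate, truth) {
  al <- align_pair(estimate, truth)
  pracma::trapz(al$times, abs(al$est - al$tru))
}

#' Normalized ITAE
#'
#' [itae()] divided by the area of the true signal over the common
#' support, matching error-as-fraction-of-signal reporting: a recovery
#' that misses everything (estimate identically zero) scores exactly 1.
#'
#' @param estimate,truth [resp_ts()] objects with equal `dt`; the truth
#'   must have positive area.
#' @return Dimensionless normalized error (>= 0).
#' @export
normalized_itae <- function(estimate, truth) {
  al <- align_pair(estimate, truth)
  area <- pracma::trapz(al$times, al$tru)
  if (!is.finite(area) || area <= 0) {
    stop("true signal has non-positive area; cannot normalize",
         call. = FALSE)
  }
  pracma::trapz(al$times, abs(al$est - al$tru)) / area
}

align_pair <- function(estimate, truth) {
  stopifnot(inherits(estimate, "resp_ts"), inherits(truth, "resp_ts"))
  dt <- truth$dt
  if (abs(estimate$dt - dt) > 1e-9 * dt) {
    stop("sampling periods differ; resample before comparing",
         call. = FALSE)
  }
  off_raw <- (estimate$t0 - truth$t0) / dt
  off <- round(off_raw)
  if (abs(off_raw - off) > 1e-6) {
    stop("series are not on the same sample grid", call. = FALSE)
  }
  ne <- length(estimate$values); nt <- length(truth$values)
  # overlap in truth indices (1-based)
  lo <- max(1L, 1L + off)
  hi <- min(nt, ne + off)
  if (hi - lo < 1L) stop("no overlapping time support", call. = FALSE)
  ti <- lo:hi
  list(times = truth$t0 + (ti - 1L) * dt,
       est = estimate$values[ti - off],
       tru = truth$values[ti])
}

#' Frequency-sweep comparison of the recovery methods
#'
#' Re-creates the benchmark design used to compare the methods: trains of
#' three rectangular CO2 pulses at each switching frequency (50% duty)
#' are pushed through the chamber model, sensor noise is added, each
#' requested method recovers the input, and the normalized ITAE against
#' the known truth is averaged over seeds.
#'
#' The scenario list understands:
#' \describe{
#'   \item{chamber}{a [chamber_config()] (required).}
#'   \item{ir}{a [gamma_ir()]; NULL means a perfectly mixed chamber,
#'     simulated with the exact ODE integrator.}
#'   \item{noise_sigma}{additive noise SD (same unit as the amplitude).}
#'   \item{amplitude}{pulse height (default 100, as for a 100 ppm
#'     source).}
#'   \item{settings}{a [recovery_settings()] used by the derivative-based
#'     methods.}
#'   \item{gzt_n_taps}{FIR order for the generalized method
#'     (default 230).}
#' }
#'
#' Method details: `zt` uses the exact discrete inverse when the scenario
#' is well mixed, and otherwise the continuous form with the best-fit
#' exponential (shape fixed at 0) to the scenario's impulse response;
#' `ezt` uses the true integer-shape impulse response; `gzt` is calibrated
#' per seed on the standard three 200-ms pulses two seconds apart. When
#' noise is present, all methods share the adaptive weak-signal filter,
#' with the noise floor estimated on the pre-pulse quiet region.
#'
#' @param scenario scenario list (above).
#' @param frequencies switching frequencies in Hz (default the benchmark
#'   grid `c(0.1, 0.167, 0.25, 0.5, 1)`).
#' @param methods subset of `c("zt", "ezt", "gzt")`.
#' @param seeds integer vector of noise seeds (one replicate each).
#' @return An object of class `method_comparison`: `table` (data.frame of
#'   method, frequency_hz, mean normalized ITAE), `replicates` (array
#'   method x frequency x seed), and the scenario.
#' @export
run_frequency_sweep <- function(scenario,
                                frequencies = c(0.1, 0.167, 0.25, 0.5, 1),
                                methods = c("zt", "ezt", "gzt"),
                                seeds = 1:5) {
  stopifnot(inherits(scenario$chamber, "chamber_config"))
  methods <- match.arg(methods, several.ok = TRUE)
  chamber <- scenario$chamber
  ir <- scenario$ir
  dt <- chamber$sample_dt_s
  sigma <- if (is.null(scenario$noise_sigma)) 0 else scenario$noise_sigma
  amp <- if (is.null(scenario$amplitude)) 100 else scenario$amplitude
  settings <- if (is.null(scenario$settings)) recovery_settings()
              else scenario$settings
  n_taps <- if (is.null(scenario$gzt_n_taps)) 230L else scenario$gzt_n_taps

  well_mixed <- is.null(ir)
  tail_s <- if (well_mixed) 40 * chamber$tau_s
            else ir$delay + ir_support_length(ir)
  pre_pad_s <- max(20, settings$smooth_span * dt * 4)

  simulate <- function(u) {
    if (well_mixed) simulate_well_mixed(u, chamber, c0 = 0)
    else simulate_convolution(u, ir)
  }

  # exponential-decay fit to the scenario IR, for the zt method on
  # non-well-mixed scenarios (done once; it is deterministic)
  zt_fit <- NULL
  if (!well_mixed && "zt" %in% methods) {
    grid <- seq(0, ir$delay + ir_support_length(ir), by = dt)
    h <- resp_ts(ir_evaluate(ir, grid), dt = dt)
    h <- normalize_measured_response(h)
    zt_fit <- fit_impulse_response(h, mode = "zt")$model
  }

  quiet_idx_for <- function(n_out) {
    n_quiet <- floor(pre_pad_s / dt)
    lo <- min(2L * settings$smooth_span, n_quiet %/% 2L)
    seq.int(lo + 1L, min(n_quiet, n_out))
  }

  post_filter <- function(u_rec) {
    if (sigma <= 0) return(u_rec)
    qi <- quiet_idx_for(length(u_rec$values))
    fl <- estimate_noise_floor(resp_ts(u_rec$values[qi], dt = dt),
                               factor = settings$noise_threshold_factor)
    adaptive_filter(u_rec, fl, settings$weak_signal_span)
  }

  reps <- array(NA_real_,
                dim = c(length(methods), length(frequencies),
                        length(seeds)),
                dimnames = list(methods, paste0(frequencies, "Hz"),
                                paste0("seed", seeds)))

  for (si in seq_along(seeds)) {
    seed <- seeds[si]
    gzt_cal <- NULL
    if ("gzt" %in% methods) {
      u_cal <- generate_pulse_train(
        pulse_train_spec(amp, pulse_duration_s = 0.2, period_s = 2,
                         n_pulses = 3, pre_pad_s = pre_pad_s,
                         post_pad_s = tail_s), dt)
      c_cal <- add_noise(simulate(u_cal), sigma, seed = seed * 1000L + 1L)
      gzt_cal <- suppressWarnings(calibrate_gzt(u_cal, c_cal, n_taps))
    }
    for (fi in seq_along(frequencies)) {
      f <- frequencies[fi]
      period <- 1 / f
      u <- generate_pulse_train(
        pulse_train_spec(amp, pulse_duration_s = period / 2,
                         period_s = period, n_pulses = 3,
                         pre_pad_s = pre_pad_s, post_pad_s = tail_s), dt)
      cc <- add_noise(simulate(u), sigma,
                      seed = seed * 1000L + 10L + fi)
      for (mi in seq_along(methods)) {
        meth <- methods[mi]
        u_rec <- switch(meth,
          zt = if (well_mixed) {
            recover_zt_discrete(cc, compute_z(chamber))
          } else {
            post_filter(recover_zt_continuous(
              cc, zt_params(tau_s = 1 / zt_fit$beta, dt = dt),
              settings = settings, delay_s = zt_fit$delay))
          },
          ezt = post_filter(recover_ezt(cc, ir_or_wm(ir, chamber),
                                        settings = settings)),
          gzt = post_filter(recover_gzt(cc, gzt_cal)))
        reps[mi, fi, si] <- normalized_itae(u_rec, u)
      }
    }
  }
  means <- apply(reps, c(1, 2), mean)
  tab <- data.frame(
    method = rep(methods, times = length(frequencies)),
    frequency_hz = rep(frequencies, each = length(methods)),
    mean_normalized_itae = as.vector(means))
  structure(list(table = tab, replicates = reps, scenario = scenario,
                 frequencies = frequencies, methods = methods,
                 seeds = seeds),
            class = "method_comparison")
}

ir_or_wm <- function(ir, chamber) {
  if (is.null(ir)) gamma_ir(0, chamber$rate_per_s, 0) else ir
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison> mean normalized ITAE\n")
  wide <- stats::reshape(x$table, idvar = "method",
                         timevar = "frequency_hz", direction = "wide")
  print(wide, row.names = FALSE)
  invisible(x)
}
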