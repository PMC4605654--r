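# Shared fixtures: the 28 mL chamber benchmark system and its gamma
# impulse response (integer shape, 250 and 500 mL/min variants).

std_chamber <- function(flow = 250, dt = 0.1) chamber_config(28, flow, dt)

std_ir_250 <- function(delay = 5.82) gamma_ir(m = 1, beta = 0.249, delay = delay)
std_ir_500 <- function(delay = 4.19) gamma_ir(m = 1, beta = 0.459, delay = delay)

# standard calibration input: three 200 ms pulses of 100 ppm, 2 s apart
std_calibration_input <- function(dt = 0.1, pre_pad_s = 20, post_pad_s = 80) {
  generate_pulse_train(
    pulse_train_spec(100, pulse_duration_s = 0.2, period_s = 2, n_pulses = 3,
                     pre_pad_s = pre_pad_s, post_pad_s = post_pad_s), dt)
}

# sampled, unit-area impulse-response curve for fitting tests
sampled_ir_curve <- function(ir, dt = 0.1, noise_sd = 0, seed = 1) {
  grid <- seq(0, ir$delay + ir_support_length(ir), by = dt)
  x <- resp_ts(ir_evaluate(ir, grid), dt = dt)
  if (noise_sd > 0) x <- add_noise(x, noise_sd * max(x$values), seed)
  normalize_measured_response(x)
}

expect_ts_equal <- function(x, y, tol = 1e-12) {
  expect_s3_class(x, "resp_ts")
  expect_equal(x$dt, y$dt, tolerance = tol)
  expect_equal(x$t0, y$t0, tolerance = tol)
  expect_equal(x$values, y$values, tolerance = tol)
}
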