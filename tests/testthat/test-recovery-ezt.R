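test_that("derivative weights match the benchmark chamber values", {
  # analytic coefficients for the 28 mL chamber's integer-shape responses
  co250 <- compute_ezt_coefficients(1, 0.249)
  expect_equal(round(co250$a[2], 2), 8.03)
  expect_equal(round(co250$a[3], 2), 16.13)
  co500 <- compute_ezt_coefficients(1, 0.459)
  expect_equal(round(co500$a[2], 2), 4.36)
  expect_equal(round(co500$a[3], 2), 4.75)
  # m = 0 collapses to the continuous Z-transform pair (1, 1/beta)
  expect_equal(compute_ezt_coefficients(0, 0.25)$a, c(1, 4))
  expect_error(compute_ezt_coefficients(1.5, 1), "integer")
})

test_that("weights satisfy the binomial identity sum a_k beta^k = 2^(m+1)", {
  for (m in 0:6) {
    beta <- 0.1 + 0.3 * m
    co <- compute_ezt_coefficients(m, beta)
    expect_equal(sum(co$a * beta^seq(0, m + 1)), 2^(m + 1))
    expect_equal(co$a[1], 1)
    expect_equal(length(co$a), m + 2)
  }
})

test_that("smoothed derivative recovers known derivatives", {
  st <- recovery_settings(post_derivative_smooth = FALSE)
  # line: constant slope everywhere
  x <- resp_ts(3 + 2 * seq(0, 10, by = 0.1), dt = 0.1)
  d <- smoothed_derivative(x, st)
  expect_equal(d$values, rep(2, length(d$values)), tolerance = 1e-10)
  # constant: all zeros
  d0 <- smoothed_derivative(resp_ts(rep(4, 50), dt = 0.1), st)
  expect_equal(d0$values, rep(0, 50))
  # sine: derivative is omega*cos within 1% (interior, smoothing on)
  om <- 0.4; dt <- 0.05
  tt <- seq(0, 80, by = dt)
  sm <- recovery_settings(smooth_span = 5)
  ds <- smoothed_derivative(resp_ts(sin(om * tt), dt = dt), sm)
  interior <- 50:(length(tt) - 50)
  expect_lt(max(abs(ds$values[interior] - om * cos(om * tt[interior]))) / om,
            0.01)
})

test_that("noiseless round-trip on the exact model class is accurate", {
  ir <- std_ir_500(delay = 0)
  u <- generate_pulse_train(pulse_train_spec(100, 2, 4, 1, pre_pad_s = 2,
                                             post_pad_s = 60), dt = 0.1)
  cc <- simulate_convolution(u, ir)
  st <- recovery_settings(pre_smooth = FALSE, post_derivative_smooth = FALSE)
  ur <- recover_ezt(cc, ir, st)
  expect_lt(normalized_itae(ur, u), 0.1)
  # silence in, silence out
  u0 <- recover_ezt(resp_ts(rep(0, 200), dt = 0.1), ir, st)
  expect_equal(u0$values, rep(0, 200))
})

test_that("recovery error decays with grid refinement on smooth input", {
  # analytic identity: with exact derivatives the weighted sum returns u;
  # finite differences converge at least first order as dt shrinks
  ir <- gamma_ir(1, 0.459, 0)
  st <- recovery_settings(pre_smooth = FALSE, post_derivative_smooth = FALSE)
  err <- vapply(c(0.1, 0.05, 0.025), function(dt) {
    tt <- seq(0, 40, by = dt)
    u <- resp_ts(100 * exp(-(tt - 12)^2 / 4), dt = dt)
    cc <- simulate_convolution(u, ir)
    ur <- recover_ezt(cc, ir, st)
    n <- length(u$values)
    max(abs(ur$values[5:(n - 5)] - u$values[5:(n - 5)]))
  }, numeric(1))
  expect_gt(err[1] / err[2], 1.5)
  expect_gt(err[2] / err[3], 1.5)
})

test_that("m = 0 recovery equals the continuous Z-transform sample-for-sample", {
  ch <- std_chamber(500)
  u <- generate_pulse_train(pulse_train_spec(50, 1, 2, 2, pre_pad_s = 1,
                                             post_pad_s = 30), dt = 0.1)
  cc <- add_noise(simulate_well_mixed(u, ch), 0.2, seed = 12)
  st <- recovery_settings()
  a <- recover_ezt(cc, gamma_ir(0, 1 / ch$tau_s, 0), st)
  b <- recover_zt_continuous(cc, compute_z(ch), st)
  expect_identical(a$values, b$values)
})

test_that("with noise, the gamma recovery beats the exponential inverse", {
  # the benchmark scenario at low switching frequency with sensor noise
  ir <- std_ir_250(delay = 5.8)
  u <- generate_pulse_train(pulse_train_spec(100, 5, 10, 3, pre_pad_s = 20,
                                             post_pad_s = 85), dt = 0.1)
  cc <- add_noise(simulate_convolution(u, ir), 0.5, seed = 9)
  st <- recovery_settings()
  u_ezt <- recover_ezt(cc, ir, st)
  h <- sampled_ir_curve(ir)
  bfit <- fit_impulse_response(h, "zt")$model$beta
  u_zt <- recover_zt_discrete(cc, zt_params(tau_s = 1 / bfit, dt = 0.1))
  expect_lt(normalized_itae(u_ezt, u), normalized_itae(u_zt, u))
})

test_that("the adaptive filter hook engages when a quiet region is given", {
  ir <- std_ir_250(delay = 0)
  u <- generate_pulse_train(pulse_train_spec(100, 5, 10, 1, pre_pad_s = 20,
                                             post_pad_s = 80), dt = 0.1)
  cc <- add_noise(simulate_convolution(u, ir), 0.5, seed = 4)
  plain <- recover_ezt(cc, ir, recovery_settings())
  filt <- recover_ezt(cc, ir, recovery_settings(quiet_idx = 20:180))
  # filtering reduces noise in the quiet region
  expect_lt(sqrt(mean(filt$values[20:180]^2)),
            sqrt(mean(plain$values[20:180]^2)))
})
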