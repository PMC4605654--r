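test_that("the gamma model evaluates correctly at its landmarks", {
  ch <- std_chamber()
  # m = 0, beta = F/V: exponential decay starting at F/V
  ir0 <- gamma_ir(0, ch$rate_per_s, 0)
  expect_equal(ir_evaluate(ir0, 0), ch$rate_per_s)
  # causality: zero before the delay
  ir <- std_ir_250()
  expect_equal(ir_evaluate(ir, c(0, 3, 5.81)), c(0, 0, 0))
  # m = 1, beta = 1: argmax of t exp(-t) is t = 1 (derivative root)
  ir1 <- gamma_ir(1, 1, 0)
  tt <- seq(0, 10, by = 1e-3)
  expect_equal(tt[which.max(ir_evaluate(ir1, tt))], 1, tolerance = 1e-3)
})

test_that("alpha normalizes the density to unit area for random shapes", {
  # property: integral over [delay, delay + 40/beta] is 1 within 1e-4
  set.seed(11)
  for (i in 1:25) {
    m <- stats::runif(1, 0, 5)
    beta <- stats::runif(1, 0.05, 5)
    ir <- gamma_ir(m, beta, delay = stats::runif(1, 0, 3))
    area <- stats::integrate(function(t) ir_evaluate(ir, t), ir$delay,
                             ir$delay + 40 / beta, rel.tol = 1e-9,
                             subdivisions = 500L)$value
    expect_lt(abs(area - 1), 1e-4)
  }
  # for integer m the coefficient uses the factorial exactly
  expect_identical(gamma_ir(3, 2)$alpha, 2^4 / factorial(3))
})

test_that("normalize_measured_response rescales to unit trapezoidal area", {
  tt <- seq(0, 30, by = 0.01)
  x <- resp_ts(2 * exp(-tt), dt = 0.01)
  y <- normalize_measured_response(x)
  expect_lt(abs(pracma::trapz(ts_times(y), y$values) - 1), 1e-9)
  # shape preserved up to scale
  expect_equal(y$values / y$values[1], x$values / x$values[1],
               tolerance = 1e-12)
  expect_error(normalize_measured_response(resp_ts(rep(0, 10), dt = 0.1)),
               "area")
})

test_that("estimate_delay finds the threshold crossing", {
  ir <- std_ir_250()
  h <- sampled_ir_curve(ir)
  d <- estimate_delay(h)
  # within 2 samples of the best-fit delay refined by the optimizer
  fit <- fit_impulse_response(h, "integer_m")
  expect_lt(abs(d - fit$model$delay), 1.2)
  # signal that is immediately above threshold crosses at t0
  x <- resp_ts(rep(1, 10), dt = 0.1, t0 = 3)
  expect_error(estimate_delay(x), "flat")
  x <- resp_ts(c(1, rep(0.5, 9)), dt = 0.1, t0 = 3)
  expect_equal(estimate_delay(x), 3)
  expect_error(estimate_delay(resp_ts(rep(0, 5), dt = 1)), "flat")
})

test_that("fitting recovers generating parameters from noisy curves", {
  # truth taken from the benchmark chamber's integer-shape responses,
  # 0.5% multiplicative-peak noise, fixed seed
  cases <- list(list(ir = std_ir_250(), seed = 7),
                list(ir = std_ir_500(), seed = 8))
  for (cs in cases) {
    h <- sampled_ir_curve(cs$ir, noise_sd = 0.005, seed = cs$seed)
    fit <- fit_impulse_response(h, "integer_m")
    expect_identical(fit$model$m, 1)
    expect_lt(abs(fit$model$beta - cs$ir$beta) / cs$ir$beta, 0.05)
    expect_lt(abs(fit$model$delay - cs$ir$delay), 0.2)
  }
})

test_that("zt-mode fitting is self-consistent on its own model class", {
  h <- sampled_ir_curve(gamma_ir(0, 0.2, 0))
  fit <- fit_impulse_response(h, "zt")
  expect_lt(abs(fit$model$beta - 0.2) / 0.2, 0.05)
  expect_lt(fit$itae_fraction, 0.02)
})

test_that("richer fitting modes nest: larger feasible sets never fit worse", {
  h <- sampled_ir_curve(std_ir_250(), noise_sd = 0.005, seed = 3)
  f_real <- fit_impulse_response(h, "real_m")
  f_int <- fit_impulse_response(h, "integer_m")
  f_red <- fit_impulse_response(h, "reduced_m", itae_budget = Inf)
  f_zt <- fit_impulse_response(h, "zt")
  tol <- 1e-6
  expect_lte(f_real$itae_fraction, f_int$itae_fraction + tol)
  expect_lte(f_real$itae_fraction, f_zt$itae_fraction + tol)
  # infinite budget makes reduced_m stop at m = 0, the smallest integer
  expect_identical(f_red$model$m, 0)
  # finite default budget finds an integer shape within it
  f_red10 <- fit_impulse_response(h, "reduced_m")
  expect_lte(f_red10$itae_fraction, 0.10)
  expect_gte(f_int$itae_fraction - tol, 0)
})

test_that("an exponential fit is much worse than a gamma fit on m >= 1 data", {
  h <- sampled_ir_curve(std_ir_250())
  f_zt <- fit_impulse_response(h, "zt")
  f_real <- fit_impulse_response(h, "real_m")
  expect_gt(f_zt$itae_fraction / f_real$itae_fraction, 2)
})
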