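test_that("calibration solves identity and pure-delay systems exactly", {
  set.seed(51)
  u <- resp_ts(stats::rnorm(120), dt = 0.1)
  # identity system: first unit vector
  cal <- calibrate_gzt(u, u, n_taps = 5)
  expect_equal(cal$a, c(1, rep(0, 5)), tolerance = 1e-9)
  # delay by d samples: unit vector at index d, zero residual
  d <- 3L
  cc <- resp_ts(c(rep(0, d), u$values), dt = 0.1)
  cal_d <- calibrate_gzt(u, cc, n_taps = 8)
  expect_equal(cal_d$a, c(rep(0, d), 1, rep(0, 8 - d)), tolerance = 1e-8)
  n_rows <- min(length(u$values), length(cc$values) - 8L)
  C <- respdeconv:::gzt_design_matrix(cc$values, 8L, n_rows)
  expect_lt(sqrt(sum((C %*% cal_d$a - u$values[seq_len(n_rows)])^2)), 1e-8)
})

test_that("least-squares solution matches the normal-equations oracle", {
  # brute-force (C'C)^{-1} C'u on a small well-conditioned instance
  set.seed(52)
  u <- resp_ts(stats::rnorm(60), dt = 0.1)
  cv <- as.numeric(stats::filter(c(u$values, rep(0, 10)), c(0.5, 0.3, 0.2),
                                 sides = 1, method = "convolution"))
  cv[is.na(cv)] <- 0
  cc <- resp_ts(cv, dt = 0.1)
  cal <- calibrate_gzt(u, cc, n_taps = 6)
  C <- respdeconv:::gzt_design_matrix(cc$values, 6L, length(u$values))
  a_oracle <- solve(crossprod(C), crossprod(C, u$values))
  expect_equal(cal$a, as.numeric(a_oracle), tolerance = 1e-8)
  # optimality: any perturbed coefficient vector has a larger residual
  r0 <- sum((C %*% cal$a - u$values)^2)
  for (i in 1:10) {
    eps <- stats::rnorm(7, 0, 0.01)
    expect_gte(sum((C %*% (cal$a + eps) - u$values)^2), r0)
  }
})

test_that("the FIR recovery is linear, shift-covariant and truncating", {
  cal <- structure(list(a = c(1, rep(0, 4)), n_taps = 4L, dt = 0.1,
                        training_itae = 0), class = "gzt_calibration")
  x <- resp_ts(sin(seq(0, 5, by = 0.1)), dt = 0.1)
  out <- recover_gzt(x, cal)
  n <- length(x$values) - 4L
  expect_equal(out$values, x$values[seq_len(n)])
  # zero in, zero out; scaling in, scaling out
  expect_true(all(recover_gzt(resp_ts(rep(0, 30), dt = 0.1), cal)$values == 0))
  set.seed(53)
  cal2 <- structure(list(a = stats::rnorm(5), n_taps = 4L, dt = 0.1,
                         training_itae = 0), class = "gzt_calibration")
  y2 <- recover_gzt(resp_ts(3 * x$values, dt = 0.1), cal2)
  y1 <- recover_gzt(x, cal2)
  expect_equal(y2$values, 3 * y1$values, tolerance = 1e-12)
  # shifting the record shifts the recovery
  k <- 5L
  xs <- resp_ts(c(rep(0, k), x$values), dt = 0.1)
  ys <- recover_gzt(xs, cal2)
  expect_equal(ys$values[(k + 1):(k + length(y1$values))], y1$values,
               tolerance = 1e-12)
  # dt mismatch is refused: coefficients are sampling-period specific
  expect_error(recover_gzt(resp_ts(1:30, dt = 0.2), cal), "dt")
})

test_that("calibration generalizes to fresh inputs from the same system", {
  # the transport delay matters: it gives the future-only filter the
  # effective past context the inverse of an m = 1 system needs
  ir <- std_ir_500(delay = 4.2)
  dt <- 0.1
  u_cal <- std_calibration_input(dt, pre_pad_s = 5, post_pad_s = 45)
  c_cal <- simulate_convolution(u_cal, ir)
  cal <- calibrate_gzt(u_cal, c_cal, n_taps = 120)
  expect_lt(cal$training_itae, 0.01)
  u_new <- generate_pulse_train(pulse_train_spec(80, 1, 3, 2, pre_pad_s = 4,
                                                 post_pad_s = 45), dt)
  c_new <- simulate_convolution(u_new, ir)
  expect_lt(normalized_itae(recover_gzt(c_new, cal), u_new), 0.05)
})

test_that("validation error plateaus once N covers the impulse response", {
  ir <- gamma_ir(1, 2, 1)  # short washout so the test stays small
  dt <- 0.1
  # aperiodic telegraph input: a strictly periodic calibration record makes
  # the design matrix rank deficient for filters longer than the period
  set.seed(54)
  blocks <- sample(3:25, 60, replace = TRUE)
  uv <- unlist(mapply(rep, rep(c(0, 100), 30), blocks, SIMPLIFY = FALSE))
  u <- resp_ts(c(uv, rep(0, 200)), dt = dt)
  cc <- simulate_convolution(u, ir)
  ir_len <- ceiling((ir$delay + ir_support_length(ir)) / dt)
  sel <- select_n(u, cc, c(3, 40, ir_len, ir_len * 2))
  tab <- sel$table
  # beyond the IR length the score no longer improves materially
  v_ir <- tab$validation_itae[tab$n_taps == ir_len]
  v_2ir <- tab$validation_itae[tab$n_taps == ir_len * 2]
  expect_lt(abs(v_2ir - v_ir), 0.05)
  expect_gt(tab$validation_itae[tab$n_taps == 3], v_ir)
  expect_gte(sel$best_n, 40)
  # degenerate grid and tie-breaks
  expect_error(select_n(u, cc, integer(0)), "empty")
  sel0 <- select_n(u, cc, c(0))
  expect_identical(sel0$best_n, 0L)
})
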