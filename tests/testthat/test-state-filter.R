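test_that("process-noise variance follows Q0 + ||u||^2 Qu", {
  p <- filter_params() # Q0 = Qu = 0.4^2
  expect_equal(process_noise_variance(p, 0), 0.16)
  p2 <- filter_params(B_hat = c(0.7, 1.3))
  expect_equal(process_noise_variance(p2, c(3.7, 0)), 0.16 + 13.69 * 0.16)
  p3 <- filter_params(Q0 = 0, Qu = 5)
  expect_equal(process_noise_variance(p3, 0), 0)
  expect_error(process_noise_variance(p2, 0), "length")
})

test_that("state prediction combines persistence, cue gains and Q", {
  st <- list(x_hat = 5, P = 1, k = 0)
  pr <- predict_state(st, filter_params(A_hat = 0.8), u = 0)
  expect_equal(pr$xbar_hat, 4.0)
  expect_equal(pr$Q, 0.16)
  expect_equal(pr$Pbar, 0.64 * 1 + 0.16)

  # memoryless cue-driven prior (discrete-trial setting)
  pr2 <- predict_state(list(x_hat = 9, P = 2),
                       filter_params(A_hat = 0, B_hat = c(0.7, 1.3)),
                       u = c(3.7, 0))
  expect_equal(pr2$xbar_hat, 2.59)

  # identity persistence on zero state
  pr3 <- predict_state(list(x_hat = 0, P = 3), filter_params(A_hat = 1),
                       u = 0)
  expect_equal(pr3$xbar_hat, 0)
  expect_equal(pr3$Pbar, 3 + pr3$Q)
})

test_that("state update fuses prior and observation through the gain", {
  # symmetric case: equal uncertainties give the midpoint
  up <- update_state(list(xbar_hat = 2, Pbar = 0.64), z = 4, R = 0.64)
  expect_equal(up$K, 0.5)
  expect_equal(up$x_hat, 3)
  # first step with the enormous initial variance is sensor-dominated
  up2 <- update_state(list(xbar_hat = 0, Pbar = 1e6), z = 4, R = 0.8^2)
  expect_lt(abs(up2$x_hat - 4), 1e-5)
  expect_error(update_state(list(xbar_hat = 0, Pbar = 1), z = 1, R = 0),
               "R")
})

test_that("gain and variance invariants hold across parameter ranges", {
  Pbar <- c(1e-6, 0.5, 3, 1e4)
  Rs <- c(1e-8, 0.64, 3.24, 1e6)
  for (pb in Pbar) {
    K <- pb / (pb + Rs)
    up <- lapply(Rs, function(R) update_state(list(xbar_hat = 1, Pbar = pb),
                                              z = 5, R = R))
    Ks <- vapply(up, `[[`, 1, "K")
    expect_true(all(Ks > 0 & Ks < 1))
    expect_true(all(diff(Ks) < 0)) # K decreases as R grows
    Ps <- vapply(up, `[[`, 1, "P")
    expect_true(all(Ps < pb)) # conditioning never loses information
    xh <- vapply(up, `[[`, 1, "x_hat")
    expect_true(all(xh >= 1 & xh <= 5)) # convex combination of prior and z
  }
})

test_that("steady-state prior variance matches the iteration oracle", {
  expect_equal(steady_state_prior_variance(0, 0.16, 0.64), 0.16)
  # A = 1: positive root of Pbar^2 - Q Pbar - Q R = 0
  root <- (0.16 + sqrt(0.16^2 + 4 * 0.16 * 0.64)) / 2
  expect_equal(steady_state_prior_variance(1, 0.16, 0.64), root)
  grid <- expand.grid(A = c(0, 0.5, 0.9, 1, 1.2), Q = c(0.01, 0.16, 2),
                      R = c(0.05, 0.64, 100))
  for (i in seq_len(nrow(grid))) {
    cf <- steady_state_prior_variance(grid$A[i], grid$Q[i], grid$R[i])
    it <- iterate_prior_variance(grid$A[i], grid$Q[i], grid$R[i])
    expect_lt(abs(cf - it) / cf, 1e-8)
  }
})

test_that("the filter run is deterministic given a seed and converges", {
  sch <- impulse_schedule(80)
  t1 <- run_filter(sch, filter_params(), seed = 42)
  t2 <- run_filter(sch, filter_params(), seed = 42)
  expect_identical(t1, t2)
  # the prior variance settles onto the Riccati fixed point (u = 0 tail)
  sch0 <- stimulus_schedule(500, R = 0.64)
  tr <- run_filter(sch0, filter_params(A_hat = 0.9),
                   sample_process_noise = FALSE, seed = 1)
  ss <- steady_state_prior_variance(0.9, 0.16, 0.64)
  expect_lt(abs(tr$Pbar[500] - ss) / ss, 1e-10)
})

test_that("initial posterior mean is immaterial under the default P0", {
  sch <- stimulus_schedule(30, R = 0.64)
  a <- run_filter(sch, filter_params(x0 = 0), seed = 3)
  b <- run_filter(sch, filter_params(x0 = 7), seed = 3)
  expect_lt(max(abs(a$x_hat - b$x_hat)), 1e-4)
})

test_that("negative persistence is rejected at configuration time", {
  expect_error(filter_params(A_hat = -0.1), "A_hat")
  expect_error(filter_params(R = -1), "R")
  expect_error(filter_params(P0 = 0), "P0")
})
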