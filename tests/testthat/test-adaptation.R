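test_that("response function and error signal follow the model arithmetic", {
  rf <- response_function(50, 0.5)
  expect_equal(predict_mga(rf, v = 40), 70)
  expect_equal(predict_mga(rf, v = 40, x = 12), 76)
  # x = 0 reduces to the plain response function
  expect_equal(predict_mga(rf, v = 37), predict_mga(rf, v = 37, x = 0))

  # grasp larger than comfortable for the felt size -> positive error,
  # and the update lowers the state
  expect_equal(error_signal(rf, h = 44, mga_observed = 75), 3)
  expect_equal(error_signal(rf, h = 44, mga_observed = 72), 0)
  expect_equal(error_signal(rf, h = 44, mga_observed = 69), -3)
  expect_lt(update_state(0.95, 0.2, x = 0, E = 3), 0)
  # the printed convention is the mirror image
  expect_equal(error_signal(rf, 44, 75, sign_convention = "printed"), -3)
})

test_that("state update limits behave as the parameters say", {
  expect_equal(update_state(1, 0, x = 5, E = 100), 5)   # no error-correction
  expect_equal(update_state(0, 0.5, x = 99, E = 0), 0)  # no retention
  expect_error(update_state(1.2, 0.2, 0, 0))
})

test_that("closed-loop state converges to the analytic fixed point", {
  p <- sim_participant(motor_noise_sd = 0, slope_true = 1,
                       intercept_true = 24)
  sp <- schedule_spec("abrupt", magnitude = 12, n_trials = 260,
                      baseline_len = 4)
  sch <- make_abrupt_schedule(sp, rep(40, 260))
  sim <- simulate_mgas(p, sch)
  x_star <- 0.2 * 1 * 12 / (1 - 0.95 + 0.2 * 1)
  expect_equal(x_star, 9.6)
  expect_equal(sim$state_x[256], x_star, tolerance = 1e-6)
})

test_that("self-driven forward run shows exponential approach and washout", {
  rf <- response_function(24, 1)
  sch <- make_abrupt_schedule(schedule_spec("abrupt", magnitude = 12),
                              rep(40, 24))
  fwd <- run_forward(0.95, 0.2, rf, sch)
  expect_equal(fwd$state_x[1:4], rep(0, 4))            # baseline
  d_pert <- diff(fwd$state_x[5:21])
  expect_true(all(d_pert > 0))                          # monotone approach
  expect_true(all(diff(d_pert) < 0))                    # exponential slowing
  d_wash <- diff(fwd$state_x[21:24])
  expect_true(all(d_wash < 0))                          # decay in washout
  # zero perturbation: all states zero, predictions are the response function
  sch0 <- make_abrupt_schedule(schedule_spec("abrupt", magnitude = 0),
                               rep(40, 24))
  fwd0 <- run_forward(0.95, 0.2, rf, sch0)
  expect_equal(fwd0$state_x, rep(0, 24))
  expect_equal(fwd0$mga_pred, rep(predict_mga(rf, 40), 24))
})

test_that("closed loop on matching noise-free observations is self-consistent", {
  p <- sim_participant(motor_noise_sd = 0)
  sch <- make_sinusoidal_schedule(schedule_spec("sinusoidal", magnitude = 12),
                                  rep(44, 36))
  sim <- simulate_mgas(p, sch)
  rf <- response_function(24, 0.93)
  fwd <- run_forward(0.95, 0.2, rf, sch, observed_mgas = sim$mga_mm)
  expect_equal(fwd$mga_pred, sim$mga_mm, tolerance = 1e-12)
  expect_error(run_forward(0.95, 0.2, rf, sch, observed_mgas = 1:5), "length")
})

test_that("sinusoidal steady state matches the linear-filter frequency response", {
  # noise-free closed loop is x' = (A - b s) x + b s * mismatch: compare the
  # simulated steady-state sinusoid with H(e^{i w}) computed numerically
  A <- 0.95; b <- 0.2; s <- 0.93
  P <- 12; M <- 12
  sp <- schedule_spec("sinusoidal", magnitude = M, n_trials = 40 * P,
                      n_cycles = 40, quantum = 1e-9)
  sch <- make_sinusoidal_schedule(sp, rep(44, 40 * P))
  p <- sim_participant(A_true = A, b_true = b, slope_true = s,
                       motor_noise_sd = 0)
  sim <- simulate_mgas(p, sch)
  w <- 2 * pi / P
  late <- (20 * P + 1):(40 * P)
  t1 <- late - 1
  fit <- lm(sim$state_x[late] ~ sin(w * t1) + cos(w * t1))
  amp <- unname(sqrt(sum(coef(fit)[2:3]^2)))
  phase <- unname(atan2(coef(fit)[3], coef(fit)[2]))
  H <- (b * s) * exp(-1i * w) / (1 - (A - b * s) * exp(-1i * w))
  expect_equal(amp, M * Mod(H), tolerance = 1e-6)
  expect_equal(phase, Arg(H), tolerance = 1e-6)
  # the response lags and is attenuated, as in a leaky integrator
  expect_lt(amp, M)
  expect_lt(phase, 0)
})

test_that("block fit recovers generating parameters exactly without noise", {
  sch <- make_abrupt_schedule(schedule_spec("abrupt", magnitude = 12),
                              rep(44, 24))
  sim <- simulate_mgas(sim_participant(motor_noise_sd = 0), sch)
  fit <- fit_block(sim$mga_mm, sch, slope_fixed = 0.93)
  expect_equal(fit$A, 0.95, tolerance = 1e-3)
  expect_equal(fit$b, 0.2, tolerance = 1e-3)
  expect_equal(fit$intercept, 24, tolerance = 1e-2)
  expect_lt(fit$rmse, 1e-6)
  expect_false(fit$flat_ridge)
  # tidy/glance accessors
  td <- tidy(fit)
  expect_equal(td$term, c("A", "b", "intercept"))
  expect_equal(nrow(glance(fit)), 1)
})

test_that("fit objective at the optimum is never worse than at the truth", {
  sch <- make_abrupt_schedule(schedule_spec("abrupt", magnitude = 6),
                              rep(44, 24))
  for (seed in 1:5) {
    sim <- simulate_mgas(sim_participant(), sch, seed = seed)
    fit <- fit_block(sim$mga_mm, sch, slope_fixed = 0.93)
    rmse_truth <- {
      rf <- response_function(24, 0.93)
      fwd <- run_forward(0.95, 0.2, rf, sch, sim$mga_mm)
      sqrt(mean((fwd$mga_pred - sim$mga_mm)^2))
    }
    expect_lte(fit$rmse, rmse_truth + 1e-10)
  }
})

test_that("unperturbed constant blocks leave b on a flat ridge", {
  sch0 <- make_abrupt_schedule(schedule_spec("abrupt", magnitude = 0),
                               rep(44, 24))
  mgas <- rep(24 + 0.93 * 44, 24)
  fit <- fit_block(mgas, sch0, slope_fixed = 0.93)
  expect_true(fit$flat_ridge)
  expect_lt(fit$rmse, 1e-6)
})

test_that("excluded trials propagate the state but drop out of the RMSE", {
  sch <- make_abrupt_schedule(schedule_spec("abrupt", magnitude = 12),
                              rep(44, 24))
  sim <- simulate_mgas(sim_participant(motor_noise_sd = 0), sch)
  obs <- sim$mga_mm
  obs[c(7, 15)] <- NA
  fit <- fit_block(obs, sch, slope_fixed = 0.93)
  expect_equal(fit$n, 22)
  expect_equal(fit$A, 0.95, tolerance = 1e-3)
  expect_equal(fit$b, 0.2, tolerance = 1e-3)
  expect_error(fit_block(c(obs[1:5], rep(NA, 19)), sch, 0.93), "usable")
})

test_that("response slope estimation is exact on linear data", {
  tr <- tidyr::expand_grid(participant = 1:3, v_mm = c(40, 44, 48),
                           rep = 1:5) |>
    dplyr::mutate(mga_mm = 20 + 1.0 * v_mm)
  sl <- fit_response_slope(tr)
  expect_equal(sl$mean_slope, 1.0, tolerance = 1e-12)
  # two-point line
  tr2 <- tibble::tibble(participant = 1, v_mm = c(40, 48), mga_mm = c(70, 74))
  expect_equal(fit_response_slope(tr2)$mean_slope, 0.5)
  expect_error(fit_response_slope(
    tibble::tibble(participant = 1, v_mm = 40, mga_mm = 70)), "distinct")
})

test_that("cohort-level slope estimate recovers the generating slope", {
  cohort <- sim_cohort(6)
  sim <- simulate_experiment(cohort, "main", seed = 99)
  sl <- fit_response_slope(sim$trials)
  expect_equal(sl$mean_slope, 0.93, tolerance = 0.05)
})
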