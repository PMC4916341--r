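test_that("constant-drive firing time matches its closed form", {
  # delta = tau/2 gives T = tau ln 2
  expect_equal(lif_constant_drive_time(10, 5), 10 * log(2))
  expect_equal(lif_constant_drive_time(10, 1), 10 * log(10 / 9))
  # firing iff delta < tau
  expect_identical(lif_constant_drive_time(10, 10), Inf)
  expect_identical(lif_constant_drive_time(10, 12), Inf)
  # cross-check against simulation
  tr <- simulate_lif(lif10, constant_drive(1 / 1), t_end = 2)
  expect_equal(tr$spike_times[1], lif_constant_drive_time(10, 1),
               tolerance = 1e-5)
})

test_that("phi is strictly decreasing with the right limits", {
  expect_equal(charge_phi(2), 2 * log(2))
  s <- exp(seq(log(1.0001), log(1e4), length.out = 400))
  expect_true(all(diff(charge_phi(s)) < 0))
  expect_equal(charge_phi(1e8), 1, tolerance = 1e-7)
  expect_gt(charge_phi(1.0000001), 15)
  expect_error(charge_phi(1))
  expect_error(charge_phi(0.5))
})

test_that("charge to threshold is firing time over interval: Q = T/Delta", {
  set.seed(421)
  for (i in 1:50) {
    tau <- runif(1, 1, 30)
    delta <- runif(1, 0.05, 0.99) * tau
    expect_equal(charge_phi(tau / delta),
                 lif_constant_drive_time(tau, delta) / delta)
  }
})

test_that("delta-train prediction agrees with the event-driven jump map", {
  # boundary case w = 1 - e^(-delta/tau) exactly: does not fire
  tau <- 10; delta <- tau * log(2)   # rho = 1/2
  pred <- delta_train_predict(tau, 0.5, delta)
  expect_false(pred$fires)
  expect_identical(pred$n_pulses, Inf)
  # no-decay limit: count is ceiling(1/w)
  expect_equal(delta_train_predict(10, 0.3, 1e-9)$n_pulses, 4)
  expect_equal(delta_train_predict(10, 0.25, 1e-9)$n_pulses, 4)
  # 20 x 20 grid against brute-force iteration of v <- v rho + w
  for (w in seq(0.05, 0.99, length.out = 20)) {
    for (dt_ratio in seq(0.02, 3, length.out = 20)) {
      delta <- dt_ratio * 10
      pred <- delta_train_predict(10, w, delta)
      brute <- lif_jump_map_count(10, w, delta)
      expect_equal(pred$n_pulses, brute,
                   info = sprintf("w=%.3f delta=%.2f", w, delta))
      expect_identical(pred$fires, is.finite(brute))
    }
  }
})

test_that("ramp firing solves the threshold equation to high accuracy", {
  for (delta in c(0.0125, 0.05, 0.5, 2)) {
    res <- ramp_firing(tau = 10, c = 0.025, delta = delta)
    expect_lt(res$residual, 1e-12)
    expect_equal(res$M_tilde, res$T_tilde / delta)
    expect_gt(res$T_tilde, 0)
  }
  # small-delta approximation T ~ sqrt(2 delta / c)
  res <- ramp_firing(10, 0.025, 1e-5)
  expect_equal(res$T_tilde, sqrt(2 * 1e-5 / 0.025), tolerance = 1e-3)
  # asymptote M sqrt(delta) -> sqrt(2/c), within 2 percent for
  # delta < 1e-3 c tau^2
  delta <- 1e-3 * 0.025 * 100
  res <- ramp_firing(10, 0.025, delta)
  expect_equal(res$M_tilde * sqrt(delta), sqrt(2 / 0.025), tolerance = 0.02)
})

test_that("ramp firing agrees with direct simulation of the ramp drive", {
  res <- ramp_firing(tau = 10, c = 0.025, delta = 0.05)
  tr <- simulate_lif(lif10, ramp_drive(0.025, 0.05),
                     t_end = res$T_tilde * 1.5, dt = 0.001)
  expect_equal(tr$spike_times[1], res$T_tilde, tolerance = 1e-5)
})
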