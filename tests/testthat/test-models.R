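test_that("LIF threshold, reset and closed-form firing time", {
  # tau = 10, constant drive 1/5: first spike at the closed-form time
  tr <- simulate_lif(lif10, constant_drive(1 / 5), t_end = 40)
  expect_equal(tr$spike_times[1], lif_constant_drive_time(10, 5),
               tolerance = 1e-6)
  # periodic: subsequent interspike intervals equal the first firing time
  expect_equal(diff(tr$spike_times)[1], tr$spike_times[1], tolerance = 1e-5)
  # after reset v restarts below threshold
  expect_true(all(tr$states[, "v"] < 1))
  # no spike for delta >= tau, for a long horizon
  tr2 <- simulate_lif(lif10, constant_drive(1 / 10), t_end = 500)
  expect_length(tr2$spike_times, 0)
  # zero drive from v = 0 stays at equilibrium
  tr3 <- simulate_lif(lif10, NULL, t_end = 50)
  expect_true(all(tr3$states[, "v"] == 0))
})

test_that("delta-pulse injections jump the LIF voltage and can spike it", {
  pred <- delta_train_predict(10, 0.4, 5)   # geometric-sum pulse count
  tr <- simulate_lif(lif10, delta_train(w = 0.4, delta = 5), t_end = 60)
  # the predicted arrival lifts v above 1: spike exactly at that pulse time
  expect_equal(tr$spike_times[1], 5 * pred$n_pulses)
  i <- which(tr$times == 5)
  expect_equal(unname(tr$states[i, "v"]), 0.4)  # right-limit at the jump
})

test_that("LIF comparison principle: larger tau gives larger response", {
  for (par in list(c(1.25, 1), c(2, 0.3), c(0.8, 3))) {
    p <- alpha_pulse(par[1], par[2])
    a <- simulate_lif(lif_model(4), p, t_end = 40, reset = FALSE)
    b <- simulate_lif(lif_model(12), p, t_end = 40, reset = FALSE)
    expect_true(all(a$states[, "v"] <= b$states[, "v"] + 1e-12))
    big <- b$states[, "v"] > 1e-6
    expect_true(all(a$states[big, "v"] < b$states[big, "v"]))
  }
})

test_that("LIF scaling identity: v_eps(t, tau) = v(t/eps, tau/eps)", {
  set.seed(77)
  for (i in 1:4) {
    r <- runif(1, 0.5, 2); eps <- runif(1, 0.3, 3); tau <- runif(1, 2, 20)
    a <- simulate_lif(lif_model(tau), alpha_pulse(r, eps),
                      t_end = 10 * eps, dt = 0.002 * eps, reset = FALSE)
    b <- simulate_lif(lif_model(tau / eps), alpha_pulse(r, 1),
                      t_end = 10, dt = 0.002, reset = FALSE)
    expect_equal(a$states[, "v"], b$states[, "v"], tolerance = 1e-8)
  }
})

test_that("theta neuron fixed points and bifurcation", {
  expect_equal(theta_fixed_points(theta_half, 0), c(v_minus = 0, v_plus = 1))
  expect_equal(theta_fixed_points(theta_half, 1 / (4 * 0.5)),
               c(v_minus = 0.5, v_plus = 0.5))
  fp <- theta_fixed_points(theta_half, 0.3)
  expect_equal(unname(fp), 0.5 + c(-1, 1) * sqrt(0.25 - 0.15))
  # both values are roots of -v(1-v)/tau + I
  expect_equal(-fp * (1 - fp) / 0.5 + 0.3, c(v_minus = 0, v_plus = 0))
  expect_null(theta_fixed_points(theta_half, 0.6))
  # zero drive, started at the stable fixed point v = 0: stationary
  tr <- simulate_theta(theta_half, NULL, t_end = 20, theta0 = -pi / 2)
  expect_true(all(abs(tr$states[, "theta"] + pi / 2) < 1e-12))
  # I above the saddle-node value 1/(4 tau): periodic firing
  tr2 <- simulate_theta(theta_half, constant_drive(0.8), t_end = 50)
  expect_gt(length(tr2$spike_times), 3)
  expect_true(tr2$blew_up)
  # I below it: no firing
  tr3 <- simulate_theta(theta_half, constant_drive(0.3), t_end = 200)
  expect_length(tr3$spike_times, 0)
})

test_that("theta blow-up time from v = q matches separation of variables", {
  for (q in c(1.5, 4, 10)) {
    th0 <- 2 * atan(2 * q - 1)
    tr <- simulate_theta(theta_half, NULL, t_end = 2, dt = 1e-4, theta0 = th0)
    expect_equal(tr$spike_times[1], qif_blowup_time(0.5, q), tolerance = 1e-4)
  }
  # same via an instantaneous charge injection from rest: jump to v = 4
  tr <- simulate_theta(theta_half, delta_train(w = 4, delta = 1, n_pulses = 1),
                       t_end = 2, dt = 1e-4)
  expect_equal(tr$spike_times[1], 1 + qif_blowup_time(0.5, 4), tolerance = 1e-4)
})

test_that("theta trajectories from v = 0 stay nonnegative under pulses", {
  for (par in list(c(1.25, 0.3), c(0.9, 1), c(2, 4))) {
    tr <- simulate_theta(theta_half, alpha_pulse(par[1], par[2]),
                         t_end = 30 * par[2])
    expect_true(all(tr$states[, "theta"] >= -pi / 2 - 1e-9))
  }
})

test_that("conductance-based resting states are true equilibria", {
  for (m in list(wb, rtm)) {
    rs <- resting_state(m)
    dv <- pulsesync:::hh_deriv_cpp(m$model_id, rs, 0)
    expect_lt(max(abs(dv)), 1e-10)
    expect_lt(rs[["v"]], m$spike_detection_level)
    # self-consistency: 100 ms of zero-drive simulation stays put
    tr <- simulate_hh(m, NULL, t_end = 100, init = rs)
    expect_lt(max(abs(tr$states[, "v"] - rs[["v"]])), 0.01)
    expect_length(tr$spike_times, 0)
  }
})

test_that("WB pulse responses: firing premise and non-firing compression", {
  # the strong reference pulse 20 t e^-t elicits exactly one spike
  tr <- simulate_hh(wb, alpha_pulse(20, 1), t_end = 40)
  expect_length(tr$spike_times, 1)
  # the weaker pulse 7 t e^-t stretched beyond its firing window does not
  tr2 <- simulate_hh(wb, alpha_pulse(7, 3), t_end = 150)
  expect_length(tr2$spike_times, 0)
})

test_that("halving dt leaves spike times essentially unchanged", {
  t1 <- simulate_lif(lif10, constant_drive(1 / 2), t_end = 10, dt = 0.01)
  t2 <- simulate_lif(lif10, constant_drive(1 / 2), t_end = 10, dt = 0.005)
  expect_equal(t1$spike_times, t2$spike_times, tolerance = 1e-6)
  w1 <- simulate_hh(wb, alpha_pulse(20, 1), t_end = 20, dt = 0.01)
  w2 <- simulate_hh(wb, alpha_pulse(20, 1), t_end = 20, dt = 0.005)
  expect_equal(w1$spike_times, w2$spike_times, tolerance = 1e-4)
  th1 <- simulate_theta(theta_half, alpha_pulse(4, 1), t_end = 20, dt = 0.01)
  th2 <- simulate_theta(theta_half, alpha_pulse(4, 1), t_end = 20, dt = 0.005)
  expect_equal(th1$spike_times, th2$spike_times, tolerance = 1e-6)
})

test_that("trace objects expose state, spikes and tidy CSV export", {
  tr <- simulate_theta(theta_half, alpha_pulse(4, 1), t_end = 10)
  d <- as.data.frame(tr)
  expect_named(d, c("time_ms", "theta", "v"))
  f <- tempfile(fileext = ".csv"); fs <- tempfile(fileext = ".csv")
  write_trace(tr, f, fs)
  back <- utils::read.csv(f)
  expect_equal(back$time_ms, tr$times)
  expect_equal(utils::read.csv(fs)$spike_time_ms, tr$spike_times)
})
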