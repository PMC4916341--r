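test_that("pulse_value follows the compression scaling rule", {
  p <- alpha_pulse(2, 1)
  expect_equal(pulse_value(p, 1), 2 * exp(-1))       # mode of r t e^-t
  expect_equal(pulse_value(p, 0), 0)
  expect_equal(pulse_value(alpha_pulse(2, 7), 0), 0)
  # I_eps(t) = (1/eps) I(t/eps): at eps = 1/2, t = 1/2 this is 2 I(1)
  expect_equal(pulse_value(alpha_pulse(1.25, 0.5), 0.5),
               2 * pulse_value(alpha_pulse(1.25, 1), 1))
  # nonnegative and decaying
  tt <- seq(0, 50, by = 0.5)
  v <- pulse_value(alpha_pulse(1.5, 2), tt)
  expect_true(all(v >= 0))
  expect_lt(v[length(v)], 1e-8)
})

test_that("total charge equals r and is conserved under compression", {
  expect_equal(total_charge(alpha_pulse(1.25)), 1.25)
  expect_equal(total_charge(alpha_pulse(0.9)), 0.9)
  # quadrature of the pulse over [0, 40 eps] agrees with q for eps
  # spanning five orders of magnitude
  for (eps in c(1e-3, 0.1, 1, 10, 100)) {
    p <- alpha_pulse(2, eps)
    q_num <- stats::integrate(function(t) pulse_value(p, t), 0, 40 * eps,
                              rel.tol = 1e-10)$value
    expect_equal(q_num, 2, tolerance = 1e-6 / 2)
  }
})

test_that("gating_series is the exact geometric superposition of arrivals", {
  tr <- synaptic_train(gbar = 1, delta = 2)
  # before the first arrival (at t = delta, not t = 0) s is zero
  expect_equal(gating_series(tr, c(0, 1, 1.999)), c(0, 0, 0))
  # a single pulse decayed one time constant
  tr1 <- synaptic_train(gbar = 1, delta = 2, n_pulses = 1)
  expect_equal(gating_series(tr1, tr1$delta + 3), exp(-1))
  # two-term superposition at delta = 3 = tau_decay
  tr3 <- synaptic_train(gbar = 1, delta = 3)
  expect_equal(gating_series(tr3, 6), 1 + exp(-1))
  # right-limit at an arrival includes the jump
  expect_equal(gating_series(tr3, 3), 1)
  # no-decay limit: n pulses piled up give s -> n
  trs <- synaptic_train(gbar = 1, delta = 1e-7, n_pulses = 12)
  expect_equal(gating_series(trs, 12 * 1e-7), 12, tolerance = 1e-5)
  # between arrivals, ds/dt = -s/3 exactly (piecewise closed form)
  t1 <- 3.2; t2 <- 5.9   # same inter-arrival interval for delta = 3
  expect_equal(gating_series(tr3, t2),
               gating_series(tr3, t1) * exp(-(t2 - t1) / 3))
})

test_that("a fast-decaying synaptic train acts like a delta train on a LIF cell", {
  # charge per pulse ~ gbar * tau_d * (v_rev - v); at small v this is
  # w = 5 gbar tau_d, and the voltage right after pulse k approaches the
  # geometric sum w (1 - rho^k)/(1 - rho) of the instantaneous-injection model
  tau <- 10; delta <- 2; tau_d <- 0.005; gbar <- 1
  w <- 5 * gbar * tau_d
  tr <- synaptic_train(gbar, delta, tau_decay = tau_d)
  out <- simulate_lif(lif10, tr, t_end = 5 * delta + 1, dt = 0.001)
  rho <- exp(-delta / tau)
  for (k in 1:5) {
    v_sim <- unname(out$states[which.min(abs(out$times - (k * delta + 0.1))), "v"])
    v_pred <- w * (1 - rho^k) / (1 - rho) * exp(-0.1 / tau)
    expect_equal(v_sim, v_pred, tolerance = 0.03)
  }
})

test_that("stimulus constructors validate their parameters", {
  expect_error(alpha_pulse(-1, 1))
  expect_error(alpha_pulse(1, 0))
  expect_error(delta_train(0, 1))
  expect_error(synaptic_train(0.1, -2))
  expect_error(ramp_drive(0.025, 0))
})
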