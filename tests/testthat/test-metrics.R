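test_that("peak response decreases with compression, from q down to 0", {
  # LIF, tau = 10, r = 1.25
  eps <- 10^seq(-3, 2, length.out = 12)
  M <- vapply(eps, function(e) peak_response(lif10, alpha_pulse(1.25, e)),
              numeric(1))
  expect_true(all(diff(M) < 0))
  expect_equal(M[1], 1.25, tolerance = 1e-2)        # delta limit: M -> q
  expect_lt(M[length(M)], 0.05)                     # slow limit: M -> 0
  # value at eps = 1 against a frozen fine-step (dt = 1e-4) reference
  expect_equal(peak_response(lif10, alpha_pulse(1.25, 1)), 0.9044355032,
               tolerance = 1e-5)
  # theta, tau = 1/2: decreasing wherever finite and below 1
  Mt <- vapply(c(0.2, 0.5, 1, 5), function(e)
    peak_response(theta_half, alpha_pulse(1.25, e)), numeric(1))
  expect_true(all(is.finite(Mt)))
  expect_true(all(diff(Mt) < 0))
  expect_lt(Mt[4], 0.06)
})

test_that("critical compression exists iff charge exceeds one", {
  expect_error(critical_epsilon(lif10, alpha_pulse(0.9, 1)),
               "no critical epsilon")
  e0 <- critical_epsilon(lif10, alpha_pulse(1.25, 1))
  expect_gt(e0, 0)
  # at the critical compression the peak response is the threshold
  expect_equal(peak_response(lif10, alpha_pulse(1.25, e0)), 1,
               tolerance = 1e-3)
  # spike/no-spike dichotomy across the critical point
  expect_true(is.finite(firing_time(lif10, alpha_pulse(1.25, 0.9 * e0))))
  expect_false(is.finite(firing_time(lif10, alpha_pulse(1.25, 1.1 * e0))))
  # stronger pulses tolerate more stretching
  expect_gt(critical_epsilon(lif10, alpha_pulse(1.5, 1)), e0)
})

test_that("firing-time limits: LIF to zero, theta to the blow-up time", {
  # LIF with q > 1: instantaneous firing in the delta limit
  expect_lt(firing_time(lif10, alpha_pulse(2, 1e-4)), 0.01)
  # theta, tau = 1/2, r = 4: the limit is the time to rise from q to infinity
  expect_equal(firing_time(theta_half, alpha_pulse(4, 1e-4)),
               qif_blowup_time(0.5, 4), tolerance = 3e-3)
  # theta firing time grows without bound approaching the critical
  # compression (the divergence is slow; assert steady growth)
  e0 <- critical_epsilon(theta_half, alpha_pulse(4, 1))
  T_mid <- firing_time(theta_half, alpha_pulse(4, 0.5 * e0))
  T_near <- firing_time(theta_half, alpha_pulse(4, 0.98 * e0))
  T_nearer <- firing_time(theta_half, alpha_pulse(4, 0.9999 * e0))
  expect_gt(T_near, 2 * T_mid)
  expect_gt(T_nearer, 1.3 * T_near)
})

test_that("time ratio is increasing for LIF and U-shaped for theta", {
  e0 <- critical_epsilon(lif10, alpha_pulse(2, 1))
  eps <- e0 * c(0.02, 0.1, 0.3, 0.6, 0.9, 0.99)
  R <- vapply(eps, function(e) time_ratio(lif10, alpha_pulse(2, e)),
              numeric(1))
  expect_true(all(diff(R) > 0))
  # theta: ratio blows up at both ends of the firing window
  e0t <- critical_epsilon(theta_half, alpha_pulse(4, 1))
  Rt <- vapply(e0t * c(0.002, 0.05, 0.3, 0.7, 0.9999), function(e)
    time_ratio(theta_half, alpha_pulse(4, e)), numeric(1))
  expect_gt(Rt[1], 3 * min(Rt))
  expect_gt(Rt[5], 2 * min(Rt))
  expect_true(which.min(Rt) %in% 2:4)
})

test_that("charge to fire equals the pulse integral both ways", {
  cases <- list(list(lif10, alpha_pulse(2, 0.5)),
                list(lif10, alpha_pulse(1.25, 0.3)),
                list(theta_half, alpha_pulse(4, 0.2)))
  for (cs in cases) {
    model <- cs[[1]]; p <- cs[[2]]
    Tf <- firing_time(model, p)
    Q1 <- charge_to_fire(model, p)
    Q2 <- stats::integrate(function(t) pulse_value(p, t), 0,
                           min(Tf, 100 * p$epsilon), rel.tol = 1e-12)$value
    expect_equal(Q1, Q2, tolerance = 1e-6)
  }
  expect_error(charge_to_fire(lif10, alpha_pulse(0.9, 1)), "spike")
})

test_that("charge to fire: monotone for LIF, near q when firing is slow", {
  e0 <- critical_epsilon(lif10, alpha_pulse(2, 1))
  Q <- vapply(e0 * c(0.05, 0.2, 0.5, 0.8, 0.95), function(e)
    charge_to_fire(lif10, alpha_pulse(2, e)), numeric(1))
  expect_true(all(diff(Q) > 0))
  # weak WB pulse: the target fires long after the input is over, so the
  # charge spent is (very close to) the whole pulse charge q = 7
  expect_equal(charge_to_fire(wb, alpha_pulse(7, 0.5)), 7, tolerance = 1e-3)
})

test_that("pulse count to threshold matches the geometric-sum oracle", {
  for (w in c(0.15, 0.3, 0.6)) {
    for (delta in c(0.5, 1, 4)) {
      tr <- delta_train(w, delta)
      expect_equal(pulses_to_threshold(lif10, tr),
                   delta_train_predict(10, w, delta)$n_pulses,
                   info = sprintf("w=%.2f delta=%.1f", w, delta))
    }
  }
  # too-weak train never reaches threshold: w <= 1 - e^(-delta/tau)
  expect_identical(pulses_to_threshold(lif10, delta_train(0.05, 1)), Inf)
})

test_that("count until firing dominates count to threshold", {
  # inter-pulse intervals inside each model's firing window for gbar = 0.005
  cases <- list(list(lif10, 0.1), list(theta_half, 0.02), list(wb, 1))
  for (cs in cases) {
    tr <- synaptic_train(gbar = 0.005, delta = cs[[2]])
    N <- pulses_to_threshold(cs[[1]], tr)
    M <- pulses_until_fire(cs[[1]], tr)
    expect_true(is.finite(N) && is.finite(M))
    expect_gte(M, N)
  }
})

test_that("near-critical theta input hovers at the unstable level", {
  # just below the critical compression the trajectory lingers near v = 1
  # (theta = pi/2) before resolving, longer the closer to critical
  r <- 1.25
  e0 <- critical_epsilon(theta_half, alpha_pulse(r, 1))
  hover <- function(eps) {
    tr <- simulate_theta(theta_half, alpha_pulse(r, eps), t_end = 400)
    th <- tr$states[, "theta"]
    band <- th > 2 * atan(2 * 0.95 - 1) & th < 2 * atan(2 * 1.05 - 1)
    sum(band) * tr$dt
  }
  h_far <- hover(0.9 * e0)
  h_near <- hover(0.9999 * e0)
  expect_gt(h_near, 3 * h_far)
})

test_that("sweeps carry metadata and summaries detect shape", {
  sw <- sweep_epsilon(lif10, 2, 10^seq(-2, 0, length.out = 8),
                      metric = "time_ratio")
  expect_s3_class(sw, "sweep_result")
  expect_identical(attr(sw, "metric"), "R_hat")
  sm <- sweep_summary(sw)
  expect_identical(sm$monotonicity, "increasing")
  f <- tempfile(fileext = ".csv"); fj <- tempfile(fileext = ".json")
  write_sweep(sw, f, fj)
  expect_equal(utils::read.csv(f)$value, sw$value)
  expect_identical(jsonlite::read_json(fj)$metric, "R_hat")
})
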