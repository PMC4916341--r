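#!/usr/bin/env Rscript
# The two pulse-count ledgers for periodic synaptic input trains, and the
# ramp model problem that explains the small-interval behavior.
#
# N_delta: pulses needed before the input may cease with the target still
# certain to fire ("input until threshold"). Increasing in the inter-pulse
# interval delta, so by this accounting perfect synchrony is optimal.
#
# M_delta: pulses that arrive before the target actually fires, with the
# train never switched off ("input until firing"). Non-monotone: for rapid
# trains, many pulses land between threshold crossing and the spike and are
# wasted; the count is minimized at an interior, imperfect synchrony.
#
# For delta much smaller than the 3 ms synaptic decay, the drive builds
# linearly and the LIF model problem dv/dt = -v/tau + (c/delta)t predicts
# M ~ sqrt(2/c) delta^(-1/2); the simulated counts follow the same
# square-root blow-up.

library(pulsesync)
dir.create("results", showWarnings = FALSE)

lif <- lif_model(10); theta <- theta_model(0.5); wb <- wb_model()

message("N_delta for the WB neuron, gbar = 1e-3 ...")
swN <- sweep_delta(wb, synaptic_train(1e-3, 1),
                   c(0.05, 0.1, 0.2, 0.4, 0.7, 1, 1.3),
                   metric = "pulses_to_threshold")
write_sweep(swN, "results/n_delta_wb.csv", "results/n_delta_wb_summary.json")
stopifnot(all(diff(swN$value[is.finite(swN$value)]) >= 0))
message(sprintf("  N rises from %d to %d as delta goes 0.05 -> 1.3 ms: synchrony optimal",
                min(swN$value), max(swN$value[is.finite(swN$value)])))

message("M_delta for LIF, theta, WB, gbar = 0.005 ...")
grids <- list(lif = c(0.0125, 0.025, 0.05, 0.1, 0.2, 0.3, 0.45, 0.6),
              theta = c(0.0025, 0.005, 0.01, 0.02, 0.04, 0.08, 0.12),
              wb = c(0.0125, 0.025, 0.05, 0.1, 0.25, 0.5, 1, 2, 4))
models <- list(lif = lif, theta = theta, wb = wb)
for (nm in names(grids)) {
  swM <- sweep_delta(models[[nm]], synaptic_train(0.005, 1), grids[[nm]],
                     metric = "pulses_until_fire")
  write_sweep(swM, sprintf("results/m_delta_%s.csv", nm))
  s <- sweep_summary(swM)
  message(sprintf("  %s: min M = %d at delta = %g ms (%s)",
                  nm, s$min_value, s$min_at, s$monotonicity))
}

message("Square-root blow-up at small delta (LIF, gbar = 0.005) ...")
small <- c(0.0125, 0.025, 0.05)
Ms <- vapply(small, function(d)
  pulses_until_fire(lif, synaptic_train(0.005, d)), numeric(1))
message("  M * sqrt(delta): ", paste(round(Ms * sqrt(small), 2), collapse = ", "),
        "  (approximately constant)")

message("Ramp model problem, tau = 10, c = 0.025 ...")
deltas <- 10^seq(-4, 0, length.out = 21)
ramp <- t(vapply(deltas, function(d) {
  r <- ramp_firing(10, 0.025, d)
  c(delta = d, T_tilde = r$T_tilde, M_tilde = r$M_tilde,
    asymptotic_M = r$asymptotic_M)
}, numeric(4)))
utils::write.csv(as.data.frame(ramp), "results/ramp_m_tilde.csv",
                 row.names = FALSE)
message(sprintf("  M_tilde * sqrt(delta) -> sqrt(2/c) = %.4f (value at delta = 1e-4: %.4f)",
                sqrt(2 / 0.025), ramp[1, "M_tilde"] * sqrt(ramp[1, "delta"])))
message("  the ramp captures the decreasing branch of M_delta, not the large-delta rise")
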