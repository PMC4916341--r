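# shared fixtures: the parameter points used throughout the analyses
lif10 <- lif_model(10)
theta_half <- theta_model(0.5)
wb <- wb_model()
rtm <- rtm_model()

# time-to-blow-up of the undriven QIF voltage from v = q > 1, by separation
# of variables: t = tau * log(q / (q - 1))
qif_blowup_time <- function(tau, q) tau * log(q / (q - 1))

# event-driven jump-decay map for a LIF delta train: v <- v * rho + w at each
# arrival; returns the pulse count to reach 1, or Inf
lif_jump_map_count <- function(tau, w, delta, max_n = 10000) {
  rho <- exp(-delta / tau)
  v <- 0
  for (n in seq_len(max_n)) {
    v <- v * rho + w
    if (v >= 1) return(n)
  }
  Inf
}
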