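---
title: "Does synchrony maximize the downstream effect of excitatory input?"
author: "pulsesync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Does synchrony maximize the downstream effect of excitatory input?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsesync)
```

## The question

Leaky neurons are commonly called *coincidence detectors*: charge injected
over a long window partly leaks away before threshold is reached, so a
synchronous excitatory volley seems strictly more effective than a dispersed
one. `pulsesync` implements the computational machinery to make that claim
precise — and to show that its truth depends entirely on the accounting
convention. If the input may cease the moment the target *crosses threshold*
(i.e., firing becomes inevitable), perfect synchrony is optimal. If the input
keeps flowing until the target *actually fires* — as it does whenever the
input is shut off by feedback from the target, e.g. the E→I interaction in a
gamma rhythm — an interior, imperfect degree of synchrony minimizes the
input spent.

## Target models

Four single-neuron models, all integrated with fixed-step classical
Runge–Kutta (RK4):

* **LIF** — `lif_model(tau)`: \(dv/dt = -v/\tau + I\), threshold fixed at 1,
  reset at 0 (a normalization, not a parameter). Spike time = threshold
  crossing.
* **Theta / QIF** — `theta_model(tau)`: the voltage form
  \(dv/dt = -v(1-v)/\tau + I\) blows up in finite time, so the package
  *always* integrates the phase form
  \(d\theta/dt = -\cos\theta/\tau + 2I(1+\cos\theta)\), with
  \(v = (1+\tan(\theta/2))/2\). Firing = upward crossing of
  \(\theta = \pi\), after which the phase wraps to \(-\pi\) and integration
  continues. Under constant drive the fixed points
  \(v_\pm = 1/2 \pm \sqrt{1/4 - \tau I}\) annihilate in a saddle-node
  bifurcation at \(I = 1/(4\tau)\) (`theta_fixed_points()`).
* **WB** — `wb_model()`: the Wang–Buzsáki fast-firing interneuron
  (\(g_{Na}=35\), \(g_K=9\), \(g_L=0.1\) mS/cm², \(\phi=5\), instantaneous
  sodium activation), in its classical published form.
* **RTM** — `rtm_model()`: the reduced Traub–Miles pyramidal cell
  (\(g_{Na}=100\), \(g_K=80\), \(g_L=0.1\)), likewise the classical form.

For the conductance-based models the spike time is the upward crossing of a
detection level (default 0 mV) and `resting_state()` supplies the zero-drive
equilibrium, found by relaxation followed by a one-dimensional root solve of
the current balance with the gates on their steady-state curves (all three
derivatives vanish below 1e-10).

## Input families: the synthetic-data generator

No external data exist in this problem; the stimulus generator *is* the
study's data source, and its defaults are the study conditions themselves.

* `alpha_pulse(r, epsilon)` — \(I_\epsilon(t) =
  (r/\epsilon)(t/\epsilon)e^{-t/\epsilon}\). The compression factor
  \(\epsilon\) shortens the pulse while preserving its total charge
  \(q = r\) (`total_charge()`); smaller \(\epsilon\) models a more tightly
  synchronized presynaptic volley, and \(\epsilon \to 0\) approaches an
  instantaneous injection \(q\,\delta(t)\).
* `delta_train(w, delta)` — instantaneous voltage jumps \(w\) every
  \(\Delta\) ms, the idealized limit of very fast synapses.
* `synaptic_train(gbar, delta)` — a gating variable s jumps by +1 at
  \(\Delta, 2\Delta, \dots\) (first arrival at \(\Delta\), exactly as the
  train is defined) and decays with the 3 ms time constant of
  AMPA-receptor-mediated synapses; the drive is
  \(\bar g\, s(t)(v_{rev} - v)\) with \(v_{rev} = 5\) for the normalized
  models and 0 mV for the conductance-based ones. s sums many weak synapses
  and is deliberately unbounded. `gating_series()` evaluates s by its
  piecewise closed form (a geometric superposition), never by ODE stepping,
  so the train contributes no discretization error of its own.
* `constant_drive(1/delta)` and `ramp_drive(c, delta)` — the closed-form
  reference problems.

What the generator does *not* emulate: jittered or Poisson arrival times,
conductance noise, stochastic background drive, synaptic depression. Tests
passing under these deterministic, strictly periodic conditions show the
mechanisms — leak-versus-compression, threshold-versus-firing accounting —
but not robustness of the quantitative values to biological variability.

## Efficiency metrics

For pulses: `peak_response()` (\(M_\epsilon\), computed without
threshold/reset for the LIF and with an infinity flag for the theta model
once \(v > 1\), since any excursion above 1 blows up), `critical_epsilon()`
(\(\epsilon_0\), bisection on the spike predicate, relative tolerance 1e-6;
defined only for charge \(q > 1\)), `firing_time()` (\(\hat T_\epsilon\)),
`time_ratio()` (\(\hat R_\epsilon = \hat T_\epsilon/\epsilon\)), and
`charge_to_fire()` (\(\hat Q_\epsilon = \int_0^{\hat R_\epsilon} I(s)\,ds\)
by quadrature of the *unscaled* pulse, equal by substitution to
\(\int_0^{\hat T_\epsilon} I_\epsilon\,dt\) — the equality is a standing
test).

For trains, the two counts that carry the paper-level distinction:
`pulses_to_threshold()` (\(N_\Delta\), smallest k such that k pulses
followed by silence still fire the target) and `pulses_until_fire()`
(\(M_\Delta\), arrivals strictly before the spike with the train running
continuously). \(N_\Delta\) grows with \(\Delta\); \(M_\Delta\) has an
interior minimum, and for \(\Delta\) much shorter than the synaptic decay
both the simulated counts and the ramp model problem
(`ramp_firing()`, solved by bracketed bisection plus Newton polish to
residual < 1e-12) blow up as \(\sqrt{2/c}\,\Delta^{-1/2}\).

## Numerical choices

* **Integrator**: fixed-step RK4, default dt = 0.01 ms. Reproducibility and
  exact event placement matter more here than adaptivity; every run is
  bit-reproducible.
* **Events on the grid**: when a stimulus has an inter-pulse interval, dt is
  shrunk so that \(\Delta\) is an integer number of steps and every arrival
  lands exactly on a step boundary. Pulses much shorter than the default
  step are resolved by refining dt to \(\epsilon/40\).
* **Spike times** are localized by linear interpolation between the
  bracketing grid points (O(dt²) accuracy at fixed cost). After a LIF
  reset the integrator restarts *at the interpolated crossing time* and
  integrates the remainder of the step, so periodic firing accumulates no
  O(dt) phase error per cycle.
* **Spike-free certification**: no fixed horizon is correct near
  \(\epsilon_0\), where the firing time diverges. A run is declared
  spike-free only when >99.999% of the pulse charge has arrived, the state
  is below the relevant unstable level (1 for the LIF, \(v = 1\) i.e.
  \(\theta = \pi/2\) for the theta model, the detection level for WB/RTM),
  and the membrane potential is falling; otherwise the horizon doubles.
  Train runs are certified non-firing by comparing the state at two times
  exactly one period apart.
* **Search structure**: \(\epsilon\)-sweeps use logarithmic grids, and
  minima of \(\hat R_\epsilon\) are refined by golden-section search on the
  log axis, since the ratio spans orders of magnitude. The minimal pulse
  count \(N_\Delta\) is found by bracketing at the first-spike pulse count
  of the untruncated train and binary search downward — the spike predicate
  is monotone in the truncation point, so this is equivalent to incremental
  search from k = 1 at a fraction of the simulations.
* **Counting conventions**: \(M_\Delta\) counts arrivals *strictly* before
  the spike time; an arrival coinciding with the spike is not counted.
  Truncation for \(N_\Delta\) removes later arrivals entirely while the
  already-risen gating variable keeps decaying.

## The network experiment

`simulate_ping()` runs the motivating rhythm: 200 RTM E-cells with constant
drives \(1.5 + j/200\) µA/cm² (a linear gradient), 50 undriven WB I-cells,
all-to-all synapses with per-synapse conductance = population total divided
by the presynaptic count (totals 0.4 E→I, 1 I→E, 0.6 I→I, 0 E→E mS/cm²),
reversal potentials 0/−67 mV, rise/decay constants 0.1/3 ms (excitation) and
0.3/9 ms (inhibition), gating
\(ds/dt = \frac{1+\tanh(v/10)}{2}\frac{1-s}{\tau_R} - s/\tau_D\), and
optionally tonic inhibition \(g_{tonic}(-67 - v)\) on every E-cell. There is
no stochastic element anywhere.

Design choices the problem left open, and how they were fixed:

* **Initial conditions**: all cells start at their zero-drive resting state;
  the drive gradient desynchronizes them and the E–I loop settles into PING.
  The steady-state metrics are insensitive to this choice — staggered and
  warm-started initializations converge to the same attractor.
* **Run length**: 650 ms at dt = 0.01 ms, with the first 150 ms discarded as
  transient and metrics computed on the remaining 500 ms (about 25–35
  volleys). These sizes keep every quantity stable to roughly one cell and
  one Hz under dt halving and horizon doubling.
* **Volley segmentation** (`rhythm_metrics()`): the pooled E-spike train is
  split at gaps longer than half the median inter-volley interval, iterated
  to self-consistency from a quarter-gamma-period seed; edge volleys are
  dropped. Participation is the per-volley count of distinct E-cells
  (averaged, rounded; a warning fires if the per-volley counts are
  unsteady), frequency is the reciprocal mean inter-onset interval, and the
  volley duration is the mean first-to-100th distinct-cell time.
  Participation is defined per volley rather than as a whole-run distinct
  count: a steady rhythm makes the former a single integer, which is the
  natural reading of a per-cycle participation figure.

## Known limitations

* The rhythm metrics of the network experiment are sensitive to how close
  the per-spike inhibitory gating saturation comes to 1, which in turn
  hinges on fine details of the synapse model (the Wang–Buzsáki spike is
  only ~0.6 ms wide, so with \(\tau_R = 0.3\) ms the standard gating reaches
  s ≈ 0.77 rather than 1). The baseline rhythm here runs near 73 Hz with
  ~143 E-cells per volley; an inhibitory gating that saturated fully would
  slow it toward ~62 Hz. Qualitative statements (tonic inhibition slows the
  rhythm, removes participants, and loosens the volleys; frequencies stay in
  the gamma band) are robust across all variants tested.
* The theta-model firing time diverges only slowly as
  \(\epsilon \to \epsilon_0\), and the peak response approaches 1 with
  square-root steepness; assertions near the critical point therefore test
  growth over decades of \(\epsilon_0 - \epsilon\), not the literal limit.
* Deterministic periodic trains only; how noise reshapes the optimal
  synchrony is outside the package's scope.

## Reproducing the study quantities

`scripts/acceptance.R` recomputes, from scratch: the baseline and tonic
network metrics (participation, frequency, first-100-cells volley time) and
the minimal firing-time ratio of a WB neuron under the pulse family built
from \(7te^{-t}\). The numbered scripts under `analysis/` run the full set
of sweeps (peak response and critical compression; firing time, ratio, and
charge; the two pulse counts and the ramp asymptotics; the network
experiment) and write their tables under `results/`.
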