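#' Closed-form results for the LIF neuron
#'
#' Exact expressions used both as results in their own right and as oracles
#' for the simulation code.
#'
#' \code{lif_constant_drive_time}: a LIF neuron driven by the constant input
#' \eqn{1/\Delta} from v = 0 fires iff \eqn{\Delta < \tau}, at time
#' \eqn{T_\Delta = \tau\,\ln\frac{\tau/\Delta}{\tau/\Delta - 1}}.
#'
#' \code{charge_phi}: the charge delivered up to that firing time is
#' \eqn{Q_\Delta = T_\Delta/\Delta = \varphi(\tau/\Delta)} with
#' \eqn{\varphi(s) = s \ln\frac{s}{s-1}}, strictly decreasing on
#' \eqn{(1, \infty)} with \eqn{\varphi \to \infty} as \eqn{s \to 1^+} and
#' \eqn{\varphi \to 1} as \eqn{s \to \infty}. Since \eqn{\varphi} decreases,
#' faster pulse delivery (smaller \eqn{\Delta}) always reduces the charge
#' needed to reach threshold.
#'
#' @param tau membrane time constant (ms)
#' @param delta inter-pulse interval \eqn{\Delta} (ms); the constant drive is
#'   its reciprocal
#' @return \code{lif_constant_drive_time}: the firing time in ms, or
#'   \code{Inf} when no action potential occurs. \code{charge_phi}:
#'   \eqn{\varphi(s)}.
#' @name lif_closed_forms
NULL

#' @rdname lif_closed_forms
#' @export
lif_constant_drive_time <- function(tau, delta) {
  stopifnot(tau > 0, delta > 0)
  s <- tau / delta
  if (s <= 1) return(Inf)
  tau * log(s / (s - 1))
}

#' @rdname lif_closed_forms
#' @param s ratio \eqn{\tau/\Delta}; must exceed 1
#' @export
charge_phi <- function(s) {
  if (any(s <= 1)) stop("charge_phi is defined for s > 1 only")
  s * log(s / (s - 1))
}

#' Threshold crossing of a LIF neuron under a periodic delta train
#'
#' For jumps of size w every \eqn{\Delta} ms (first jump at \eqn{\Delta}),
#' the voltage just after the n-th jump is the geometric sum
#' \eqn{v_n = w(1-\rho^n)/(1-\rho)} with \eqn{\rho = e^{-\Delta/\tau}}. The
#' supremum is \eqn{w/(1-\rho)}, so threshold 1 is reached iff
#' \eqn{w > 1 - e^{-\Delta/\tau}} (strictly: at equality the voltage only
#' approaches 1 in the limit). When it fires, the returned count is the
#' smallest n with \eqn{v_n \ge 1}. This closed form is a derived result,
#' validated in the test suite against event-driven simulation of the
#' jump-decay map.
#'
#' @param tau membrane time constant (ms)
#' @param w jump size, in (0, 1)
#' @param delta inter-pulse interval (ms)
#' @return list with \code{fires} (logical) and \code{n_pulses} (count, or
#'   \code{Inf} when the train never reaches threshold)
#' @export
delta_train_predict <- function(tau, w, delta) {
  stopifnot(tau > 0, delta > 0, w > 0, w < 1)
  rho <- exp(-delta / tau)
  if (w <= 1 - rho) return(list(fires = FALSE, n_pulses = Inf))
  # smallest n with w (1 - rho^n)/(1 - rho) >= 1
  arg <- 1 - (1 - rho) / w
  n <- ceiling(log(arg) / log(rho) - 1e-9)
  list(fires = TRUE, n_pulses = as.numeric(max(1, n)))
}

#' Firing of a LIF neuron under a linearly rising drive
#'
#' Model problem for dense synaptic trains: when the inter-pulse interval
#' \eqn{\Delta} is much shorter than the synaptic decay time, the gating
#' variable builds up nearly linearly, so the drive is approximately the ramp
#' \eqn{(c/\Delta)\,t}. The membrane equation
#' \eqn{dv/dt = -v/\tau + (c/\Delta)t} with v(0) = 0 has the explicit
#' solution \eqn{v(t) = (c/\Delta)(t-\tau)\tau + (c/\Delta)\tau^2 e^{-t/\tau}},
#' and the time \eqn{\tilde T_\Delta} at which v reaches 1 solves
#' \deqn{e^{-\tilde T_\Delta/\tau} - (1 - \tilde T_\Delta/\tau) =
#'   \Delta/(c\tau^2),}
#' which has no closed-form solution. The left side is strictly increasing
#' from 0, so the root is found by bisection (bracket grown from the small-
#' \eqn{\Delta} approximation \eqn{\sqrt{2\Delta/c}}) and polished with
#' Newton steps to residual below 1e-12. The pulse count before threshold is
#' \eqn{\tilde M_\Delta = \tilde T_\Delta/\Delta}, with small-\eqn{\Delta}
#' asymptote \eqn{\tilde M_\Delta \sim \sqrt{2/c}\,\Delta^{-1/2}}: loosening
#' synchrony (larger \eqn{\Delta}) here *reduces* the number of pulses that
#' arrive before threshold.
#'
#' @param tau membrane time constant (ms)
#' @param c ramp scale (1/ms^2)
#' @param delta inter-pulse interval (ms)
#' @return list with \code{T_tilde} (ms), \code{M_tilde} (= T_tilde/delta),
#'   \code{asymptotic_M} (= sqrt(2/(c delta))), and \code{residual} of the
#'   root equation
#' @export
ramp_firing <- function(tau, c, delta) {
  stopifnot(tau > 0, c > 0, delta > 0)
  a <- delta / (c * tau^2)
  f <- function(T) exp(-T / tau) - (1 - T / tau) - a
  # bracket: f is increasing, f(0) = -a < 0
  hi <- sqrt(2 * delta / c) * 10
  for (i in 1:200) {
    if (f(hi) > 0) break
    hi <- hi * 2
  }
  root <- stats::uniroot(f, c(0, hi), tol = .Machine$double.eps)$root
  # Newton polish: f'(T) = (1 - exp(-T/tau))/tau
  for (i in 1:4) {
    fp <- (1 - exp(-root / tau)) / tau
    if (fp <= 0) break
    root <- root - f(root) / fp
  }
  list(T_tilde = root, M_tilde = root / delta,
       asymptotic_M = sqrt(2 / (c * delta)), residual = abs(f(root)))
}
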