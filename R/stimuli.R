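#' Input stimulus families
#'
#' Constructors for the input families used throughout the package: a
#' charge-normalized "alpha" current pulse that can be compressed in time, a
#' periodic train of instantaneous charge injections, a periodic train of
#' exponentially decaying synaptic conductance pulses, a constant drive, and a
#' linearly rising ramp. All times are in ms.
#'
#' @details
#' The alpha pulse is \eqn{I_\epsilon(t) = (r/\epsilon)(t/\epsilon)
#' e^{-t/\epsilon}}: compressing with smaller \eqn{\epsilon} shortens the pulse
#' while preserving its total charge \eqn{q = \int_0^\infty I_\epsilon\,dt = r}.
#' Smaller \eqn{\epsilon} models a more tightly synchronized presynaptic
#' volley. The pulse trains deliver their first pulse at \eqn{t = \Delta}, not
#' at \eqn{t = 0}, and arrive with strict period \eqn{\Delta}.
#'
#' @param r pulse amplitude scale; units 1/ms for the normalized LIF/theta
#'   drive, current density (\eqn{\mu}A/cm\eqn{^2}) for the
#'   conductance-based models
#' @param epsilon compression factor (dimensionless, > 0); 1 leaves the
#'   reference pulse \eqn{r t e^{-t}} unchanged
#' @name stimuli
NULL

#' @rdname stimuli
#' @export
alpha_pulse <- function(r, epsilon = 1) {
  stopifnot(is.numeric(r), length(r) == 1, r > 0,
            is.numeric(epsilon), length(epsilon) == 1, epsilon > 0)
  structure(list(family = "alpha", r = r, epsilon = epsilon),
            class = c("alpha_pulse", "stimulus"))
}

#' @rdname stimuli
#' @param w size of each instantaneous voltage jump (dimensionless for
#'   LIF/theta, mV for the conductance-based models)
#' @param delta inter-pulse interval \eqn{\Delta} (ms, > 0)
#' @param n_pulses number of pulses delivered; \code{Inf} for an unbounded
#'   train
#' @export
delta_train <- function(w, delta, n_pulses = Inf) {
  stopifnot(w > 0, delta > 0, n_pulses >= 1)
  structure(list(family = "delta_train", w = w, delta = delta,
                 n_pulses = n_pulses),
            class = c("delta_train", "stimulus"))
}

#' @rdname stimuli
#' @param gbar maximal conductance of a single weak synapse (mS/cm\eqn{^2}, or
#'   the normalized analogue for LIF/theta targets)
#' @param tau_decay decay time constant of the gating variable (ms); the
#'   default 3 ms mimics AMPA-receptor-mediated synapses
#' @param v_rev synaptic reversal potential. \code{NULL} resolves to the
#'   model-appropriate default at simulation time: 5 for LIF and theta targets
#'   (threshold plus four times the threshold-reset distance), 0 mV for the
#'   conductance-based models.
#' @export
synaptic_train <- function(gbar, delta, tau_decay = 3, v_rev = NULL,
                           n_pulses = Inf) {
  stopifnot(gbar > 0, delta > 0, tau_decay > 0, n_pulses >= 1)
  structure(list(family = "synaptic_train", gbar = gbar, delta = delta,
                 tau_decay = tau_decay, v_rev = v_rev, n_pulses = n_pulses),
            class = c("synaptic_train", "stimulus"))
}

#' @rdname stimuli
#' @param amplitude constant drive value (1/ms); the threshold-crossing
#'   analyses use \code{1/delta}
#' @export
constant_drive <- function(amplitude) {
  stopifnot(amplitude >= 0)
  structure(list(family = "constant", amplitude = amplitude),
            class = c("constant_drive", "stimulus"))
}

#' @rdname stimuli
#' @param c ramp scale (1/ms\eqn{^2}); the drive at time t is \code{(c/delta)*t}
#' @export
ramp_drive <- function(c, delta) {
  stopifnot(c > 0, delta > 0)
  structure(list(family = "ramp", c = c, delta = delta),
            class = c("ramp_drive", "stimulus"))
}

#' @export
print.stimulus <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat("<stimulus:", x$family, "> ",
      paste(names(pars), vapply(pars, format, ""), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Evaluate a compressed alpha pulse
#'
#' Returns \eqn{I_\epsilon(t) = (r/\epsilon)(t/\epsilon)e^{-t/\epsilon}},
#' vectorized over \code{t}. Zero for t <= 0.
#'
#' @param p an [alpha_pulse()]
#' @param t time(s) in ms
#' @return drive values (1/ms)
#' @export
pulse_value <- function(p, t) {
  stopifnot(inherits(p, "alpha_pulse"))
  u <- t / p$epsilon
  ifelse(t <= 0, 0, (p$r / p$epsilon) * u * exp(-u))
}

#' Total charge of an alpha pulse
#'
#' The charge \eqn{q = \int_0^\infty I_\epsilon(t)\,dt} equals \code{r} for
#' every compression factor, since \eqn{\int_0^\infty t e^{-t} dt = 1}. This
#' invariance is what makes \eqn{\epsilon} a pure synchrony parameter.
#'
#' @param p an [alpha_pulse()]
#' @return the dimensionless charge q
#' @export
total_charge <- function(p) {
  stopifnot(inherits(p, "alpha_pulse"))
  p$r
}

#' Synaptic gating variable of a pulse train
#'
#' Evaluates the gating variable s(t) of a [synaptic_train()]: unit upward
#' jumps at \eqn{t = \Delta, 2\Delta, \dots}, each decaying exponentially with
#' the train's decay time constant. Computed from the piecewise closed form
#' (a geometric superposition), not by ODE stepping, so between arrivals it
#' satisfies ds/dt = -s/tau_decay exactly. At an arrival time the returned
#' value is the right-sided limit (jump included). s is a sum over many weak
#' synapses and is not bounded by 1.
#'
#' @param tr a [synaptic_train()]
#' @param t_grid times (ms) at which to evaluate s
#' @return numeric vector of gating values
#' @export
gating_series <- function(tr, t_grid) {
  stopifnot(inherits(tr, "synaptic_train"))
  m <- pmin(floor(t_grid / tr$delta + 1e-9), tr$n_pulses)
  m <- pmax(m, 0)
  rho <- exp(-tr$delta / tr$tau_decay)
  a <- t_grid - m * tr$delta   # time since most recent counted arrival
  s <- exp(-a / tr$tau_decay) * (1 - rho^m) / (1 - rho)
  s[m == 0] <- 0
  s
}

# --- internal plumbing ------------------------------------------------------

.family_code <- c(alpha = 1L, delta_train = 2L, synaptic_train = 3L,
                  constant = 4L, ramp = 5L)

# Full drive list for the C++ integrators. `m` = steps per inter-pulse
# interval; the caller must pass the dt returned by .align_dt().
.drive_list <- function(stim, model, m = 0L) {
  d <- list(family = 0L, r = 0, eps = 1, w = 0, delta = 1, n_pulses = Inf,
            gbar = 0, tau_d = 3, v_rev = 0, amp = 0, c = 0, m = 0L)
  if (is.null(stim)) return(d)
  d$family <- .family_code[[stim$family]]
  switch(stim$family,
    alpha = { d$r <- stim$r; d$eps <- stim$epsilon },
    delta_train = {
      d$w <- stim$w; d$delta <- stim$delta; d$n_pulses <- stim$n_pulses
      d$m <- m
    },
    synaptic_train = {
      d$gbar <- stim$gbar; d$delta <- stim$delta; d$n_pulses <- stim$n_pulses
      d$tau_d <- stim$tau_decay
      d$v_rev <- if (is.null(stim$v_rev)) .default_v_rev(model) else stim$v_rev
      d$m <- m
    },
    constant = { d$amp <- stim$amplitude },
    ramp = { d$c <- stim$c; d$delta <- stim$delta })
  d
}

.default_v_rev <- function(model) {
  if (model$type %in% c("lif", "theta")) 5 else 0
}

# Shrink dt so the inter-pulse interval is an integer number of steps;
# discrete events then land exactly on step boundaries.
.align_dt <- function(stim, dt) {
  if (is.null(stim) || !stim$family %in% c("delta_train", "synaptic_train"))
    return(list(dt = dt, m = 0L))
  m <- max(1L, as.integer(ceiling(stim$delta / dt - 1e-9)))
  list(dt = stim$delta / m, m = m)
}
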