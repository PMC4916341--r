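#' Target neuron models
#'
#' Constructors for the four single-neuron model classes: the linear
#' integrate-and-fire (LIF) neuron, the theta (quadratic integrate-and-fire)
#' neuron, and two conductance-based Hodgkin-Huxley-type models — the
#' Wang-Buzsaki (WB) fast-firing interneuron and the reduced Traub-Miles (RTM)
#' pyramidal cell.
#'
#' @details
#' The LIF membrane potential is normalized so the firing threshold is exactly
#' 1 and the reset is exactly 0; \code{tau} is the membrane time constant in
#' ms. The theta model is the phase form of the QIF neuron,
#' \eqn{d\theta/dt = -\cos\theta/\tau + 2I(1+\cos\theta)}, with membrane
#' potential \eqn{v = (1+\tan(\theta/2))/2}; firing means \eqn{\theta} reaches
#' \eqn{\pi} (equivalently v blows up to \eqn{+\infty}).
#'
#' The WB and RTM models carry the classical published parameter sets
#' (Wang & Buzsaki 1996; Ermentrout & Kopell 1998): spike-generating sodium,
#' delayed-rectifier potassium, and leak currents, with instantaneous sodium
#' activation. Their spike time convention is the upward crossing of
#' \code{spike_detection_level} (default 0 mV).
#'
#' @param tau membrane time constant (ms, > 0)
#' @return an object of class \code{"model_spec"}
#' @name models
NULL

#' @rdname models
#' @export
lif_model <- function(tau) {
  stopifnot(is.numeric(tau), length(tau) == 1, tau > 0)
  structure(list(type = "lif", tau = tau, v_threshold = 1, v_reset = 0),
            class = "model_spec")
}

#' @rdname models
#' @export
theta_model <- function(tau = 0.5) {
  stopifnot(is.numeric(tau), length(tau) == 1, tau > 0)
  structure(list(type = "theta", tau = tau), class = "model_spec")
}

#' @rdname models
#' @param spike_detection_level membrane potential (mV) whose upward crossing
#'   defines the spike time; must lie strictly between the subthreshold range
#'   and the spike peak
#' @export
wb_model <- function(spike_detection_level = 0) {
  structure(list(type = "wb", model_id = 0L,
                 spike_detection_level = spike_detection_level),
            class = "model_spec")
}

#' @rdname models
#' @export
rtm_model <- function(spike_detection_level = 0) {
  structure(list(type = "rtm", model_id = 1L,
                 spike_detection_level = spike_detection_level),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  extra <- switch(x$type,
    lif = paste0("tau = ", x$tau, ", threshold 1, reset 0"),
    theta = paste0("tau = ", x$tau),
    paste0("spike detection at ", x$spike_detection_level, " mV"))
  cat("<model:", x$type, "> ", extra, "\n", sep = "")
  invisible(x)
}

#' Fixed points of the theta/QIF neuron under constant drive
#'
#' For constant drive I the QIF membrane equation
#' \eqn{dv/dt = -v(1-v)/\tau + I} has two fixed points
#' \eqn{v_\pm = 1/2 \pm \sqrt{1/4 - \tau I}} when \eqn{\tau I < 1/4}
#' (\eqn{v_-} stable, \eqn{v_+} unstable). They collide in a saddle-node
#' bifurcation at \eqn{\tau I = 1/4}, above which the neuron fires
#' periodically.
#'
#' @param model a [theta_model()]
#' @param I constant drive (1/ms, >= 0)
#' @return named vector \code{c(v_minus, v_plus)}, the degenerate pair
#'   \code{c(0.5, 0.5)} exactly at the bifurcation, or \code{NULL} when no
#'   fixed points exist
#' @export
theta_fixed_points <- function(model, I) {
  stopifnot(model$type == "theta", I >= 0)
  disc <- 0.25 - model$tau * I
  if (disc < 0) return(NULL)
  s <- sqrt(disc)
  c(v_minus = 0.5 - s, v_plus = 0.5 + s)
}

#' Zero-drive resting state of a conductance-based model
#'
#' Finds the equilibrium (v, h, n) with no external drive: the gating
#' variables are at their voltage-dependent steady states and the membrane
#' current balance vanishes. Located by relaxing the dynamics for a few
#' hundred ms and then polishing the voltage with a one-dimensional root
#' solve of the current balance (with h and n eliminated through their
#' steady-state curves). All three time derivatives vanish to within 1e-10 at
#' the returned state.
#'
#' @param model a [wb_model()] or [rtm_model()]
#' @param tol acceptable residual on the state derivatives
#' @return named numeric vector \code{c(v, h, n)}
#' @export
resting_state <- function(model, tol = 1e-10) {
  stopifnot(model$type %in% c("wb", "rtm"))
  id <- model$model_id
  # relax toward the equilibrium to get a bracket
  relax <- sim_hh_cpp(id, .drive_list(NULL, model), t_end = 300, dt = 0.05,
                      init = hh_inf_state_cpp(id, -70),
                      detect = model$spike_detection_level, record = FALSE)
  v0 <- relax$v_end
  lo <- v0 - 5; hi <- v0 + 5
  flo <- hh_rest_residual_cpp(id, lo); fhi <- hh_rest_residual_cpp(id, hi)
  for (i in 1:20) {
    if (sign(flo) != sign(fhi)) break
    lo <- lo - 5; hi <- hi + 5
    flo <- hh_rest_residual_cpp(id, lo); fhi <- hh_rest_residual_cpp(id, hi)
  }
  if (sign(flo) == sign(fhi))
    stop("resting_state: failed to bracket the current-balance root")
  root <- stats::uniroot(function(v) hh_rest_residual_cpp(id, v), c(lo, hi),
                         tol = .Machine$double.eps^0.75)
  st <- hh_inf_state_cpp(id, root$root)
  dv <- hh_deriv_cpp(id, st, 0)
  if (max(abs(dv)) > tol)
    stop("resting_state: failed to converge (max |derivative| = ",
         format(max(abs(dv))), ")")
  st
}
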