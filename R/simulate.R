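#' Simulate a single target neuron
#'
#' Fixed-step classical RK4 integration of one neuron driven by one stimulus,
#' with spike times localized by linear interpolation between the bracketing
#' grid points. Discrete events (instantaneous charge injections, synaptic
#' arrivals) are applied exactly at step boundaries; when a stimulus carries an
#' inter-pulse interval, dt is shrunk so the interval is an integer number of
#' steps.
#'
#' \code{simulate_lif} integrates \eqn{dv/dt = -v/\tau + I(t)} plus any
#' synaptic conductance term, with threshold 1 and reset 0 (set
#' \code{reset = FALSE} to track the free membrane response of the
#' threshold-less equation). \code{simulate_theta} integrates the phase
#' equation — never the voltage form, which blows up in finite time; a spike
#' is an upward crossing of \eqn{\theta = \pi}, after which the phase wraps to
#' \eqn{-\pi} and integration continues. \code{simulate_hh} integrates a
#' conductance-based model from a full (v, h, n) state; spikes are upward
#' crossings of the model's detection level and the state is not reset.
#'
#' @param model a \code{model_spec} from [lif_model()], [theta_model()],
#'   [wb_model()] or [rtm_model()]
#' @param drive a stimulus object (see [alpha_pulse()] and friends), or
#'   \code{NULL} for no drive
#' @param t_end simulation length (ms)
#' @param dt requested step (ms); may be reduced for event alignment
#' @param v0,theta0,init initial state (LIF voltage, theta phase, HH state
#'   vector c(v, h, n); HH default is the zero-drive resting state)
#' @param reset LIF only: apply the threshold/reset rule
#' @return a \code{neuron_trace}: list with \code{times}, \code{states}
#'   (matrix, one column per state variable), \code{spike_times},
#'   \code{blew_up} (theta only), \code{dt}, plus the model and stimulus
#' @name simulate
NULL

#' @rdname simulate
#' @export
simulate_lif <- function(model, drive, t_end, dt = 0.01, v0 = 0, reset = TRUE) {
  stopifnot(model$type == "lif", t_end > 0, dt > 0, v0 < 1)
  al <- .align_dt(drive, dt)
  raw <- sim_lif_cpp(model$tau, .drive_list(drive, model, al$m), t_end, al$dt,
                     v0, reset, record = TRUE)
  .trace(times = raw$times, states = cbind(v = raw$v),
         spike_times = raw$spike_times, blew_up = FALSE, dt = al$dt,
         model = model, stimulus = drive)
}

#' @rdname simulate
#' @export
simulate_theta <- function(model, drive, t_end, dt = 0.01, theta0 = -pi / 2) {
  stopifnot(model$type == "theta", t_end > 0, dt > 0,
            theta0 > -pi, theta0 < pi)
  al <- .align_dt(drive, dt)
  raw <- sim_theta_cpp(model$tau, .drive_list(drive, model, al$m), t_end,
                       al$dt, theta0, record = TRUE)
  v <- .theta_to_v(raw$theta)
  .trace(times = raw$times, states = cbind(theta = raw$theta, v = v),
         spike_times = raw$spike_times, blew_up = raw$blew_up, dt = al$dt,
         model = model, stimulus = drive)
}

#' @rdname simulate
#' @export
simulate_hh <- function(model, drive, t_end, dt = 0.01, init = NULL) {
  stopifnot(model$type %in% c("wb", "rtm"), t_end > 0, dt > 0)
  if (is.null(init)) init <- resting_state(model)
  stopifnot(length(init) == 3)
  al <- .align_dt(drive, dt)
  raw <- sim_hh_cpp(model$model_id, .drive_list(drive, model, al$m), t_end,
                    al$dt, init, model$spike_detection_level, record = TRUE)
  .trace(times = raw$times, states = cbind(v = raw$v, h = raw$h, n = raw$n),
         spike_times = raw$spike_times, blew_up = FALSE, dt = al$dt,
         model = model, stimulus = drive)
}

#' @rdname simulate
#' @export
simulate_neuron <- function(model, drive, t_end, dt = 0.01, ...) {
  switch(model$type,
    lif = simulate_lif(model, drive, t_end, dt, ...),
    theta = simulate_theta(model, drive, t_end, dt, ...),
    simulate_hh(model, drive, t_end, dt, ...))
}

.trace <- function(times, states, spike_times, blew_up, dt, model, stimulus) {
  structure(list(times = times, states = states, spike_times = spike_times,
                 blew_up = blew_up, dt = dt, model = model,
                 stimulus = stimulus),
            class = "neuron_trace")
}

# v = (1 + tan(theta/2))/2, +/-Inf near the wrap point
.theta_to_v <- function(theta) {
  v <- 0.5 * (1 + tan(theta / 2))
  v[abs(abs(theta) - pi) < 1e-12] <- Inf
  v
}

#' @export
print.neuron_trace <- function(x, ...) {
  cat("<neuron_trace> model ", x$model$type, ", ",
      length(x$times), " samples over ", format(max(x$times)), " ms, ",
      length(x$spike_times), " spike(s)",
      if (isTRUE(x$blew_up)) " [blow-up]", "\n", sep = "")
  if (length(x$spike_times))
    cat("  spike times (ms):",
        paste(format(utils::head(x$spike_times, 8), digits = 6),
              collapse = ", "),
        if (length(x$spike_times) > 8) "...", "\n")
  invisible(x)
}

#' @export
as.data.frame.neuron_trace <- function(x, ...) {
  data.frame(time_ms = x$times, x$states, check.names = FALSE)
}

#' Export a trace as tidy CSV
#'
#' Writes the trajectory (column \code{time_ms} plus one column per state
#' variable) and, optionally, the spike times as a separate single-column CSV.
#'
#' @param trace a \code{neuron_trace}
#' @param path output CSV path for the trajectory
#' @param spikes_path optional path for the spike-time CSV
#' @return \code{path}, invisibly
#' @export
write_trace <- function(trace, path, spikes_path = NULL) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  if (!is.null(spikes_path))
    utils::write.csv(data.frame(spike_time_ms = trace$spike_times),
                     spikes_path, row.names = FALSE)
  invisible(path)
}

# --- internal fast simulation (no trajectory storage) -----------------------

# Returns the raw C++ result; init: LIF v0 / theta theta0 / HH c(v,h,n).
.sim_raw <- function(model, stim, t_end, dt, init = NULL, reset = TRUE,
                     record = FALSE) {
  al <- .align_dt(stim, dt)
  dl <- .drive_list(stim, model, al$m)
  switch(model$type,
    lif = sim_lif_cpp(model$tau, dl, t_end, al$dt,
                      if (is.null(init)) 0 else init, reset, record),
    theta = sim_theta_cpp(model$tau, dl, t_end, al$dt,
                          if (is.null(init)) -pi / 2 else init, record),
    sim_hh_cpp(model$model_id, dl, t_end, al$dt,
               if (is.null(init)) resting_state(model) else init,
               model$spike_detection_level, record))
}
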