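#' Efficiency metrics for pulse-driven firing
#'
#' The central quantities of the package. For a target neuron driven by the
#' compressed pulse family \eqn{I_\epsilon}:
#' \describe{
#'   \item{\code{peak_response} (\eqn{M_\epsilon})}{the maximum of the free
#'     membrane response (LIF without threshold/reset; theta with an
#'     infinity flag once v exceeds 1, since any excursion above 1 blows up).}
#'   \item{\code{critical_epsilon} (\eqn{\epsilon_0})}{the largest compression
#'     at which the pulse still elicits a spike; exists iff the pulse charge
#'     q exceeds 1.}
#'   \item{\code{firing_time} (\eqn{\hat T_\epsilon})}{the time of the first
#'     spike, or \code{Inf} if the pulse never elicits one.}
#'   \item{\code{time_ratio} (\eqn{\hat R_\epsilon = \hat T_\epsilon/\epsilon})}{
#'     firing time relative to input duration; \eqn{\hat R_\epsilon \gg 1}
#'     means the input is essentially over long before the target fires.}
#'   \item{\code{charge_to_fire} (\eqn{\hat Q_\epsilon})}{the charge delivered
#'     up to the moment the target actually fires,
#'     \eqn{\int_0^{\hat R_\epsilon} I(s)\,ds} with the *unscaled* pulse —
#'     equal, by substitution, to \eqn{\int_0^{\hat T_\epsilon}
#'     I_\epsilon(t)\,dt}.}
#' }
#'
#' A simulation is declared spike-free only when more than 99.999 percent of
#' the pulse charge has arrived, the state is below the relevant unstable
#' level (1 for LIF, v = 1 i.e. \eqn{\theta = \pi/2} for theta, the detection
#' level for the conductance-based models), and the membrane potential is
#' falling; otherwise the horizon is doubled. No fixed horizon is correct
#' near \eqn{\epsilon_0}, where the firing time diverges.
#'
#' @param model a \code{model_spec}
#' @param pulse an [alpha_pulse()]
#' @param dt integration step (ms); automatically refined to resolve pulses
#'   much shorter than the step
#' @name efficiency_metrics
NULL

# resolve very short pulses on the grid
.pulse_dt <- function(pulse, dt) min(dt, pulse$epsilon / 40)

# cached zero-drive resting states
.rest_cache <- new.env(parent = emptyenv())
.rest_of <- function(model) {
  key <- paste0(model$type, "@", model$spike_detection_level)
  if (is.null(.rest_cache[[key]]))
    .rest_cache[[key]] <- resting_state(model)
  .rest_cache[[key]]
}

.init_for <- function(model) {
  switch(model$type, lif = 0, theta = -pi / 2, .rest_of(model))
}

.state_below_unstable <- function(model, raw) {
  switch(model$type,
    lif = raw$v_end < 1,
    theta = raw$theta_end < pi / 2,
    raw$v_end < model$spike_detection_level)
}

.state_falling <- function(model, raw) {
  if (model$type == "theta") raw$theta_end <= raw$theta_prev
  else raw$v_end <= raw$v_prev
}

# Decide spike / certified no-spike for a single alpha pulse, doubling the
# horizon until the outcome is certain.
.pulse_spike_decision <- function(model, pulse, dt) {
  dtu <- .pulse_dt(pulse, dt)
  init <- .init_for(model)
  t_end <- max(30 * pulse$epsilon, 20)
  repeat {
    raw <- .sim_raw(model, pulse, t_end, dtu, init = init, reset = TRUE)
    if (length(raw$spike_times))
      return(list(spiked = TRUE, t_spike = raw$spike_times[1]))
    charge_done <- t_end > 28 * pulse$epsilon   # (1+x)e^-x < 1e-10 at x = 28
    settled <- .state_falling(model, raw) || t_end > 30 * pulse$epsilon + 500
    if (charge_done && .state_below_unstable(model, raw) && settled)
      return(list(spiked = FALSE, t_spike = Inf))
    t_end <- t_end * 2
    if (t_end > 1e7)
      stop("spike/no-spike decision did not resolve by t = 1e7 ms")
  }
}

#' @rdname efficiency_metrics
#' @return \code{peak_response}: the peak \eqn{M_\epsilon} (possibly
#'   \code{Inf} for the theta model)
#' @export
peak_response <- function(model, pulse, dt = 0.01) {
  stopifnot(model$type %in% c("lif", "theta"), inherits(pulse, "alpha_pulse"))
  dtu <- .pulse_dt(pulse, dt)
  t_end <- max(30 * pulse$epsilon, 10 * if (model$type == "lif") model$tau else 1)
  repeat {
    raw <- .sim_raw(model, pulse, t_end, dtu, reset = FALSE)
    if (model$type == "theta" && (raw$blew_up || raw$theta_max > pi / 2))
      return(Inf)
    if (t_end > 28 * pulse$epsilon && .state_falling(model, raw))
      return(if (model$type == "lif") raw$v_max
             else .theta_to_v(raw$theta_max))
    t_end <- t_end * 2
    if (t_end > 1e7) stop("peak search did not settle by t = 1e7 ms")
  }
}

#' @rdname efficiency_metrics
#' @param rel_tol relative tolerance on the returned critical compression
#' @return \code{critical_epsilon}: the critical compression
#'   \eqn{\epsilon_0 > 0}
#' @export
critical_epsilon <- function(model, pulse, rel_tol = 1e-6, dt = 0.01) {
  stopifnot(model$type %in% c("lif", "theta"), inherits(pulse, "alpha_pulse"))
  if (total_charge(pulse) <= 1)
    stop("no critical epsilon exists: the pulse charge q = ",
         total_charge(pulse), " does not exceed 1")
  fires <- function(eps)
    .pulse_spike_decision(model, alpha_pulse(pulse$r, eps), dt)$spiked

  e <- pulse$epsilon
  if (fires(e)) {
    lo <- e
    repeat {
      e <- e * 2
      if (!fires(e)) { hi <- e; break }
      lo <- e
      if (e > 1e8) stop("failed to bracket epsilon_0 from below")
    }
  } else {
    hi <- e
    repeat {
      e <- e / 2
      if (fires(e)) { lo <- e; break }
      hi <- e
      if (e < 1e-10) stop("failed to bracket epsilon_0 from above")
    }
  }
  while (hi - lo > rel_tol * lo) {
    mid <- sqrt(lo * hi)
    if (fires(mid)) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' @rdname efficiency_metrics
#' @return \code{firing_time}: first spike time in ms, or \code{Inf}
#' @export
firing_time <- function(model, pulse, dt = 0.01) {
  stopifnot(inherits(pulse, "alpha_pulse"))
  .pulse_spike_decision(model, pulse, dt)$t_spike
}

#' @rdname efficiency_metrics
#' @return \code{time_ratio}: \eqn{\hat R_\epsilon} (\code{Inf} propagates)
#' @export
time_ratio <- function(model, pulse, dt = 0.01) {
  firing_time(model, pulse, dt) / pulse$epsilon
}

#' @rdname efficiency_metrics
#' @return \code{charge_to_fire}: \eqn{\hat Q_\epsilon}
#' @export
charge_to_fire <- function(model, pulse, dt = 0.01) {
  Tf <- firing_time(model, pulse, dt)
  if (!is.finite(Tf))
    stop("charge_to_fire: the pulse does not elicit a spike")
  .charge_up_to(pulse$r, Tf / pulse$epsilon)
}

# integral of the unscaled pulse r s e^-s over [0, R], by quadrature
.charge_up_to <- function(r, R) {
  upper <- min(R, 80)   # tail beyond 80 is below 1e-30
  stats::integrate(function(s) r * s * exp(-s), 0, upper,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# --- pulse-train counts -----------------------------------------------------

# First spike time under the full (untruncated) train, with horizon doubling.
# Never-fires is certified by comparing the state at two times one period
# apart: once the pulse-to-pulse map has converged and no spike occurred, the
# drive is subthreshold-periodic and can never fire.
.train_first_spike <- function(model, train, dt) {
  stopifnot(train$family %in% c("delta_train", "synaptic_train"))
  init <- .init_for(model)
  d <- train$delta
  t_end <- d * max(64, ceiling(200 / d))
  repeat {
    raw <- .sim_raw(model, train, t_end, dt, init = init, reset = TRUE)
    if (length(raw$spike_times))
      return(list(t_spike = raw$spike_times[1], t_end = t_end))
    raw2 <- .sim_raw(model, train, t_end - d, dt, init = init, reset = TRUE)
    x1 <- if (model$type == "theta") raw$theta_end else raw$v_end
    x2 <- if (model$type == "theta") raw2$theta_end else raw2$v_end
    if (abs(x1 - x2) < 1e-9 && t_end > 20 * d + 100)
      return(list(t_spike = Inf, t_end = t_end))
    t_end <- t_end * 2
    if (t_end > 2e5) {
      warning("train did not fire or settle by t = 2e5 ms; treating as non-firing")
      return(list(t_spike = Inf, t_end = t_end))
    }
  }
}

# Does delivering exactly k pulses (then nothing) still produce a spike?
.truncated_fires <- function(model, train, k, dt) {
  tr <- train
  tr$n_pulses <- k
  tau_d <- if (train$family == "synaptic_train") train$tau_decay else 0
  settle <- max(tau_d * (log(k + 1) + 25), 50)
  t_end <- k * train$delta + settle
  repeat {
    raw <- .sim_raw(model, tr, t_end, dt, init = .init_for(model), reset = TRUE)
    if (length(raw$spike_times)) return(TRUE)
    if (.state_below_unstable(model, raw) &&
        (.state_falling(model, raw) || settle > 2000))
      return(FALSE)
    settle <- settle * 2
    t_end <- k * train$delta + settle
    if (settle > 1e6) stop("truncated-train decision did not resolve")
  }
}

#' Pulse counts: input needed to reach threshold vs. input until firing
#'
#' Two distinct counts for a periodic input train driving a target neuron
#' from rest, and the heart of the distinction the package is about:
#'
#' \code{pulses_to_threshold} (\eqn{N_\Delta}) is the smallest number k of
#' pulses such that, if the train stops after pulse k, the target still goes
#' on to fire — the input is allowed the "foresight" of ceasing as soon as
#' firing is inevitable. Truncation removes later arrivals entirely; an
#' already-risen gating variable keeps decaying. \eqn{N_\Delta} grows with
#' \eqn{\Delta}, so by this ledger perfect synchrony is optimal.
#'
#' \code{pulses_until_fire} (\eqn{M_\Delta}) is the number of pulses that
#' have arrived, with the train running continuously, strictly before the
#' moment the target actually fires (an arrival coinciding exactly with the
#' spike time is not counted). \eqn{M_\Delta} is non-monotone in
#' \eqn{\Delta}: for rapid trains many pulses land in the interval between
#' threshold crossing and the actual spike and are wasted, so an interior,
#' imperfect degree of synchrony minimizes the count.
#'
#' The never-fires case returns \code{Inf}. The minimal k is located by
#' bracketing (any k at or past the first-spike pulse count suffices) and
#' binary search, since the spike predicate is monotone in k.
#'
#' @param model a \code{model_spec}
#' @param train a [delta_train()] or [synaptic_train()]
#' @param dt integration step (ms); reduced internally so the inter-pulse
#'   interval is resolved by at least four steps
#' @return a count, or \code{Inf}
#' @name pulse_counts
NULL

#' @rdname pulse_counts
#' @export
pulses_to_threshold <- function(model, train, dt = 0.01) {
  dtu <- min(dt, train$delta / 4)
  first <- .train_first_spike(model, train, dtu)
  if (!is.finite(first$t_spike)) return(Inf)
  hi <- max(1, ceiling(first$t_spike / train$delta + 1e-9))
  if (hi == 1) return(1)
  lo <- 0   # 0 pulses certainly does not fire
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (.truncated_fires(model, train, mid, dtu)) hi <- mid else lo <- mid
  }
  hi
}

#' @rdname pulse_counts
#' @export
pulses_until_fire <- function(model, train, dt = 0.01) {
  dtu <- min(dt, train$delta / 4)
  first <- .train_first_spike(model, train, dtu)
  if (!is.finite(first$t_spike)) return(Inf)
  floor((first$t_spike - 1e-9) / train$delta)
}

# --- parameter sweeps -------------------------------------------------------

#' Sweep a metric over the compression factor or the inter-pulse interval
#'
#' \code{sweep_epsilon} evaluates one of the pulse metrics over an ordered
#' grid of compression factors; \code{sweep_delta} evaluates one of the pulse
#' counts over a grid of inter-pulse intervals, rebuilding the template train
#' at each value. Grids for \eqn{\epsilon} are typically logarithmic, since
#' the metrics span orders of magnitude.
#'
#' @param model a \code{model_spec}
#' @param r alpha-pulse amplitude (charge q = r)
#' @param epsilon,deltas strictly increasing grid of swept values
#' @param metric which quantity to compute
#' @param template a train whose \code{delta} is replaced at each grid value
#' @param dt integration step (ms)
#' @return a \code{sweep_result} data frame: swept value, \code{value}, and a
#'   \code{fired} flag; non-firing points carry \code{Inf} (counts, firing
#'   time, ratio) or \code{NA} (charge)
#' @export
sweep_epsilon <- function(model, r, epsilon,
                          metric = c("peak", "firing_time", "time_ratio",
                                     "charge"),
                          dt = 0.01) {
  metric <- match.arg(metric)
  stopifnot(all(diff(epsilon) > 0))
  vals <- numeric(length(epsilon))
  fired <- logical(length(epsilon))
  for (i in seq_along(epsilon)) {
    p <- alpha_pulse(r, epsilon[i])
    if (metric == "peak") {
      vals[i] <- peak_response(model, p, dt)
      fired[i] <- vals[i] >= 1
    } else {
      Tf <- firing_time(model, p, dt)
      fired[i] <- is.finite(Tf)
      vals[i] <- switch(metric,
        firing_time = Tf,
        time_ratio = Tf / epsilon[i],
        charge = if (is.finite(Tf)) .charge_up_to(r, Tf / epsilon[i]) else NA_real_)
    }
  }
  out <- data.frame(epsilon = epsilon, value = vals, fired = fired)
  class(out) <- c("sweep_result", "data.frame")
  attr(out, "swept") <- "epsilon"
  attr(out, "metric") <- c(peak = "M_eps", firing_time = "T_hat",
                           time_ratio = "R_hat", charge = "Q_hat")[[metric]]
  attr(out, "model") <- model$type
  out
}

#' @rdname sweep_epsilon
#' @export
sweep_delta <- function(model, template, deltas,
                        metric = c("pulses_to_threshold", "pulses_until_fire"),
                        dt = 0.01) {
  metric <- match.arg(metric)
  stopifnot(all(diff(deltas) > 0),
            template$family %in% c("delta_train", "synaptic_train"))
  f <- if (metric == "pulses_to_threshold") pulses_to_threshold
       else pulses_until_fire
  vals <- vapply(deltas, function(d) {
    tr <- template
    tr$delta <- d
    f(model, tr, dt)
  }, numeric(1))
  out <- data.frame(delta = deltas, value = vals, fired = is.finite(vals))
  class(out) <- c("sweep_result", "data.frame")
  attr(out, "swept") <- "delta"
  attr(out, "metric") <- c(pulses_to_threshold = "N_delta",
                           pulses_until_fire = "M_delta")[[metric]]
  attr(out, "model") <- model$type
  out
}

#' Locate the minimum of the firing-time ratio over compression
#'
#' Scans \eqn{\hat R_\epsilon = \hat T_\epsilon/\epsilon} on a logarithmic
#' grid, finds the firing window, and refines the interior minimum by
#' golden-section search on the log axis. For strong pulses into a
#' conductance-based neuron the firing window has both a lower and an upper
#' edge, with \eqn{\hat R_\epsilon \to \infty} at the upper edge.
#'
#' @param model a \code{model_spec}
#' @param r alpha-pulse amplitude
#' @param eps_range search interval for the compression factor
#' @param n_grid points in the initial logarithmic scan
#' @param tol absolute tolerance on log(epsilon) at the minimum
#' @param dt integration step (ms)
#' @return list with \code{epsilon} (argmin), \code{value} (min
#'   \eqn{\hat R_\epsilon}), and the scan as \code{sweep}
#' @export
min_time_ratio <- function(model, r, eps_range = c(1e-2, 1e2), n_grid = 36,
                           tol = 1e-3, dt = 0.01) {
  grid <- exp(seq(log(eps_range[1]), log(eps_range[2]), length.out = n_grid))
  sw <- sweep_epsilon(model, r, grid, metric = "time_ratio", dt = dt)
  finite <- which(is.finite(sw$value))
  if (!length(finite))
    stop("no epsilon in the range elicits a spike; widen eps_range or raise r")
  i <- finite[which.min(sw$value[finite])]
  lo <- log(grid[max(i - 1, 1)])
  hi <- log(grid[min(i + 1, n_grid)])
  Rhat <- function(x) time_ratio(model, alpha_pulse(r, exp(x)), dt)

  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- Rhat(x1); f2 <- Rhat(x2)
  while (hi - lo > tol) {
    if (f1 <= f2) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- Rhat(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- Rhat(x2)
    }
  }
  xm <- if (f1 <= f2) x1 else x2
  list(epsilon = exp(xm), value = min(f1, f2), sweep = sw)
}

#' Summarize a sweep
#'
#' Reports the location and value of the (finite) minimum and a monotonicity
#' verdict over the fired portion of the grid.
#'
#' @param sw a \code{sweep_result}
#' @param tol slack used when classifying monotonicity
#' @return a list suitable for JSON export
#' @export
sweep_summary <- function(sw, tol = 1e-9) {
  v <- sw$value
  x <- sw[[attr(sw, "swept")]]
  ok <- is.finite(v)
  verdict <- if (sum(ok) < 3) "undetermined" else {
    d <- diff(v[ok])
    if (all(d > -tol)) "increasing"
    else if (all(d < tol)) "decreasing"
    else "non-monotone"
  }
  list(metric = attr(sw, "metric"), swept = attr(sw, "swept"),
       model = attr(sw, "model"),
       min_at = if (any(ok)) x[ok][which.min(v[ok])] else NA,
       min_value = if (any(ok)) min(v[ok]) else NA,
       monotonicity = verdict, n_points = nrow(sw), n_fired = sum(sw$fired))
}

#' Write a sweep to CSV, with an optional JSON summary
#'
#' @param sw a \code{sweep_result}
#' @param csv_path output CSV path
#' @param json_path optional path for the [sweep_summary()] JSON
#' @return \code{csv_path}, invisibly
#' @export
write_sweep <- function(sw, csv_path, json_path = NULL) {
  utils::write.csv(as.data.frame(sw), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(sweep_summary(sw), json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(csv_path)
}
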