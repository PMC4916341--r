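#' Configuration of the E-I gamma (PING) network
#'
#' The motivating network experiment: 200 RTM pyramidal cells (E-cells) and 50
#' WB interneurons (I-cells), all-to-all coupled, no gap junctions, no
#' stochastic drive. The j-th E-cell receives constant drive
#' \eqn{1.5 + j/200\ \mu}A/cm\eqn{^2} (a linear gradient), the I-cells receive
#' none and fire only in response to the E-cells. Synapses are
#' conductance-based with per-presynaptic-cell gating variables
#' \eqn{ds/dt = \frac{1+\tanh(v/10)}{2}\,\frac{1-s}{\tau_R} - s/\tau_D};
#' the per-synapse conductance is the population total divided by the number
#' of presynaptic cells. Optionally a tonic (constant-conductance) inhibition
#' term \code{g_tonic * (-67 - v)} is added to every E-cell.
#'
#' @param g_tonic tonic inhibitory conductance on the E-cells (mS/cm^2); 0
#'   for the baseline rhythm, 0.2 for the slowed one
#' @param t_end simulated time (ms)
#' @param dt integration step (ms)
#' @param transient initial interval discarded before computing rhythm
#'   metrics (ms)
#' @param n_e,n_i population sizes
#' @param g_ei,g_ie,g_ii,g_ee total synaptic conductances (mS/cm^2): E-to-I,
#'   I-to-E, I-to-I, E-to-E
#' @param v_rev_e,v_rev_i synaptic reversal potentials (mV)
#' @param tau_r_e,tau_d_e,tau_r_i,tau_d_i synaptic rise/decay time constants
#'   (ms) of the excitatory and inhibitory synapses
#' @param drive_i external drive to the I-cells (\eqn{\mu}A/cm\eqn{^2})
#' @param detect spike-detection level (mV)
#' @return a \code{ping_config} list
#' @export
ping_config <- function(g_tonic = 0, t_end = 650, dt = 0.01, transient = 150,
                        n_e = 200, n_i = 50,
                        g_ei = 0.4, g_ie = 1, g_ii = 0.6, g_ee = 0,
                        v_rev_e = 0, v_rev_i = -67,
                        tau_r_e = 0.1, tau_d_e = 3,
                        tau_r_i = 0.3, tau_d_i = 9,
                        drive_i = 0, detect = 0) {
  stopifnot(g_ei >= 0, g_ie >= 0, g_ii >= 0, g_ee >= 0, g_tonic >= 0,
            t_end > transient, dt > 0)
  structure(list(
    n_e = n_e, n_i = n_i,
    drive_e = 1.5 + seq_len(n_e) / 200, drive_i = drive_i,
    g_ei = g_ei, g_ie = g_ie, g_ii = g_ii, g_ee = g_ee,
    v_rev_e = v_rev_e, v_rev_i = v_rev_i,
    tau_r_e = tau_r_e, tau_d_e = tau_d_e,
    tau_r_i = tau_r_i, tau_d_i = tau_d_i,
    g_tonic = g_tonic, v_tonic = -67,
    t_end = t_end, dt = dt, transient = transient, detect = detect),
    class = "ping_config")
}

#' Simulate the PING network
#'
#' Integrates the full coupled system (four state variables per cell) with
#' fixed-step RK4 from the zero-drive resting state of every cell; the drive
#' gradient desynchronizes the E-cells, after which the E-I loop settles into
#' a pyramidal-interneuronal gamma rhythm. The run is fully deterministic.
#'
#' @param cfg a [ping_config()]
#' @return a \code{spike_raster} data frame with columns \code{cell} and
#'   \code{time} (ms). Cells follow the raster labeling convention: I-cells
#'   are 1..n_i, the j-th E-cell is n_i + j, so larger labels received larger
#'   drive.
#' @export
simulate_ping <- function(cfg) {
  stopifnot(inherits(cfg, "ping_config"))
  rest_e <- resting_state(rtm_model(cfg$detect))
  rest_i <- resting_state(wb_model(cfg$detect))
  init_e <- matrix(rest_e, cfg$n_e, 3, byrow = TRUE)
  init_i <- matrix(rest_i, cfg$n_i, 3, byrow = TRUE)
  raw <- sim_ping_cpp(cfg$n_e, cfg$n_i, cfg$drive_e, cfg$drive_i,
                      cfg$g_ei, cfg$g_ie, cfg$g_ii, cfg$g_ee,
                      cfg$v_rev_e, cfg$v_rev_i,
                      cfg$tau_r_e, cfg$tau_d_e, cfg$tau_r_i, cfg$tau_d_i,
                      cfg$g_tonic, cfg$v_tonic, cfg$t_end, cfg$dt,
                      cfg$detect, init_e, init_i)
  out <- data.frame(cell = raw$cell, time = raw$time)
  out <- out[order(out$cell, out$time), ]
  rownames(out) <- NULL
  class(out) <- c("spike_raster", "data.frame")
  attr(out, "config") <- cfg
  out
}

#' Export a spike raster as CSV
#'
#' Columns \code{cell_id} (I-cells 1..n_i, E-cells n_i+1..n_i+n_e) and
#' \code{spike_time_ms}.
#'
#' @param raster a \code{spike_raster}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_raster <- function(raster, path) {
  utils::write.csv(data.frame(cell_id = raster$cell,
                              spike_time_ms = raster$time),
                   path, row.names = FALSE)
  invisible(path)
}

#' Rhythm metrics of a PING raster
#'
#' Segments the pooled E-cell spike train into volleys and reports, in steady
#' state: the number of distinct E-cells participating per volley, the rhythm
#' frequency, and the time it takes the first \code{k} distinct E-cells to
#' fire within a volley.
#'
#' Volleys are separated at gaps in the pooled E-spike train longer than half
#' the median inter-volley interval; the threshold is iterated to convergence
#' from a quarter-gamma-period seed. The first and last volleys of the
#' analysis window are dropped (either may be truncated by the window).
#' Participation is the per-volley count of distinct E-cells, averaged and
#' rounded to the nearest integer; the per-volley counts are expected to be
#' steady (variance of about one cell or less — a warning is issued
#' otherwise). Frequency is 1000 divided by the mean interval (ms) between
#' consecutive volley onsets. The volley duration is the mean, over volleys
#' with at least \code{k} participants, of the time from the first to the
#' k-th distinct E-cell's first spike.
#'
#' @param raster a \code{spike_raster} from [simulate_ping()], or any data
#'   frame with \code{cell} and \code{time}
#' @param cfg the [ping_config()] (defaults to the raster's own)
#' @param k participation depth for the volley-duration measure
#' @return list of class \code{rhythm_metrics}: \code{participation},
#'   \code{frequency_hz}, \code{volley_duration_ms}, \code{n_volleys},
#'   and a per-volley data frame
#' @export
rhythm_metrics <- function(raster, cfg = attr(raster, "config"), k = 100) {
  stopifnot(!is.null(cfg))
  es <- raster[raster$cell > cfg$n_i &
               raster$time >= cfg$transient & raster$time <= cfg$t_end, ]
  if (nrow(es) < 10) stop("no rhythm detected: too few E-spikes after transient")
  ord <- order(es$time)
  tt <- es$time[ord]; cc <- es$cell[ord]

  # iterate the gap threshold to self-consistency
  thr <- 4
  bounds <- NULL
  for (it in 1:25) {
    brk <- which(diff(tt) > thr)
    starts <- c(1, brk + 1); ends <- c(brk, length(tt))
    onsets <- tt[starts]
    if (length(onsets) < 3) stop("no rhythm detected: fewer than 3 volleys")
    thr_new <- stats::median(diff(onsets)) / 2
    if (abs(thr_new - thr) < 1e-9) break
    thr <- thr_new
  }

  # drop possibly-truncated edge volleys
  keep <- seq_along(starts)
  if (length(keep) > 2) keep <- keep[-c(1, length(keep))]
  if (length(keep) < 3)
    stop("no rhythm detected: need at least 3 steady-state volleys")

  per <- lapply(keep, function(i) {
    cells <- cc[starts[i]:ends[i]]; times <- tt[starts[i]:ends[i]]
    first <- tapply(times, cells, min)
    list(onset = times[1], n = length(first), first_times = sort(first))
  })
  n_cells <- vapply(per, function(x) x$n, numeric(1))
  onsets <- vapply(per, function(x) x$onset, numeric(1))
  dur_k <- vapply(per, function(x) {
    if (x$n >= k) unname(x$first_times[k] - x$first_times[1]) else NA_real_
  }, numeric(1))

  if (stats::var(n_cells) > 1.5)
    warning("per-volley participation is unsteady (variance ",
            format(stats::var(n_cells), digits = 3), " cells^2)")

  structure(list(
    participation = round(mean(n_cells)),
    frequency_hz = 1000 / mean(diff(onsets)),
    volley_duration_ms = if (all(is.na(dur_k))) NA_real_
                         else mean(dur_k, na.rm = TRUE),
    k = k, n_volleys = length(keep),
    per_volley = data.frame(onset = onsets, participation = n_cells,
                            duration_k = dur_k)),
    class = "rhythm_metrics")
}

#' @export
print.rhythm_metrics <- function(x, ...) {
  cat("<rhythm_metrics> ", x$n_volleys, " volleys\n",
      "  participation:    ", x$participation, " E-cells per volley\n",
      "  frequency:        ", format(x$frequency_hz, digits = 4), " Hz\n",
      "  first ", x$k, " E-cells in: ",
      format(x$volley_duration_ms, digits = 3), " ms\n", sep = "")
  invisible(x)
}

#' Write rhythm metrics as JSON
#'
#' @param m a \code{rhythm_metrics} object
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_rhythm_metrics <- function(m, path) {
  jsonlite::write_json(
    list(participation = m$participation, frequency_hz = m$frequency_hz,
         volley_duration_ms = m$volley_duration_ms, k = m$k,
         n_volleys = m$n_volleys),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
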