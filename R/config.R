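#' Serialize stimuli and simulation settings as structured text
#'
#' Stimulus specs round-trip through plain lists (and YAML files) of the form
#' \code{list(family = "alpha", r = ..., epsilon = ...)} etc.; simulation
#' settings load from a YAML config with keys \code{model}, \code{tau},
#' \code{dt}, \code{t_end}, \code{detection_level_mV}.
#'
#' @param stim a stimulus object
#' @return \code{stimulus_to_list}: a plain named list;
#'   \code{stimulus_from_list}: the stimulus object
#' @name config_io
NULL

#' @rdname config_io
#' @export
stimulus_to_list <- function(stim) {
  stopifnot(inherits(stim, "stimulus"))
  lst <- unclass(stim)
  lst[!vapply(lst, is.null, logical(1))]
}

#' @rdname config_io
#' @param lst a list with a \code{family} entry and the family's parameters
#' @export
stimulus_from_list <- function(lst) {
  fam <- match.arg(lst$family,
                   c("alpha", "delta_train", "synaptic_train", "constant",
                     "ramp"))
  arg <- function(nm, default) if (is.null(lst[[nm]])) default else lst[[nm]]
  switch(fam,
    alpha = alpha_pulse(lst$r, arg("epsilon", 1)),
    delta_train = delta_train(lst$w, lst$delta, arg("n_pulses", Inf)),
    synaptic_train = synaptic_train(lst$gbar, lst$delta, arg("tau_decay", 3),
                                    arg("v_rev", NULL), arg("n_pulses", Inf)),
    constant = constant_drive(lst$amplitude),
    ramp = ramp_drive(lst$c, lst$delta))
}

#' @rdname config_io
#' @param path YAML file path
#' @export
save_stimulus <- function(stim, path) {
  lst <- stimulus_to_list(stim)
  # YAML has no native Inf
  if (!is.null(lst$n_pulses) && is.infinite(lst$n_pulses)) lst$n_pulses <- ".inf"
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname config_io
#' @export
load_stimulus <- function(path) {
  lst <- yaml::read_yaml(path)
  if (identical(lst$n_pulses, ".inf")) lst$n_pulses <- Inf
  stimulus_from_list(lst)
}

#' Read a simulation config
#'
#' @param path YAML file with keys \code{model} (one of lif, theta, wb, rtm),
#'   \code{tau} (ms; LIF/theta only), \code{dt}, \code{t_end} (ms), and
#'   \code{detection_level_mV} (conductance-based models only)
#' @return list with a \code{model} spec plus \code{dt} and \code{t_end}
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  type <- match.arg(cfg$model, c("lif", "theta", "wb", "rtm"))
  model <- switch(type,
    lif = lif_model(cfg$tau),
    theta = theta_model(if (is.null(cfg$tau)) 0.5 else cfg$tau),
    wb = wb_model(if (is.null(cfg$detection_level_mV)) 0
                  else cfg$detection_level_mV),
    rtm = rtm_model(if (is.null(cfg$detection_level_mV)) 0
                    else cfg$detection_level_mV))
  list(model = model, dt = if (is.null(cfg$dt)) 0.01 else cfg$dt,
       t_end = cfg$t_end)
}
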