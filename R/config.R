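.default_run_config <- function() {
  list(
    septum = list(n_oscillators = 250, center_frequency_hz = 6,
                  frequency_sd_hz = 0.5, sync_ratio = 15, reset_gain = 4,
                  peak_phase_rad = 0, phase_offset_rad = 0,
                  theta_gain_na = 0.25, rate_time_constant_ms = 10),
    areas = list(EC = list(n_exc = 10000L, n_inh = 1000L),
                 DG = list(n_exc = 10000L, n_inh = 100L),
                 CA3 = list(n_exc = 1000L, n_inh = 100L),
                 CA1 = list(n_exc = 10000L, n_inh = 1000L)),
    synapses = list(excitatory = list(reversal_mv = 0, rise_ms = 0.3,
                                      decay_ms = 5),
                    inhibitory = list(reversal_mv = -80, rise_ms = 1,
                                      decay_ms = 10)),
    topology = list(sigma_intra_exc_um = 2500, sigma_intra_inh_um = 350,
                    sigma_inter_um = 1000, lloyd_iter = 1000,
                    lloyd_tol = 1e-6),
    stimulation = list(target_area = "CA1", amplitude_na = 0,
                       pulse_width_ms = 1, mode = "none",
                       target_phase_rad = NA, phase_tol_rad = 0.05,
                       arm_time_ms = 100, train_frequency_hz = 6,
                       train_duration_s = 2),
    runtime = list(dt_ms = 0.1, duration_s = 3, burn_in_s = 1,
                   scale_factor = 1, seed = 1L, noise = TRUE,
                   noise_ref_ms = 1, reset_on = TRUE))
}

.validate_section <- function(value, default, path) {
  if (is.list(default)) {
    if (!is.list(value)) .stopf("config key '%s' must be a mapping", path)
    unknown <- setdiff(names(value), names(default))
    if (length(unknown))
      .stopf("unknown config key '%s.%s'", path, unknown[1])
    for (nm in names(value))
      default[[nm]] <- .validate_section(value[[nm]], default[[nm]],
                                         paste(path, nm, sep = "."))
    return(default)
  }
  value
}

.check_run_config <- function(cfg) {
  rt <- cfg$runtime
  if (rt$dt_ms <= 0) .stopf("runtime.dt_ms must be > 0")
  if (rt$duration_s <= rt$burn_in_s)
    .stopf("runtime.duration_s must exceed runtime.burn_in_s")
  if (rt$scale_factor <= 0 || rt$scale_factor > 1)
    .stopf("runtime.scale_factor must be in (0, 1]")
  if (cfg$septum$n_oscillators < 1) .stopf("septum.n_oscillators must be >= 1")
  if (!cfg$stimulation$mode %in% c("none", "times", "phase", "train"))
    .stopf("stimulation.mode must be one of none/times/phase/train")
  cfg
}

#' Load a run configuration
#'
#' Reads a YAML run configuration, validates it against the package schema
#' (unknown keys are rejected, constraint violations name the offending
#' key), and fills every omitted key with its default - an empty file yields
#' the reference parameterisation of the model at scale 1.
#'
#' @param path YAML file path (missing file or empty file = all defaults).
#' @return a validated configuration list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- .default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) .stopf("config file '%s' does not exist", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- .validate_section(user, cfg, "config")
  }
  cfg <- .check_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration
#'
#' @param cfg a `run_config` (or plain list matching the schema).
#' @param path output YAML path.
#' @return invisibly, `path`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Instantiate model objects from a run configuration
#'
#' Converts a [load_config()] result into the package objects it describes:
#' a [network_config()] (with the septum, synapse, topology and runtime
#' sections applied) and the [stim_protocol()] of the stimulation section.
#'
#' @param cfg a `run_config`.
#' @return list with `network_config` and `protocol` (`NULL` when the mode
#'   is `"none"`).
#' @export
config_to_model <- function(cfg) {
  sp <- cfg$septum
  septum <- kuramoto_params(
    n_oscillators = sp$n_oscillators,
    center_frequency_hz = sp$center_frequency_hz,
    frequency_sd_hz = sp$frequency_sd_hz, sync_ratio = sp$sync_ratio,
    reset_gain = sp$reset_gain, peak_phase_rad = sp$peak_phase_rad,
    phase_offset_rad = sp$phase_offset_rad,
    theta_gain_na = sp$theta_gain_na,
    rate_time_constant_ms = sp$rate_time_constant_ms)
  wiring <- wiring_defaults()
  for (a in names(cfg$areas)) {
    wiring$sizes$n_exc[wiring$sizes$area == a] <- cfg$areas[[a]]$n_exc
    wiring$sizes$n_inh[wiring$sizes$area == a] <- cfg$areas[[a]]$n_inh
  }
  wiring$sigma_um <- c(intra_exc = cfg$topology$sigma_intra_exc_um,
                       intra_inh = cfg$topology$sigma_intra_inh_um,
                       inter = cfg$topology$sigma_inter_um)
  se <- cfg$synapses$excitatory
  si <- cfg$synapses$inhibitory
  rt <- cfg$runtime
  ncfg <- network_config(
    septum = septum, wiring = wiring,
    syn_exc = synapse_params("excitatory", se$reversal_mv, se$rise_ms,
                             se$decay_ms),
    syn_inh = synapse_params("inhibitory", si$reversal_mv, si$rise_ms,
                             si$decay_ms),
    scale = rt$scale_factor, dt_ms = rt$dt_ms, noise = rt$noise,
    noise_ref_ms = rt$noise_ref_ms, reset_on = rt$reset_on,
    lloyd_iter = cfg$topology$lloyd_iter, lloyd_tol = cfg$topology$lloyd_tol,
    seed = rt$seed)
  st <- cfg$stimulation
  protocol <- if (st$mode == "none") NULL else
    stim_protocol(target_area = st$target_area,
                  amplitude_na = st$amplitude_na,
                  pulse_width_ms = st$pulse_width_ms, mode = st$mode,
                  onsets_ms = if (is.null(st$onsets_ms)) numeric(0)
                              else st$onsets_ms,
                  target_phase_rad = if (is.null(st$target_phase_rad) ||
                                          is.na(st$target_phase_rad))
                    NA_real_ else st$target_phase_rad,
                  phase_tol_rad = st$phase_tol_rad,
                  arm_time_ms = st$arm_time_ms,
                  train_frequency_hz = st$train_frequency_hz,
                  train_duration_s = st$train_duration_s)
  list(network_config = ncfg, protocol = protocol)
}
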