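#' Configuration of the closed-loop network model
#'
#' Collects everything needed to build and run the full septo-hippocampal
#' loop: oscillator parameters, wiring constants, synapse kinetics, the
#' population scale factor and the integration clock.  At `scale = 1` the
#' defaults reproduce the reference parameterisation (32,200 neurons in a
#' 15 mm slice).  For desk-scale work populations *and* the slice thickness
#' are both multiplied by `scale` (preserving volumetric neuron density),
#' and the conductance increments of each wiring rule are multiplied by the
#' kernel-mass ratio of [z_kernel_mean()], so the expected synaptic drive a
#' neuron receives per presynaptic population spike is conserved for every
#' rule.
#'
#' @param septum a [kuramoto_params()] object.
#' @param wiring wiring constants as [wiring_defaults()].
#' @param syn_exc,syn_inh [synapse_params()] for the two synapse kinds.
#' @param scale population scale factor in (0, 1].
#' @param dt_ms integration step shared by all model components (default
#'   0.1 ms).
#' @param noise logical; membrane noise on by default.
#' @param noise_ref_ms reference step at which noise SDs are quoted.
#' @param reset_on logical; enable the CA1-to-septum phase-reset pathway.
#' @param lloyd_iter,lloyd_tol neuron-placement relaxation controls.
#' @param seed integer seed for placement and wiring.
#' @return a list of class `network_config`.
#' @export
network_config <- function(septum = kuramoto_params(),
                           wiring = wiring_defaults(),
                           syn_exc = synapse_params("excitatory"),
                           syn_inh = synapse_params("inhibitory"),
                           scale = 1, dt_ms = 0.1,
                           noise = TRUE, noise_ref_ms = 1,
                           reset_on = TRUE,
                           lloyd_iter = 1000, lloyd_tol = 1e-6,
                           seed = 1L) {
  if (scale <= 0 || scale > 1) .stopf("scale must be in (0, 1]")
  if (dt_ms <= 0) .stopf("dt_ms must be > 0")
  structure(list(septum = septum, wiring = wiring, syn_exc = syn_exc,
                 syn_inh = syn_inh, scale = scale, dt_ms = dt_ms,
                 noise = noise, noise_ref_ms = noise_ref_ms,
                 reset_on = reset_on, lloyd_iter = lloyd_iter,
                 lloyd_tol = lloyd_tol, seed = as.integer(seed)),
            class = "network_config")
}

#' Build the runnable network
#'
#' Places neurons on the parametric slice, wires all intra- and inter-area
#' connections, and attaches the oscillator ensemble: theta drive targets
#' both EC populations, the CA1 excitatory rate feeds the oscillator reset
#' term.
#'
#' @param config a [network_config()].
#' @return object of class `hf_network`.
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  set.seed(config$seed)
  sizes <- config$wiring$sizes
  counts <- data.frame(area = sizes$area,
                       n_exc = pmax(1L, as.integer(round(sizes$n_exc * config$scale))),
                       n_inh = pmax(1L, as.integer(round(sizes$n_inh * config$scale))))
  layout <- place_neurons(slice_geometry(z_extent_um = 15000 * config$scale),
                          counts,
                          lloyd_iter = config$lloyd_iter,
                          lloyd_tol = config$lloyd_tol)
  # compensation factors are a property of the harness, evaluated at the
  # reference inter-area gains regardless of the gains being simulated
  ref <- config$wiring
  ref$inter_gain <- wiring_defaults()$inter_gain
  topo <- build_topology(layout, config$wiring,
                         increment_factors = .scale_increment_factors(
                           config$scale, ref))
  structure(list(config = config, layout = layout, topology = topo,
                 counts = counts,
                 theta_target = which(layout$area == "EC"),
                 ca1_exc = which(layout$area == "CA1" & layout$cell == "exc")),
            class = "hf_network")
}

#' Reduced excitatory-inhibitory circuit
#'
#' A single CA1-like area (default 1000 pyramidal cells, 100 interneurons)
#' with the CA1 intra-area wiring rules, used for studying gamma generation
#' under ramping or pulsed drive in isolation from the theta loop.  By
#' default the circuit is point-local: connection probabilities are the
#' zero-distance maxima of the spatial kernel, so the reduced circuit
#' behaves as one local E-I module rather than a thinned-out slice.
#'
#' @param n_exc,n_inh population sizes.
#' @param coupled logical; `FALSE` removes all synaptic coupling (the
#'   decoupled control).
#' @param spatial logical; `TRUE` applies the distance-decayed kernel of the
#'   full slice instead of the point-local probabilities.
#' @param config a [network_config()]; its CA1 wiring row, synapse and noise
#'   settings are used.  Increments are not rescaled (the reduced circuit is
#'   its own reference size).
#' @return object of class `hf_network`.
#' @export
ei_circuit <- function(n_exc = 1000, n_inh = 100, coupled = TRUE,
                       spatial = FALSE, config = network_config()) {
  set.seed(config$seed)
  counts <- data.frame(area = "CA1", n_exc = as.integer(n_exc),
                       n_inh = as.integer(n_inh))
  layout <- place_neurons(slice_geometry(), counts,
                          lloyd_iter = config$lloyd_iter,
                          lloyd_tol = config$lloyd_tol)
  wiring <- config$wiring
  wiring$sizes <- counts
  wiring$inter_gain[] <- 0
  if (!coupled) wiring$intra_prob[] <- 0
  if (!spatial) wiring$sigma_um[c("intra_exc", "intra_inh")] <- 1e9
  topo <- build_topology(layout, wiring)
  structure(list(config = config, layout = layout, topology = topo,
                 counts = counts, theta_target = integer(0),
                 ca1_exc = which(layout$cell == "exc")),
            class = "hf_network")
}

#' Stimulation protocol
#'
#' Intracellular current pulses applied equally to all neurons (both classes)
#' of the target area.  Modes: `"times"` (explicit onsets), `"phase"` (a
#' single pulse at the first crossing of a target theta phase after an
#' arming time), `"train"` (a pulse train at fixed frequency, with onset
#' either phase-targeted or at the arming time when `target_phase_rad` is
#' `NA`), or `"none"`.
#'
#' @param target_area `"EC"`, `"DG"`, `"CA3"` or `"CA1"` (default).
#' @param amplitude_na pulse amplitude (nA, depolarising positive).
#' @param pulse_width_ms pulse width (default 1 ms).
#' @param mode stimulation mode.
#' @param onsets_ms explicit onset times for `"times"` mode.
#' @param target_phase_rad theta phase triggering the (first) pulse; 0 is
#'   the theta peak, `pi`/`-pi` the trough.
#' @param phase_tol_rad tolerance of the phase trigger (default 0.05 rad).
#' @param arm_time_ms time before which no pulse may fire (default 100 ms).
#' @param train_frequency_hz,train_duration_s pulse-train parameters.
#' @return a list of class `stim_protocol`.
#' @export
stim_protocol <- function(target_area = "CA1", amplitude_na = 10,
                          pulse_width_ms = 1,
                          mode = c("none", "times", "phase", "train"),
                          onsets_ms = numeric(0),
                          target_phase_rad = NA_real_,
                          phase_tol_rad = 0.05,
                          arm_time_ms = 100,
                          train_frequency_hz = 6,
                          train_duration_s = 2) {
  mode <- match.arg(mode)
  if (!is.finite(amplitude_na)) .stopf("amplitude_na must be finite")
  if (mode == "train" && train_frequency_hz <= 0)
    .stopf("train_frequency_hz must be > 0")
  if (mode == "times" && !length(onsets_ms))
    .stopf("mode 'times' needs at least one onset")
  structure(list(target_area = target_area, amplitude_na = amplitude_na,
                 pulse_width_ms = pulse_width_ms, mode = mode,
                 onsets_ms = sort(as.numeric(onsets_ms)),
                 target_phase_rad = target_phase_rad,
                 phase_tol_rad = phase_tol_rad, arm_time_ms = arm_time_ms,
                 train_frequency_hz = train_frequency_hz,
                 train_duration_s = train_duration_s),
            class = "stim_protocol")
}

#' Stimulus current series from a protocol
#'
#' Renders a protocol into a per-step current series on a fixed clock.  For
#' phase-targeted modes a theta-phase series must be supplied; the (first)
#' pulse fires at the first crossing of the requested phase after the arming
#' time.
#'
#' @param protocol a [stim_protocol()].
#' @param n_steps number of steps.
#' @param dt_ms step size.
#' @param theta_phase_rad optional phase series (length `n_steps`), needed
#'   for phase-targeted modes.
#' @return numeric current series (nA) with attribute `"onsets_ms"`.
#' @export
make_stimulus <- function(protocol, n_steps, dt_ms = 0.1,
                          theta_phase_rad = NULL) {
  stopifnot(inherits(protocol, "stim_protocol"))
  t <- (seq_len(n_steps) - 1) * dt_ms
  onsets <- switch(protocol$mode,
    none = numeric(0),
    times = protocol$onsets_ms,
    phase = ,
    train = {
      first <- if (is.finite(protocol$target_phase_rad)) {
        if (is.null(theta_phase_rad))
          .stopf("phase-targeted protocol needs a theta_phase_rad series")
        d <- .wrap_pi(theta_phase_rad - protocol$target_phase_rad)
        armed <- t >= protocol$arm_time_ms
        hit <- which(armed[-1] & d[-1] >= 0 & d[-n_steps] < 0 &
                       (d[-1] - d[-n_steps]) < pi)
        if (!length(hit)) {
          near <- which(armed & abs(d) < protocol$phase_tol_rad)
          if (!length(near))
            .stopf("requested phase %.2f rad never reached after %.0f ms",
                   protocol$target_phase_rad, protocol$arm_time_ms)
          t[near[1]]
        } else t[hit[1] + 1L]
      } else protocol$arm_time_ms
      if (protocol$mode == "phase") first
      else {
        period <- 1000 / protocol$train_frequency_hz
        n_pulses <- floor(protocol$train_duration_s * 1000 / period + 1e-9)
        first + period * (seq_len(n_pulses) - 1)
      }
    })
  cur <- numeric(n_steps)
  for (on in onsets)
    cur[t >= on - 1e-9 & t < on + protocol$pulse_width_ms - 1e-9] <-
      protocol$amplitude_na
  attr(cur, "onsets_ms") <- onsets
  cur
}

#' Exponential-kernel instantaneous population rate
#'
#' The feedback signal `X(t)`: each spike adds `1/(N tau)` and the trace
#' decays with time constant `tau`, yielding a per-neuron rate in spikes/s.
#'
#' @param spike_times_ms spike times (any order).
#' @param n_neurons population size `N`.
#' @param tau_fr_ms kernel decay (default 10 ms).
#' @param dt_ms sampling step.
#' @param duration_ms length of the output series.
#' @param x0 initial value.
#' @return data frame with `time_ms` and `rate` (spikes/s per neuron).
#' @export
firing_rate_feedback <- function(spike_times_ms, n_neurons, tau_fr_ms = 10,
                                 dt_ms = 0.1, duration_ms, x0 = 0) {
  if (tau_fr_ms <= 0) .stopf("tau_fr_ms must be > 0")
  n <- round(duration_ms / dt_ms)
  counts <- tabulate(pmin(n, floor(spike_times_ms / dt_ms) + 1L), nbins = n)
  dec <- exp(-dt_ms / tau_fr_ms)
  inc <- counts / (n_neurons * tau_fr_ms * 1e-3)
  x <- numeric(n)
  prev <- x0
  for (i in seq_len(n)) {
    prev <- prev * dec + inc[i]
    x[i] <- prev
  }
  data.frame(time_ms = (seq_len(n) - 1) * dt_ms, rate = x)
}

.csr_edges <- function(edges, n_neurons) {
  if (!nrow(edges))
    return(list(ptr = integer(n_neurons + 1L), post = integer(0),
                w = numeric(0)))
  ord <- order(edges$pre)
  cnt <- tabulate(edges$pre, nbins = n_neurons)
  list(ptr = c(0L, cumsum(cnt)),
       post = as.integer(edges$post[ord] - 1L),
       w = edges$weight_ps[ord] * 1e-6)  # pS -> uS
}

#' Run a closed-loop simulation
#'
#' Integrates the oscillator ensemble, all neurons and all synapses in
#' lockstep on one clock.  The theta drive is injected into both EC
#' populations, the CA1 excitatory rate feeds the oscillator reset term with
#' a one-step lag, and the stimulation protocol is applied to its target
#' area.  Fully reproducible for a given `seed`.
#'
#' @param network an [build_network()] or [ei_circuit()] object.
#' @param duration_s simulated time (seconds).
#' @param protocol optional [stim_protocol()].
#' @param ext optional extra injected currents: a list with `current_na` (a
#'   `n_steps x k` matrix) and `groups` (length-`k` list of neuron index
#'   vectors).
#' @param seed integer seed for initial conditions, noise and oscillator
#'   initialisation.
#' @param theta_gain_na optional override of the septum output gain.
#' @param reset_on optional override of the phase-reset flag.
#' @param noise optional override of the membrane-noise flag.
#' @param monitor_neurons indices of neurons whose voltage and CAN/M currents
#'   are recorded every step.
#' @param exc_overrides,inh_overrides named lists of [cell_class()] overrides
#'   (e.g. `list(g_can = 0)` removes the CAN channel network-wide).
#' @param init_state optional list with `phases` and `omega_rad_s` to resume
#'   the oscillator ensemble from a previous trace.
#' @return an object of class `theta_trace`; see [print.theta_trace()].
#' @export
run_simulation <- function(network, duration_s, protocol = NULL, ext = NULL,
                           seed = 1L, theta_gain_na = NULL, reset_on = NULL,
                           noise = NULL, monitor_neurons = integer(0),
                           exc_overrides = list(), inh_overrides = list(),
                           init_state = NULL) {
  stopifnot(inherits(network, "hf_network"))
  cfg <- network$config
  dt <- cfg$dt_ms
  n_steps <- as.integer(round(duration_s * 1000 / dt))
  n_neurons <- nrow(network$layout)
  set.seed(seed)

  exc <- do.call(cell_class, c(list(type = "excitatory"), exc_overrides))
  inh <- do.call(cell_class, c(list(type = "inhibitory"), inh_overrides))
  csr <- .csr_edges(network$topology$edges, n_neurons)

  sp <- cfg$septum
  if (!is.null(theta_gain_na)) sp$theta_gain_na <- theta_gain_na
  if (is.null(reset_on)) reset_on <- cfg$reset_on
  if (is.null(noise)) noise <- cfg$noise
  if (is.null(init_state)) {
    ens <- init_ensemble(kuramoto_params(
      n_oscillators = sp$n_oscillators,
      center_frequency_hz = sp$center_frequency_hz,
      frequency_sd_hz = sp$frequency_sd_hz, seed = NULL))
    phases <- ens$phases_rad; omega <- ens$natural_freqs_rad_s
  } else {
    phases <- init_state$phases; omega <- init_state$omega_rad_s
  }

  if (is.null(protocol)) protocol <- stim_protocol(mode = "none", amplitude_na = 0)
  mode_code <- match(protocol$mode, c("none", "times", "phase", "train")) - 1L
  tgt <- which(network$layout$area == protocol$target_area)
  if (mode_code > 0L && !length(tgt))
    .stopf("stimulation target area '%s' is empty", protocol$target_area)

  if (is.null(ext)) {
    ext_cpp <- list(current_na = matrix(numeric(0), nrow = n_steps, ncol = 0),
                    groups = list())
  } else {
    stopifnot(nrow(ext$current_na) == n_steps,
              ncol(ext$current_na) == length(ext$groups))
    ext_cpp <- list(current_na = ext$current_na,
                    groups = lapply(ext$groups,
                                    function(g) as.integer(sort(g) - 1L)))
  }

  v0 <- runif(n_neurons, -70, -60)
  res <- sim_network_cpp(
    net = list(class_id = as.integer(network$layout$cell == "inh"),
               exc_params = exc, inh_params = inh,
               edge_ptr = csr$ptr, edge_post = csr$post, edge_w_us = csr$w,
               syn_tau_ms = c(cfg$syn_exc$rise_ms, cfg$syn_exc$decay_ms,
                              cfg$syn_inh$rise_ms, cfg$syn_inh$decay_ms),
               e_rev_e = cfg$syn_exc$reversal_mv,
               e_rev_i = cfg$syn_inh$reversal_mv,
               theta_target = as.integer(network$theta_target - 1L),
               ca1_exc = as.integer(network$ca1_exc - 1L),
               v0 = v0),
    kur = list(phases = phases, omega_rad_s = omega,
               sync_ratio = sp$sync_ratio, reset_gain = sp$reset_gain,
               peak_phase_rad = sp$peak_phase_rad,
               phase_offset_rad = sp$phase_offset_rad,
               theta_gain_na = sp$theta_gain_na,
               rate_time_constant_ms = sp$rate_time_constant_ms,
               reset_on = isTRUE(reset_on)),
    stim = list(mode = mode_code, onsets_ms = protocol$onsets_ms,
                amplitude_na = protocol$amplitude_na,
                pulse_width_ms = protocol$pulse_width_ms,
                target_phase_rad = protocol$target_phase_rad,
                phase_tol_rad = protocol$phase_tol_rad,
                arm_time_ms = protocol$arm_time_ms,
                train_frequency_hz = if (protocol$mode == "train")
                  protocol$train_frequency_hz else 0,
                train_duration_ms = protocol$train_duration_s * 1000,
                target = as.integer(tgt - 1L)),
    ext = ext_cpp,
    run = list(dt_ms = dt, n_steps = n_steps, noise_on = isTRUE(noise),
               noise_ref_ms = cfg$noise_ref_ms,
               monitor_idx = as.integer(monitor_neurons - 1L),
               record_theta = TRUE))

  if (mode_code %in% c(2L, 3L) && is.finite(protocol$target_phase_rad) &&
      !isTRUE(res$stim_triggered))
    .stopf("requested stimulation phase %.2f rad never reached after %.0f ms",
           protocol$target_phase_rad, protocol$arm_time_ms)

  trace <- list(
    spikes = data.frame(time_ms = res$spike_t_ms,
                        neuron = res$spike_id + 1L),
    series = data.frame(time_ms = (seq_len(n_steps) - 1) * dt,
                        theta_amplitude = res$theta_amplitude,
                        theta_phase = res$theta_phase,
                        theta_drive_na = res$theta_drive_na,
                        ca1_rate = res$ca1_rate,
                        stim_na = res$stim_na),
    layout = network$layout,
    dt_ms = dt, duration_s = duration_s,
    stim_onsets_ms = res$stim_onsets_ms,
    protocol = protocol,
    theta_gain_na = sp$theta_gain_na,
    reset_on = isTRUE(reset_on),
    seed = seed,
    final_phases = res$phases,
    omega_rad_s = omega)
  if (length(monitor_neurons)) {
    trace$monitors <- list(neurons = monitor_neurons, v_mv = res$monitor_v,
                           i_can_na = res$monitor_i_can,
                           i_m_na = res$monitor_i_m)
  }
  class(trace) <- "theta_trace"
  trace
}

#' Mean firing rate of a population within a trace
#'
#' @param trace a `theta_trace`.
#' @param area area name or `NULL` for all areas.
#' @param cell `"exc"`, `"inh"` or `NULL` for both.
#' @param window_ms time window `c(from, to)`; default the full run.
#' @return mean rate in Hz (spikes per second per neuron).
#' @export
population_rate <- function(trace, area = NULL, cell = NULL, window_ms = NULL) {
  sel <- rep(TRUE, nrow(trace$layout))
  if (!is.null(area)) sel <- sel & trace$layout$area %in% area
  if (!is.null(cell)) sel <- sel & trace$layout$cell %in% cell
  ids <- which(sel)
  if (!length(ids)) .stopf("no neurons selected")
  if (is.null(window_ms)) window_ms <- c(0, trace$duration_s * 1000)
  sp <- trace$spikes
  k <- sum(sp$neuron %in% ids & sp$time_ms >= window_ms[1] &
             sp$time_ms < window_ms[2])
  k / (length(ids) * diff(window_ms) * 1e-3)
}
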