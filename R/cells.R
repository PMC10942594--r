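#' Built-in conductance-based cell classes
#'
#' Two single-compartment Hodgkin-Huxley cell classes are provided.  The
#' excitatory class (pyramidal cells in EC/CA3/CA1, granule cells in DG)
#' carries leak, Na, K, low-threshold Ca, calcium-activated non-specific
#' cation (CAN) and M-type adaptation currents; the inhibitory class
#' (fast-spiking basket cells, Wang-Buzsaki kinetics) carries leak, Na and K
#' only.  Conductances are specific (mS/cm2) and scaled by the membrane area;
#' membrane noise is a per-step Gaussian voltage perturbation scaled as
#' `sqrt(dt / noise_ref_ms)`, with the class standard deviation quoted at a
#' 1 ms reference step.
#'
#' @param type `"excitatory"` or `"inhibitory"`.
#' @param ... named overrides of individual parameters (e.g. `g_can = 0` to
#'   remove the CAN channel, `noise_sd_uv = 0`).
#' @return a named list of class `cell_class`.
#' @export
cell_class <- function(type = c("excitatory", "inhibitory"), ...) {
  type <- match.arg(type)
  p <- if (type == "excitatory") {
    list(type = "excitatory", is_exc = TRUE,
         area_um2 = 29e3, capacitance_uf_cm2 = 1,
         g_l = 0.01, e_l = -70,
         g_k = 5, e_k = -100,
         g_na = 50, e_na = 50,
         g_ca = 0.1, e_ca = 120,
         g_can = 25e-3, e_can = -20,
         g_m = 90e-3, e_m = -100,
         tau_ca_ms = 1000, ca_inf = 0.24, k_u = 1e4, depth_um = 1,
         noise_sd_uv = 1000,
         spike_thresh_mv = -20, refractory_ms = 2)
  } else {
    list(type = "inhibitory", is_exc = FALSE,
         area_um2 = 14e3, capacitance_uf_cm2 = 1,
         g_l = 0.1, e_l = -65,
         g_k = 9, e_k = -90,
         g_na = 35, e_na = 55,
         g_ca = 0, e_ca = 120,
         g_can = 0, e_can = -20,
         g_m = 0, e_m = -100,
         tau_ca_ms = 1000, ca_inf = 0.24, k_u = 1e4, depth_um = 1,
         noise_sd_uv = 100,
         spike_thresh_mv = -20, refractory_ms = 2)
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) .stopf("unknown cell parameter(s): %s", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  if (any(unlist(p[c("g_l", "g_k", "g_na", "g_ca", "g_can", "g_m")]) < 0))
    .stopf("conductances must be >= 0")
  p$area_cm2 <- p$area_um2 * 1e-8
  class(p) <- "cell_class"
  p
}

#' Voltage-dependent gating rates
#'
#' Evaluates the transition rates (1/ms) of a gating variable at a membrane
#' potential, with removable singularities replaced by their analytic limits.
#' Channels with a direct steady-state/time-constant description (the M
#' current gate `p`) return `x_inf` and `tau_ms` only.  For the
#' calcium-dependent CAN gate, `ca_molar` selects the operating point.
#'
#' @param vm_mv membrane potential, mV.
#' @param channel one of `"n"` (K), `"m"`, `"h"` (Na), `"m_ca"`, `"h_ca"`
#'   (Ca), `"m_can"` (CAN), `"p"` (M).
#' @param cell a [cell_class()] object (or `"excitatory"`/`"inhibitory"`).
#' @param ca_molar intracellular calcium (mol/L), used by `"m_can"` only.
#' @return list with `alpha`, `beta` (1/ms), `x_inf` and `tau_ms` (or the
#'   latter two only for `"p"`).
#' @export
gating_rates <- function(vm_mv, channel, cell = "excitatory", ca_molar = 0.24) {
  if (is.character(cell)) cell <- cell_class(cell)
  gating_rates_cpp(vm_mv, channel, cell$is_exc, ca_molar)
}

#' Per-channel membrane currents
#'
#' Computes the ionic currents (nA) for a given state, using the printed
#' gating-power laws: \eqn{n^4} for K, \eqn{m^3 h} for Na, \eqn{m^2 h} for
#' Ca, \eqn{m_{CAN}^2} for CAN, and \eqn{p} for M.  Currents are signed so
#' that positive values are hyperpolarising (they enter the membrane equation
#' with a minus sign).
#'
#' @param state named list with `vm_mv` and the gate values present for the
#'   class (`n`, `m`, `h`, and for excitatory cells `m_ca`, `h_ca`, `p`,
#'   `m_can`).
#' @param cell a [cell_class()] object.
#' @return named list of currents in nA: `i_l`, `i_k`, `i_na`, `i_ca`,
#'   `i_can`, `i_m`.
#' @export
ionic_currents <- function(state, cell) {
  stopifnot(inherits(cell, "cell_class"))
  g <- function(spec) spec * cell$area_cm2 * 1e3  # mS/cm2 * cm2 -> uS
  v <- state$vm_mv
  gt <- function(nm) if (!is.null(state[[nm]])) state[[nm]] else 0
  for (nm in c("n", "m", "h", "m_ca", "h_ca", "p", "m_can")) {
    x <- gt(nm)
    if (any(x < 0 | x > 1)) .stopf("gate '%s' outside [0, 1]", nm)
  }
  list(i_l   = g(cell$g_l) * (v - cell$e_l),
       i_k   = g(cell$g_k) * gt("n")^4 * (v - cell$e_k),
       i_na  = g(cell$g_na) * gt("m")^3 * gt("h") * (v - cell$e_na),
       i_ca  = g(cell$g_ca) * gt("m_ca")^2 * gt("h_ca") * (v - cell$e_ca),
       i_can = g(cell$g_can) * gt("m_can")^2 * (v - cell$e_can),
       i_m   = g(cell$g_m) * gt("p") * (v - cell$e_m))
}

#' Intracellular calcium update
#'
#' Integrates \eqn{d[Ca]/dt = \gamma(I_{Ca}) + ([Ca]_\infty - [Ca])/\tau}
#' with the influx term \eqn{\gamma = -k_u I_{Ca} / (2 F d A)} evaluated in
#' the standard submembrane-shell convention (current density over `2 F d`);
#' inward (negative) calcium currents raise the concentration.  The pool is
#' expressed in micromolar (resting value 0.24) and floored at zero.
#'
#' @param ca_molar current concentration (uM).
#' @param i_ca_na calcium current (nA; negative = depolarising influx).
#' @param dt_ms time step (ms).
#' @param cell a [cell_class()] object.
#' @return updated concentration (mol/L).
#' @export
calcium_update <- function(ca_molar, i_ca_na, dt_ms, cell) {
  if (dt_ms <= 0) .stopf("dt_ms must be > 0")
  faraday <- 96485.33212
  dens <- i_ca_na * 1e-6 / cell$area_cm2                      # mA/cm^2
  gamma <- -cell$k_u * dens / (2 * faraday * cell$depth_um) * 1e3  # uM/ms
  ca <- ca_molar + dt_ms * (gamma + (cell$ca_inf - ca_molar) / cell$tau_ca_ms)
  pmax(ca, 0)
}

#' Integrate a single isolated neuron
#'
#' Runs one cell of a given class under an applied current series using the
#' same compiled integrator as the network simulation (exponential Euler for
#' gates, explicit Euler for the membrane and calcium).
#'
#' @param cell a [cell_class()] object.
#' @param i_ext_na applied current series (nA), one value per step.
#' @param dt_ms time step (default 0.1 ms).
#' @param v0_mv initial membrane potential (default rest near the leak
#'   reversal).
#' @param noise logical; apply the class membrane noise.
#' @param noise_ref_ms reference step at which `noise_sd_uv` is quoted.
#' @param record logical; keep the full voltage/calcium/current traces.
#' @param seed optional integer seed.
#' @return list with `spike_times_ms`, the final `state`, and (if `record`)
#'   traces `vm_mv`, `ca_molar`, `i_can_na`, `i_m_na`.
#' @export
simulate_neuron <- function(cell, i_ext_na, dt_ms = 0.1, v0_mv = cell$e_l,
                            noise = FALSE, noise_ref_ms = 1, record = TRUE,
                            seed = NULL) {
  stopifnot(inherits(cell, "cell_class"))
  if (dt_ms <= 0) .stopf("dt_ms must be > 0")
  if (!is.null(seed)) set.seed(seed)
  sim_neuron_cpp(cell, v0_mv, as.numeric(i_ext_na), dt_ms, noise_ref_ms,
                 noise, record)
}

#' Advance one neuron by a single step
#'
#' Thin wrapper around the compiled integrator for stepping a neuron state by
#' `dt_ms` under instantaneous synaptic/theta/stimulation currents.  Mostly
#' useful for didactic traces and tests; network runs use [run_simulation()].
#'
#' @inheritParams simulate_neuron
#' @param i_total_na total applied current for this step (depolarising
#'   positive), nA.
#' @param v0_mv membrane potential at the start of the step.
#' @return list with the new `state` and a `spike` flag.
#' @export
step_neuron <- function(cell, v0_mv, i_total_na = 0, dt_ms = 0.1,
                        noise = FALSE, noise_ref_ms = 1) {
  out <- sim_neuron_cpp(cell, v0_mv, i_total_na, dt_ms, noise_ref_ms, noise, FALSE)
  list(state = out$state, spike = length(out$spike_times_ms) > 0)
}

#' Input-frequency curve of an isolated cell
#'
#' Mean firing rate of a single neuron as a function of tonic input current,
#' measured by counting detected spikes over the simulation window.
#'
#' @param cell a [cell_class()] object.
#' @param currents_na grid of tonic input currents (nA).
#' @param duration_ms simulated time per grid point (default 1000 ms).
#' @param dt_ms integration step.
#' @param noise logical; apply membrane noise.
#' @param discard_ms initial transient excluded from the count (default
#'   100 ms).
#' @param seed optional integer seed.
#' @return data frame with `current_na` and `rate_hz`.
#' @export
if_curve <- function(cell, currents_na, duration_ms = 1000, dt_ms = 0.1,
                     noise = FALSE, discard_ms = 100, seed = NULL) {
  if (!length(currents_na)) .stopf("currents_na must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_ms / dt_ms)
  rate <- vapply(currents_na, function(i0) {
    out <- sim_neuron_cpp(cell, cell$e_l, rep(i0, n), dt_ms, 0.1, noise, FALSE)
    sp <- out$spike_times_ms
    sum(sp >= discard_ms) / ((duration_ms - discard_ms) * 1e-3)
  }, numeric(1))
  data.frame(current_na = currents_na, rate_hz = rate)
}
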