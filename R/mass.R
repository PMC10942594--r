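#' Parameters of the Wilson-Cowan mass model with oscillatory drive
#'
#' A fast, generalisable reference version of the loop: one excitatory and
#' one inhibitory neural mass,
#' \deqn{\tau_E dE/dt = -E + f(g_E\theta_E + W_{EE}E - W_{IE}I + stim_E(t))}
#' \deqn{\tau_I dI/dt = -I + f(g_I\theta_I + W_{EI}E)}
#' with the logistic response \eqn{f(x) = 1/(1+e^{-\beta(x - x_m)})}, driven
#' by a Kuramoto ensemble whose reset term is fed by `E(t)` (taking the role
#' of the CA1 rate in the spiking model).  The theta waveform enters as the
#' normalised rectified cosine \eqn{\theta_E = (A\cos\phi + 1)/2 \in [0,1]}.
#'
#' @param tau_e_ms,tau_i_ms mass time constants (default 3.2 ms).
#' @param g_e,g_i drive gains onto the two masses (default 0.7 and 0).
#' @param w_ee,w_ei,w_ie,w_ii coupling weights (default 4.8, 4, 4, 0).
#' @param beta,x_m logistic slope and midpoint (default 4 and 1).
#' @param oscillators a [kuramoto_params()] for the driving ensemble
#'   (default: 100 oscillators at 4 Hz, coupling 25, reset gain 90 - the
#'   strong-reset regime appropriate for a drive bounded in \eqn{[0,1]}).
#' @return a list of class `mass_params`.
#' @export
mass_params <- function(tau_e_ms = 3.2, tau_i_ms = 3.2,
                        g_e = 0.7, g_i = 0,
                        w_ee = 4.8, w_ei = 4, w_ie = 4, w_ii = 0,
                        beta = 4, x_m = 1,
                        oscillators = kuramoto_params(
                          n_oscillators = 100, center_frequency_hz = 4,
                          sync_ratio = 25, reset_gain = 90)) {
  if (tau_e_ms <= 0 || tau_i_ms <= 0) .stopf("mass time constants must be > 0")
  structure(list(tau_e_ms = tau_e_ms, tau_i_ms = tau_i_ms, g_e = g_e,
                 g_i = g_i, w_ee = w_ee, w_ei = w_ei, w_ie = w_ie,
                 w_ii = w_ii, beta = beta, x_m = x_m,
                 oscillators = oscillators),
            class = "mass_params")
}

#' Logistic response function of the neural mass
#'
#' \eqn{f(x) = 1 / (1 + e^{-\beta(x - x_m)})}, mapping net input to activity
#' in (0, 1).
#'
#' @param x net input.
#' @param beta slope (default 4).
#' @param x_m midpoint (default 1).
#' @return activity in (0, 1), vectorised over `x`.
#' @export
sigmoid_response <- function(x, beta = 4, x_m = 1) {
  1 / (1 + exp(-beta * (x - x_m)))
}

#' Advance the mass model by one step
#'
#' Explicit Euler for the two masses; the oscillator ensemble advances on
#' the same clock with `E(t)` feeding its reset term.
#'
#' @param state list with `e`, `i` and `ensemble` (a `kuramoto_state`).
#' @param params a [mass_params()].
#' @param stim_e external stimulation input to the excitatory mass.
#' @param dt_ms step size.
#' @return the advanced state.
#' @export
step_mass_model <- function(state, params, stim_e = 0, dt_ms = 0.01) {
  if (dt_ms <= 0) .stopf("dt_ms must be > 0")
  op <- order_parameter(state$ensemble)
  theta_e <- (op$amplitude * cos(op$phase_rad) + 1) / 2
  fe <- sigmoid_response(params$g_e * theta_e + params$w_ee * state$e -
                           params$w_ie * state$i + stim_e,
                         params$beta, params$x_m)
  fi <- sigmoid_response(params$g_i * theta_e + params$w_ei * state$e -
                           params$w_ii * state$i,
                         params$beta, params$x_m)
  e_new <- state$e + dt_ms * (-state$e + fe) / params$tau_e_ms
  i_new <- state$i + dt_ms * (-state$i + fi) / params$tau_i_ms
  state$ensemble <- step_ensemble(state$ensemble, params$oscillators,
                                  ca1_rate = state$e, dt_ms = dt_ms)
  state$e <- e_new
  state$i <- i_new
  state
}

#' Run the mass model
#'
#' Integrates the Wilson-Cowan pair coupled to its Kuramoto drive and
#' records mass activities, the collective theta state, and the stimulus.
#'
#' @param params a [mass_params()].
#' @param duration_s simulated time.
#' @param dt_ms step size (default 0.01 ms; the masses are fast).
#' @param stim optional stimulation: a numeric series (one value per step)
#'   or a [stim_protocol()] with mode `"times"`/`"train"` (phase-targeted
#'   onsets are resolved against the running theta phase).
#' @param e0,i0 initial activities.
#' @param seed integer seed (oscillator initialisation).
#' @param record_every keep every k-th sample (default 10, i.e. 0.1 ms
#'   resolution at the default step).
#' @return a data frame of class `mass_trace` with time, `e`, `i`, theta
#'   amplitude/phase/drive (normalised) and the stimulus series; attribute
#'   `"onset_ms"` carries the resolved first pulse time when a protocol was
#'   given.
#' @export
run_mass_model <- function(params = mass_params(), duration_s = 2,
                           dt_ms = 0.01, stim = NULL, e0 = 0.1, i0 = 0.1,
                           seed = 1L, record_every = 10L) {
  n_steps <- round(duration_s * 1000 / dt_ms)
  set.seed(seed)
  osc <- params$oscillators
  osc$seed <- NULL
  ens <- init_ensemble(osc)

  onset_ms <- NA_real_
  if (inherits(stim, "stim_protocol")) {
    prot <- stim
    stim_series <- NULL
  } else if (is.numeric(stim)) {
    stim_series <- rep_len(stim, n_steps)
    prot <- NULL
  } else {
    stim_series <- numeric(n_steps)
    prot <- NULL
  }

  state <- list(e = e0, i = i0, ensemble = ens)
  keep <- seq(1L, n_steps, by = record_every)
  nk <- length(keep)
  out_e <- out_i <- out_a <- out_p <- out_s <- numeric(nk)
  k <- 1L
  armed <- !is.null(prot) && is.finite(prot$target_phase_rad)
  started <- !is.null(prot) && !is.finite(prot$target_phase_rad)
  if (started) onset_ms <- prot$arm_time_ms
  d_prev <- NA_real_
  for (s in seq_len(n_steps)) {
    t <- (s - 1) * dt_ms
    op <- order_parameter(state$ensemble)
    stim_now <- 0
    if (!is.null(prot)) {
      if (armed && t >= prot$arm_time_ms) {
        d <- .wrap_pi(op$phase_rad - prot$target_phase_rad)
        hit <- if (!is.na(d_prev)) (d_prev < 0 && d >= 0 && (d - d_prev) < pi)
               else abs(d) < prot$phase_tol_rad
        d_prev <- d
        if (hit) { armed <- FALSE; started <- TRUE; onset_ms <- t }
      }
      if (started) {
        period <- if (prot$mode == "train") 1000 / prot$train_frequency_hz else Inf
        since <- t - onset_ms
        lim <- if (prot$mode == "train") prot$train_duration_s * 1000
               else prot$pulse_width_ms
        if (since >= 0 && since < lim &&
            (since %% period) < prot$pulse_width_ms)
          stim_now <- prot$amplitude_na
      }
    } else stim_now <- stim_series[s]
    state <- step_mass_model(state, params, stim_e = stim_now, dt_ms = dt_ms)
    if (s == keep[k]) {
      out_e[k] <- state$e; out_i[k] <- state$i
      out_a[k] <- op$amplitude; out_p[k] <- op$phase_rad; out_s[k] <- stim_now
      if (k < nk) k <- k + 1L
    }
  }
  out <- data.frame(time_ms = (keep - 1) * dt_ms, e = out_e, i = out_i,
                    theta_amplitude = out_a, theta_phase = out_p,
                    theta_drive = (out_a * cos(out_p) + 1) / 2,
                    stim = out_s)
  attr(out, "onset_ms") <- onset_ms
  class(out) <- c("mass_trace", "data.frame")
  out
}
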