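#' Parameters of the medial-septum oscillator ensemble
#'
#' The medial septum is modelled as `n_oscillators` coupled Kuramoto phase
#' oscillators whose collective rhythm provides the theta drive to the
#' entorhinal cortex.  Each oscillator obeys
#' \deqn{d\theta_i/dt = \omega_i + (k/N)\sum_j \sin(\theta_j - \theta_i) +
#'       G_{reset} X(t) Z(\theta_i)}
#' with natural frequencies \eqn{\omega_i} normally distributed around the
#' centre frequency, a global coupling constant `sync_ratio` (the `k/N`
#' coefficient times `N`, i.e. the two-oscillator locking boundary in rad/s),
#' and a reset term in which the CA1 population rate `X(t)` perturbs each
#' phase through the biphasic phase-response function
#' \eqn{Z(\theta) = -\sin(\theta - (\theta_{peak} + \phi_{offset}))}.
#'
#' @param n_oscillators number of oscillators (default 250).
#' @param center_frequency_hz centre of the natural-frequency distribution
#'   (default 6 Hz).
#' @param frequency_sd_hz standard deviation of the natural frequencies
#'   (default 0.5 Hz).
#' @param sync_ratio global coupling constant `k` entering the equation as
#'   `k/N` in front of the phase-coupling sum (default 15).
#' @param reset_gain gain `G_reset` of the CA1 feedback on the oscillator
#'   phases (default 4).
#' @param peak_phase_rad phase at which the theta output peaks (default 0).
#' @param phase_offset_rad offset added to the peak phase inside the
#'   phase-response function (default 0, the physiological setting).
#' @param theta_gain_na gain `G_theta` scaling the rectified-cosine theta
#'   drive, in nA (default 0.25; the tuning procedure re-estimates it).
#' @param rate_time_constant_ms decay time constant of the exponential kernel
#'   used for the CA1 instantaneous population rate (default 10 ms).
#' @param seed integer seed controlling frequency/phase initialisation.
#' @return an object of class `kuramoto_params`.
#' @seealso [init_ensemble()], [step_ensemble()], [theta_drive()]
#' @export
kuramoto_params <- function(n_oscillators = 250,
                            center_frequency_hz = 6,
                            frequency_sd_hz = 0.5,
                            sync_ratio = 15,
                            reset_gain = 4,
                            peak_phase_rad = 0,
                            phase_offset_rad = 0,
                            theta_gain_na = 0.25,
                            rate_time_constant_ms = 10,
                            seed = NULL) {
  if (n_oscillators < 1) .stopf("n_oscillators must be >= 1, got %s", n_oscillators)
  if (frequency_sd_hz < 0) .stopf("frequency_sd_hz must be >= 0")
  if (rate_time_constant_ms <= 0) .stopf("rate_time_constant_ms must be > 0")
  if (theta_gain_na < 0) .stopf("theta_gain_na must be >= 0")
  p <- list(n_oscillators = as.integer(n_oscillators),
            center_frequency_hz = center_frequency_hz,
            frequency_sd_hz = frequency_sd_hz,
            sync_ratio = sync_ratio,
            reset_gain = reset_gain,
            peak_phase_rad = peak_phase_rad,
            phase_offset_rad = phase_offset_rad,
            theta_gain_na = theta_gain_na,
            rate_time_constant_ms = rate_time_constant_ms,
            seed = seed)
  class(p) <- "kuramoto_params"
  p
}

#' Initialise the oscillator ensemble
#'
#' Natural frequencies are drawn from a normal distribution around the centre
#' frequency; phases are initialised uniformly on the circle (a burn-in period
#' is used in closed-loop runs to reach the synchronised regime).
#'
#' @param params a [kuramoto_params()] object.
#' @return an object of class `kuramoto_state` with elements `phases_rad`
#'   (wrapped to \eqn{[-\pi, \pi]}) and `natural_freqs_rad_s`.
#' @export
init_ensemble <- function(params) {
  stopifnot(inherits(params, "kuramoto_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  omega <- 2 * pi * rnorm(params$n_oscillators,
                          mean = params$center_frequency_hz,
                          sd = params$frequency_sd_hz)
  phases <- runif(params$n_oscillators, -pi, pi)
  structure(list(phases_rad = phases, natural_freqs_rad_s = omega),
            class = "kuramoto_state")
}

#' Advance the oscillator ensemble by one step
#'
#' Explicit Euler step of the phase equation.  The phase-coupling sum is
#' evaluated in mean-field form through the order parameter,
#' \eqn{(k/N)\sum_j\sin(\theta_j-\theta_i) = k A \sin(\psi - \theta_i)}.
#'
#' @param state a `kuramoto_state`.
#' @param params a [kuramoto_params()].
#' @param ca1_rate instantaneous CA1 excitatory population rate `X(t)`
#'   (spikes/s per neuron), must be non-negative.
#' @param dt_ms time step in milliseconds.
#' @return the advanced `kuramoto_state` (phases wrapped to \eqn{[-\pi,\pi]}).
#' @export
step_ensemble <- function(state, params, ca1_rate = 0, dt_ms = 0.1) {
  stopifnot(inherits(state, "kuramoto_state"))
  if (dt_ms <= 0) .stopf("dt_ms must be > 0")
  if (ca1_rate < 0) .stopf("ca1_rate must be >= 0")
  th <- state$phases_rad
  op <- order_parameter(state)
  coupling <- params$sync_ratio * op$amplitude * sin(op$phase_rad - th)
  z <- phase_response_fn(th, params$peak_phase_rad, params$phase_offset_rad)
  dth <- state$natural_freqs_rad_s + coupling + params$reset_gain * ca1_rate * z
  state$phases_rad <- .wrap_pi(th + dth * dt_ms * 1e-3)
  state
}

#' Order parameter of the ensemble
#'
#' The complex mean \eqn{r = N^{-1}\sum_i e^{j\theta_i}}; its modulus is the
#' synchrony amplitude `A` and its argument the collective phase \eqn{\phi}.
#'
#' @param state a `kuramoto_state`.
#' @return a list with `amplitude` (in \eqn{[0, 1]}) and `phase_rad`.
#' @export
order_parameter <- function(state) {
  th <- state$phases_rad
  if (length(th) == 0L) .stopf("empty oscillator state")
  re <- mean(cos(th)); im <- mean(sin(th))
  list(amplitude = sqrt(re^2 + im^2), phase_rad = atan2(im, re))
}

#' Rectified-cosine theta drive
#'
#' Converts the collective state into the depolarising current delivered to
#' the entorhinal cortex: \eqn{I_\theta = G_\theta (A\cos\phi + 1)/2}, which
#' is non-negative and bounded by \eqn{G_\theta}.
#'
#' @param sample list with `amplitude` and `phase_rad` (as returned by
#'   [order_parameter()]).
#' @param theta_gain_na output gain \eqn{G_\theta} in nA.
#' @return drive current in nA.
#' @export
theta_drive <- function(sample, theta_gain_na) {
  if (theta_gain_na < 0) .stopf("theta_gain_na must be >= 0")
  a <- sample$amplitude
  if (any(a < -1e-12 | a > 1 + 1e-12)) .stopf("amplitude must lie in [0, 1]")
  theta_gain_na * (a * cos(sample$phase_rad) + 1) / 2
}

#' Biphasic phase-response function
#'
#' \eqn{Z(\theta) = -\sin(\theta - (\theta_{peak} + \phi_{offset}))}: positive
#' (phase advance) on the ascending slope of theta, negative (delay) on the
#' descending slope, zero at the peak.
#'
#' @param phase_rad oscillator phase(s), radians.
#' @param peak_phase_rad phase of the theta peak.
#' @param phase_offset_rad additional offset from the peak.
#' @return dimensionless phase sensitivity, vectorised over `phase_rad`.
#' @export
phase_response_fn <- function(phase_rad, peak_phase_rad = 0, phase_offset_rad = 0) {
  -sin(phase_rad - (peak_phase_rad + phase_offset_rad))
}

#' Run the isolated ensemble
#'
#' Convenience loop for septum-only experiments: advances the ensemble for
#' `n_steps` steps under an optional CA1-rate series and records the
#' collective amplitude, phase and drive.
#'
#' @param params a [kuramoto_params()].
#' @param n_steps number of steps.
#' @param dt_ms step size (default 0.1 ms).
#' @param ca1_rate scalar or length-`n_steps` series of `X(t)` values.
#' @param state optional initial state (default [init_ensemble()]).
#' @return data frame with time, amplitude, phase and drive current.
#' @export
run_ensemble <- function(params, n_steps, dt_ms = 0.1, ca1_rate = 0, state = NULL) {
  if (is.null(state)) state <- init_ensemble(params)
  x <- rep_len(ca1_rate, n_steps)
  amp <- phs <- drv <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    op <- order_parameter(state)
    amp[i] <- op$amplitude; phs[i] <- op$phase_rad
    drv[i] <- theta_drive(op, params$theta_gain_na)
    state <- step_ensemble(state, params, x[i], dt_ms)
  }
  out <- data.frame(time_ms = (seq_len(n_steps) - 1) * dt_ms,
                    amplitude = amp, phase_rad = phs, drive_na = drv)
  attr(out, "state") <- state
  out
}
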