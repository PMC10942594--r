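# shared builders for the test suite: tiny networks, cached so several test
# files can reuse the same object without re-placing neurons.

tiny_circuit <- local({
  cache <- NULL
  function(n_exc = 200, n_inh = 20, seed = 3) {
    key <- paste(n_exc, n_inh, seed)
    if (is.null(cache) || !identical(attr(cache, "key"), key)) {
      net <- ei_circuit(n_exc, n_inh,
                        config = network_config(seed = seed,
                                                lloyd_iter = 50))
      attr(net, "key") <- key
      cache <<- net
    }
    cache
  }
})

tiny_network <- local({
  cache <- NULL
  function(scale = 0.02, seed = 3, ...) {
    key <- paste(scale, seed, ...)
    if (is.null(cache) || !identical(attr(cache, "key"), key)) {
      net <- build_network(network_config(scale = scale, seed = seed,
                                          lloyd_iter = 50, ...))
      attr(net, "key") <- key
      cache <<- net
    }
    cache
  }
})

desk_network <- local({
  cache <- NULL
  function(scale = 0.05, seed = 5) {
    key <- paste(scale, seed)
    if (is.null(cache) || !identical(attr(cache, "key"), key)) {
      net <- build_network(network_config(scale = scale, seed = seed,
                                          lloyd_iter = 100))
      attr(net, "key") <- key
      cache <<- net
    }
    cache
  }
})

# constant-current external drive for every neuron of a network
const_drive <- function(net, amplitude_na, n_steps) {
  list(current_na = matrix(rep(amplitude_na, n_steps), ncol = 1),
       groups = list(seq_len(nrow(net$layout))))
}

# PRC of the isolated oscillator ensemble, probed by injecting a brief pulse
# directly into the feedback-rate input X(t).  The small-perturbation limit is
# analytic: a pulse of strength a and width w delivered at collective phase
# theta shifts every oscillator by G_reset * a * w * Z(theta), so the
# collective phase difference follows the -sin phase-response function up to
# a common scale.

.kuramoto_prc_sim <- function(params, pulse_phase, amplitude, dt_ms = 0.5,
                              n_steps = 6000, arm_ms = 1500,
                              pulse_ms = 10, seed = 2) {
  set.seed(seed)
  st <- init_ensemble(params)
  t <- (seq_len(n_steps) - 1) * dt_ms
  phase <- numeric(n_steps)
  onset <- NA_real_
  d_prev <- NA_real_
  for (i in seq_len(n_steps)) {
    op <- order_parameter(st)
    phase[i] <- op$phase_rad
    x <- 0
    if (!is.na(pulse_phase)) {
      if (is.na(onset) && t[i] >= arm_ms) {
        d <- .wrap_pi(op$phase_rad - pulse_phase)
        if (!is.na(d_prev) && d_prev < 0 && d >= 0 && (d - d_prev) < pi)
          onset <- t[i]
        d_prev <- d
      }
      if (!is.na(onset) && t[i] >= onset && t[i] < onset + pulse_ms)
        x <- amplitude
    }
    st <- step_ensemble(st, params, ca1_rate = x, dt_ms = dt_ms)
  }
  list(time_ms = t, phase = phase, onset_ms = onset)
}

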