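#' Empirical phase-response curve
#'
#' Estimates the phase advance or delay caused by a single perturbation as a
#' function of the theta phase at which it is delivered.  For every phase in
#' `phases_rad` and every amplitude, two runs are performed through
#' `simulate_fn`: one perturbed and one unperturbed reference; the curve is
#' the wrapped difference between the two theta phases evaluated `lag_ms`
#' after the perturbation onset (positive values are phase advances).
#'
#' @param simulate_fn function `(phase_rad, amplitude)` returning a list
#'   with `time_ms`, `phase` (the theta-phase series) and `onset_ms` (the
#'   delivered pulse time; ignored for the reference call).  The reference
#'   is obtained as `simulate_fn(NA, 0)` and must share the time base.
#' @param amplitudes perturbation amplitudes to test.
#' @param phases_rad stimulation phases (default the centres of 16 bins of
#'   width pi/8 spanning one cycle).
#' @param lag_ms evaluation lag after the pulse (default 2.5 ms).
#' @return object of class `phase_response_curve`: data frame `curve` with
#'   `phase_rad`, `amplitude`, `dphi_rad`, plus the evaluation lag.
#' @export
compute_prc <- function(simulate_fn, amplitudes,
                        phases_rad = seq(-pi, pi - pi / 8, by = pi / 8) + pi / 16,
                        lag_ms = 2.5) {
  ref <- simulate_fn(NA, 0)
  phase_at <- function(run, t) {
    i <- findInterval(t, run$time_ms)
    i <- max(1L, min(i, length(run$time_ms)))
    run$phase[i]
  }
  rows <- list()
  for (a in amplitudes) for (ph in phases_rad) {
    res <- simulate_fn(ph, a)
    t_eval <- res$onset_ms + lag_ms
    d <- .wrap_pi(phase_at(res, t_eval) - phase_at(ref, t_eval))
    rows[[length(rows) + 1L]] <-
      data.frame(phase_rad = ph, amplitude = a, dphi_rad = d)
  }
  structure(list(curve = do.call(rbind, rows), lag_ms = lag_ms),
            class = "phase_response_curve")
}

#' Phase-response curve of the closed-loop network
#'
#' Convenience wrapper: delivers a single 1 ms pulse to an area at each
#' stimulation phase and compares the septal theta phase against the
#' unstimulated run.
#'
#' @param network an `hf_network` with a septum.
#' @param amplitudes stimulation amplitudes (nA).
#' @param duration_s run length per simulation.
#' @param arm_time_ms earliest pulse time.
#' @param target_area stimulated area (default CA1).
#' @param seed seed shared by all runs (same noise realisation).
#' @param noise membrane noise flag for the PRC runs.
#' @inheritParams compute_prc
#' @return a `phase_response_curve`.
#' @export
prc_network <- function(network, amplitudes, duration_s = 1,
                        phases_rad = seq(-pi, pi - pi / 8, by = pi / 8) + pi / 16,
                        lag_ms = 2.5, arm_time_ms = 500, target_area = "CA1",
                        seed = 1L, noise = FALSE) {
  simulate_fn <- function(phase_rad, amplitude) {
    prot <- if (is.na(phase_rad)) NULL
      else stim_protocol(target_area = target_area, amplitude_na = amplitude,
                         mode = "phase", target_phase_rad = phase_rad,
                         arm_time_ms = arm_time_ms)
    tr <- run_simulation(network, duration_s, protocol = prot, seed = seed,
                         noise = noise)
    list(time_ms = tr$series$time_ms, phase = tr$series$theta_phase,
         onset_ms = if (length(tr$stim_onsets_ms)) tr$stim_onsets_ms[1] else NA)
  }
  compute_prc(simulate_fn, amplitudes, phases_rad, lag_ms)
}

#' @export
print.phase_response_curve <- function(x, ...) {
  cat(sprintf("phase-response curve (%d phases x %d amplitudes, lag %.1f ms)\n",
              length(unique(x$curve$phase_rad)),
              length(unique(x$curve$amplitude)), x$lag_ms))
  adv <- x$curve$dphi_rad[x$curve$phase_rad < 0]
  del <- x$curve$dphi_rad[x$curve$phase_rad > 0]
  cat(sprintf("  mean dphi ascending slope: %+.3f rad, descending: %+.3f rad\n",
              mean(adv), mean(del)))
  invisible(x)
}

#' @export
plot.phase_response_curve <- function(x, ...) {
  amps <- sort(unique(x$curve$amplitude))
  cols <- hcl.colors(max(2, length(amps)), "plasma")
  plot(NA, xlim = c(-pi, pi), ylim = range(x$curve$dphi_rad),
       xlab = "stimulation phase (rad)", ylab = expression(Delta * phi ~ "(rad)"),
       ...)
  abline(h = 0, col = "grey70")
  for (i in seq_along(amps)) {
    cv <- x$curve[x$curve$amplitude == amps[i], ]
    lines(cv$phase_rad, cv$dphi_rad, col = cols[i], type = "b", pch = 16)
  }
  legend("topright", legend = amps, col = cols[seq_along(amps)], lty = 1,
         title = "amplitude", cex = 0.8)
  invisible(x)
}
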