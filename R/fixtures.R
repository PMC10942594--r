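#' Synthetic phase-amplitude-coupled test signal
#'
#' A gamma carrier whose amplitude is modulated by the phase of a slow
#' rhythm, \eqn{x(t) = (1 + d\cos(2\pi f_p t))/2 \cdot \sin(2\pi f_a t)
#' + s\cos(2\pi f_p t) + \epsilon}: modulation depth `d = 1` concentrates
#' the gamma envelope at the slow peak, `d = 0` removes the coupling while
#' keeping both spectral components.
#'
#' @param duration_s signal length.
#' @param fs_hz sampling frequency (default 1000).
#' @param f_phase_hz slow (phase) frequency (default 6).
#' @param f_amp_hz fast (amplitude) frequency (default 60).
#' @param depth modulation depth in `[0, 1]`.
#' @param slow_weight amplitude of the additive slow component (default 1).
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer seed.
#' @return data frame with `time_s` and `x`; sampling frequency in
#'   attribute `fs_hz`.
#' @export
pac_signal <- function(duration_s = 10, fs_hz = 1000, f_phase_hz = 6,
                       f_amp_hz = 60, depth = 1, slow_weight = 1,
                       noise_sd = 0.05, seed = 1L) {
  if (depth < 0 || depth > 1) .stopf("depth must be in [0, 1]")
  set.seed(seed)
  t <- seq(0, duration_s - 1 / fs_hz, by = 1 / fs_hz)
  slow <- cos(2 * pi * f_phase_hz * t)
  env <- (1 + depth * slow) / 2
  x <- env * sin(2 * pi * f_amp_hz * t) + slow_weight * slow +
    rnorm(length(t), sd = noise_sd)
  out <- data.frame(time_s = t, x = x)
  attr(out, "fs_hz") <- fs_hz
  out
}

#' Homogeneous Poisson spike table
#'
#' @param n_neurons number of neurons.
#' @param rate_hz per-neuron rate.
#' @param duration_s observation window.
#' @param seed integer seed.
#' @return data frame with `time_ms` (sorted) and `neuron`.
#' @export
poisson_spikes <- function(n_neurons, rate_hz, duration_s, seed = 1L) {
  set.seed(seed)
  counts <- stats::rpois(n_neurons, rate_hz * duration_s)
  df <- data.frame(
    time_ms = runif(sum(counts), 0, duration_s * 1000),
    neuron = rep(seq_len(n_neurons), counts))
  df[order(df$time_ms), , drop = FALSE]
}

#' Generate reproducible fixture files
#'
#' Writes small plain-text fixtures for the analysis stack and the slice
#' geometry: `"slice-geometry"` (stratum polygons as CSV plus a YAML
#' manifest), `"pac-signal"` (a [pac_signal()] as CSV), or `"spike-toy"`
#' (a [poisson_spikes()] table as CSV).  All outputs are fully determined
#' by `params` and `seed`.
#'
#' @param kind fixture kind.
#' @param dir output directory (created if needed).
#' @param params named list of overrides passed to the underlying
#'   generator.
#' @param seed integer seed.
#' @return invisibly, the written file paths.
#' @export
generate_fixtures <- function(kind = c("slice-geometry", "pac-signal",
                                       "spike-toy"),
                              dir = ".", params = list(), seed = 1L) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- switch(kind,
    "slice-geometry" = {
      geo <- do.call(slice_geometry, params)
      rows <- do.call(rbind, lapply(names(geo$regions), function(a) {
        do.call(rbind, lapply(c("exc", "inh"), function(cl) {
          p <- geo$regions[[a]][[cl]]
          data.frame(region = a, stratum = cl, x_um = p$x, y_um = p$y)
        }))
      }))
      f1 <- file.path(dir, "slice_geometry.csv")
      f2 <- file.path(dir, "slice_geometry.yaml")
      write.csv(rows, f1, row.names = FALSE)
      yaml::write_yaml(list(z_extent_um = geo$z_extent_um,
                            regions = names(geo$regions)), f2)
      c(f1, f2)
    },
    "pac-signal" = {
      sig <- do.call(pac_signal, c(params, list(seed = seed)))
      f <- file.path(dir, "pac_signal.csv")
      write.csv(sig, f, row.names = FALSE)
      f
    },
    "spike-toy" = {
      args <- modifyList(list(n_neurons = 100, rate_hz = 6, duration_s = 2),
                         params)
      sp <- do.call(poisson_spikes, c(args, list(seed = seed)))
      f <- file.path(dir, "spike_toy.csv")
      write.csv(sp, f, row.names = FALSE)
      f
    })
  invisible(paths)
}
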