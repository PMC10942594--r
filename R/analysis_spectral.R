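#' Sliding-window instantaneous population rate
#'
#' Bins spikes in rectangular windows (default 5 ms, 90% overlap, i.e.
#' consecutive windows spaced 0.5 ms) and normalises counts by window length
#' and population size, yielding an instantaneous rate in spikes/s per
#' neuron.
#'
#' @param spike_times_ms spike times of the population.
#' @param n_neurons population size.
#' @param duration_ms length of the covered interval (windows span
#'   `[0, duration_ms]`).
#' @param bin_ms window width (default 5).
#' @param overlap fraction of overlap between consecutive windows (default
#'   0.9).
#' @return data frame of class `rate_series` with `time_ms` (window centres)
#'   and `rate_hz`; the sampling frequency is attached as attribute `fs_hz`.
#' @export
binned_rate <- function(spike_times_ms, n_neurons, duration_ms,
                        bin_ms = 5, overlap = 0.9) {
  if (bin_ms <= 0) .stopf("bin_ms must be > 0")
  if (overlap < 0 || overlap >= 1) .stopf("overlap must be in [0, 1)")
  step <- bin_ms * (1 - overlap)
  starts <- seq(0, duration_ms - bin_ms, by = step)
  sp <- sort(spike_times_ms)
  n_in <- findInterval(starts + bin_ms, sp, left.open = FALSE) -
    findInterval(starts, sp, left.open = TRUE)
  out <- data.frame(time_ms = starts + bin_ms / 2,
                    rate_hz = n_in / (bin_ms * 1e-3 * n_neurons))
  attr(out, "fs_hz") <- 1000 / step
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Population rate series from a simulation trace
#'
#' @param trace a `theta_trace`.
#' @param area area name (`NULL` = all).
#' @param cell `"exc"`, `"inh"` or `NULL`.
#' @inheritParams binned_rate
#' @return a [binned_rate()] series.
#' @export
trace_rate <- function(trace, area = NULL, cell = NULL, bin_ms = 5,
                       overlap = 0.9) {
  sel <- rep(TRUE, nrow(trace$layout))
  if (!is.null(area)) sel <- sel & trace$layout$area %in% area
  if (!is.null(cell)) sel <- sel & trace$layout$cell %in% cell
  ids <- which(sel)
  sp <- trace$spikes$time_ms[trace$spikes$neuron %in% ids]
  binned_rate(sp, length(ids), trace$duration_s * 1000, bin_ms, overlap)
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

#' Welch power spectral density
#'
#' Averaged modified periodogram over Hann-tapered segments (default 1 s
#' windows with 90% overlap, i.e. 1 Hz frequency resolution), one-sided
#' density normalisation (integral over frequency approximates the signal
#' variance).
#'
#' @param x signal.
#' @param fs_hz sampling frequency.
#' @param window_s segment length in seconds (default 1).
#' @param overlap segment overlap fraction (default 0.9).
#' @return data frame with `freq_hz` and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs_hz, window_s = 1, overlap = 0.9) {
  nseg <- round(window_s * fs_hz)
  if (length(x) < nseg) .stopf("signal shorter than one Welch window")
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- .hann(nseg)
  u <- sum(w^2)
  acc <- numeric(nseg %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / (fs_hz * u)
    half <- p[seq_len(nseg %/% 2 + 1)]
    half[2:(length(half) - if (nseg %% 2 == 0) 1 else 0)] <-
      2 * half[2:(length(half) - if (nseg %% 2 == 0) 1 else 0)]
    acc <- acc + half
  }
  data.frame(freq_hz = (seq_along(acc) - 1) * fs_hz / nseg,
             psd = acc / length(starts))
}

.simpson <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  if (n == 2) return(diff(x) * mean(y))
  h <- diff(x)
  tot <- 0
  i <- 1
  while (i + 2 <= n) {
    tot <- tot + (h[i] + h[i + 1]) / 6 *
      (y[i] * (2 - h[i + 1] / h[i]) +
       y[i + 1] * (h[i] + h[i + 1])^2 / (h[i] * h[i + 1]) +
       y[i + 2] * (2 - h[i] / h[i + 1]))
    i <- i + 2
  }
  if (i < n) tot <- tot + (x[n] - x[n - 1]) * (y[n] + y[n - 1]) / 2
  tot
}

#' Band power by Simpson integration of the Welch spectrum
#'
#' @inheritParams welch_psd
#' @param band two-element frequency band (Hz).
#' @param psd optional precomputed [welch_psd()] output.
#' @return integrated power within the band.
#' @export
band_power <- function(x = NULL, fs_hz = NULL, band, window_s = 1,
                       overlap = 0.9, psd = NULL) {
  if (is.null(psd)) psd <- welch_psd(x, fs_hz, window_s, overlap)
  if (band[1] < 0 || band[2] > max(psd$freq_hz))
    .stopf("band [%g, %g] outside the resolved spectrum", band[1], band[2])
  keep <- psd$freq_hz >= band[1] & psd$freq_hz <= band[2]
  if (sum(keep) < 2) .stopf("band too narrow for the frequency resolution")
  .simpson(psd$freq_hz[keep], psd$psd[keep])
}

#' Short-time Fourier spectrogram
#'
#' Hann-windowed STFT power (default 100 ms windows with 99% overlap, i.e.
#' 10 Hz frequency resolution).
#'
#' @param x signal.
#' @param fs_hz sampling frequency.
#' @param window_ms window width (default 100).
#' @param overlap overlap fraction (default 0.99).
#' @return list of class `stft_spectrogram`: `time_ms` (window centres),
#'   `freq_hz`, and `power` (time x frequency matrix).
#' @export
spectrogram_stft <- function(x, fs_hz, window_ms = 100, overlap = 0.99) {
  nseg <- round(window_ms * 1e-3 * fs_hz)
  if (length(x) < nseg) .stopf("signal shorter than one spectrogram window")
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- .hann(nseg)
  u <- sum(w^2)
  nf <- nseg %/% 2 + 1
  pw <- matrix(0, length(starts), nf)
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / (fs_hz * u)
    pw[k, ] <- p[seq_len(nf)]
  }
  structure(list(time_ms = (starts - 1 + nseg / 2) / fs_hz * 1000,
                 freq_hz = (seq_len(nf) - 1) * fs_hz / nseg,
                 power = pw),
            class = "stft_spectrogram")
}

#' @export
plot.stft_spectrogram <- function(x, flim = NULL, ...) {
  keep <- if (is.null(flim)) rep(TRUE, length(x$freq_hz))
          else x$freq_hz >= flim[1] & x$freq_hz <= flim[2]
  image(x$time_ms, x$freq_hz[keep], log10(x$power[, keep] + 1e-12),
        col = hcl.colors(64, "inferno"), xlab = "time (ms)",
        ylab = "frequency (Hz)", ...)
  invisible(x)
}

#' Dominant frequency of a signal
#'
#' Location of the maximum of the Welch spectrum within a search band;
#' a small convenience used by the ramp and sweep experiments.
#'
#' @inheritParams welch_psd
#' @param band search band (Hz), default the full resolved range above 1 Hz.
#' @return frequency (Hz) of maximal power.
#' @export
dominant_frequency <- function(x, fs_hz, band = NULL, window_s = 1,
                               overlap = 0.9) {
  psd <- welch_psd(x, fs_hz, window_s, overlap)
  if (is.null(band)) band <- c(1, max(psd$freq_hz))
  keep <- psd$freq_hz >= band[1] & psd$freq_hz <= band[2]
  psd$freq_hz[keep][which.max(psd$psd[keep])]
}
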