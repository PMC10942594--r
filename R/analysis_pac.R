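#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x real signal.
#' @return complex analytic signal (same length).
#' @keywords internal
.analytic_signal <- function(x) {
  n <- length(x)
  f <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(f * h, inverse = TRUE) / n
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-window FIR design (order about three cycles of the low band edge,
#' capped for short signals) applied forward and backward, so the pass band
#' keeps zero phase shift; transition widths are of the order of 20% of the
#' band edges.
#'
#' @param x signal.
#' @param fs_hz sampling frequency.
#' @param band two-element pass band (Hz).
#' @return filtered signal.
#' @export
bandpass_fir <- function(x, fs_hz, band) {
  if (band[1] <= 0 || band[2] >= fs_hz / 2)
    .stopf("band [%g, %g] must lie strictly inside (0, Nyquist)", band[1], band[2])
  ord <- round(3 * fs_hz / band[1])
  ord <- min(ord, floor((length(x) - 1) / 3) - 1)
  ord <- max(ord + ord %% 2, 16)  # even order
  b <- as.numeric(signal::fir1(ord, band / (fs_hz / 2), type = "pass"))
  as.numeric(signal::filtfilt(b, 1, x))
}

#' Modulation index of an amplitude-by-phase histogram
#'
#' The Kullback-Leibler divergence between the normalised mean-amplitude
#' distribution over phase bins and the uniform distribution, divided by
#' `log(n_bins)`: 0 for a perfectly uniform histogram (no coupling), 1 when
#' all amplitude mass falls in a single bin.
#'
#' @param m non-negative vector of mean amplitudes per phase bin.
#' @return modulation index in \eqn{[0, 1]}; 0 for a zero histogram.
#' @export
mi_from_histogram <- function(m) {
  if (any(m < 0)) .stopf("amplitude histogram must be non-negative")
  if (sum(m) < 1e-300) return(0)
  p <- m / sum(m)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] * length(m))) / log(length(m))
  max(0, min(1, mi))
}

#' Kullback-Leibler modulation index
#'
#' Quantifies phase-amplitude coupling between a slow (phase) and a fast
#' (amplitude) band of one signal: both bands are band-pass filtered, the
#' phase and amplitude are extracted with the Hilbert transform, the mean
#' amplitude is binned over phase (default 72 bins of 5 degrees), and the
#' index is the Kullback-Leibler divergence of the normalised amplitude
#' distribution from uniform, divided by `log(n_bins)` so it lies in
#' \eqn{[0, 1]}.
#'
#' @param x signal (e.g. an instantaneous population rate).
#' @param fs_hz sampling frequency.
#' @param phase_band slow band providing the phase (default 3-9 Hz).
#' @param amp_band fast band providing the amplitude (default 40-80 Hz).
#' @param n_bins number of phase bins (default 72).
#' @return object of class `pac_result`: `modulation_index`, `phase_bins_rad`
#'   (bin centres), `amplitude_by_phase` (mean amplitude per bin), the bands,
#'   and a `degenerate` flag set when the amplitude envelope carries no mass.
#' @export
modulation_index <- function(x, fs_hz, phase_band = c(3, 9),
                             amp_band = c(40, 80), n_bins = 72) {
  centers <- seq(-pi + pi / n_bins, pi - pi / n_bins, length.out = n_bins)
  res <- list(modulation_index = 0, phase_bins_rad = centers,
              amplitude_by_phase = rep(0, n_bins),
              phase_band = phase_band, amp_band = amp_band,
              degenerate = TRUE)
  class(res) <- "pac_result"
  if (sd(x) < 1e-12) return(res)   # flat input: no modulation by definition
  ph <- Arg(.analytic_signal(bandpass_fir(x, fs_hz, phase_band)))
  am <- Mod(.analytic_signal(bandpass_fir(x, fs_hz, amp_band)))
  bin <- pmin(n_bins, floor((ph + pi) / (2 * pi) * n_bins) + 1L)
  m <- vapply(seq_len(n_bins),
              function(b) if (any(bin == b)) mean(am[bin == b]) else 0,
              numeric(1))
  if (sum(m) < 1e-300) return(res)
  res$modulation_index <- mi_from_histogram(m)
  res$amplitude_by_phase <- m
  res$degenerate <- FALSE
  res
}

#' @export
print.pac_result <- function(x, ...) {
  cat(sprintf("modulation index: %.4f (phase %g-%g Hz, amplitude %g-%g Hz%s)\n",
              x$modulation_index, x$phase_band[1], x$phase_band[2],
              x$amp_band[1], x$amp_band[2],
              if (x$degenerate) "; degenerate input" else ""))
  invisible(x)
}

#' @export
plot.pac_result <- function(x, ...) {
  plot(x$phase_bins_rad, x$amplitude_by_phase, type = "h", lwd = 3,
       xlab = "theta phase (rad)", ylab = "mean gamma amplitude", ...)
  invisible(x)
}

.band_starts <- function(range, width, overlap) {
  step <- width * (1 - overlap)
  seq(range[1], range[2] - width, by = step)
}

#' Phase-amplitude comodulogram
#'
#' Modulation index over a grid of (phase band, amplitude band) pairs:
#' 1 Hz-wide phase bands with 80% overlap and 10 Hz-wide amplitude bands
#' with 90% overlap by default.  Band-limited simulated rates can be exactly
#' flat inside narrow bands, which makes the raw index spuriously high;
#' uniform noise with amplitude `noise_fraction` of the signal maximum is
#' therefore added before filtering (set `noise_fraction = 0` to recover the
#' plain index).
#'
#' @param x signal.
#' @param fs_hz sampling frequency.
#' @param phase_range,amp_range frequency ranges scanned for the phase and
#'   amplitude bands (Hz).
#' @param phase_width,amp_width band widths (Hz).
#' @param phase_overlap,amp_overlap band overlap fractions.
#' @param noise_fraction uniform-noise amplitude as a fraction of `max(x)`
#'   (default 0.2).
#' @param n_bins phase bins per index.
#' @param seed seed for the injected noise (recorded in the output).
#' @return object of class `comodulogram`: `phase_hz`, `amp_hz` (band
#'   centres), `mi` matrix (phase x amplitude), `noise_fraction`, `seed`.
#' @export
comodulogram <- function(x, fs_hz, phase_range = c(3, 9), amp_range = c(20, 100),
                         phase_width = 1, amp_width = 10,
                         phase_overlap = 0.8, amp_overlap = 0.9,
                         noise_fraction = 0.2, n_bins = 72, seed = 1L) {
  set.seed(seed)
  xn <- if (noise_fraction > 0)
    x + runif(length(x), -1, 1) * noise_fraction * max(abs(x)) else x
  p0 <- .band_starts(phase_range, phase_width, phase_overlap)
  a0 <- .band_starts(amp_range, amp_width, amp_overlap)
  mi <- matrix(NA_real_, length(p0), length(a0))
  ph_sig <- lapply(p0, function(f) {
    if (sd(xn) < 1e-12) return(NULL)
    Arg(.analytic_signal(bandpass_fir(xn, fs_hz, c(f, f + phase_width))))
  })
  for (j in seq_along(a0)) {
    am <- if (sd(xn) < 1e-12) NULL
          else Mod(.analytic_signal(bandpass_fir(xn, fs_hz, c(a0[j], a0[j] + amp_width))))
    for (i in seq_along(p0)) {
      if (is.null(am) || is.null(ph_sig[[i]])) { mi[i, j] <- 0; next }
      bin <- pmin(n_bins, floor((ph_sig[[i]] + pi) / (2 * pi) * n_bins) + 1L)
      m <- vapply(seq_len(n_bins),
                  function(b) if (any(bin == b)) mean(am[bin == b]) else 0,
                  numeric(1))
      mi[i, j] <- mi_from_histogram(m)
    }
  }
  structure(list(phase_hz = p0 + phase_width / 2, amp_hz = a0 + amp_width / 2,
                 mi = mi, noise_fraction = noise_fraction, seed = seed),
            class = "comodulogram")
}

#' @export
plot.comodulogram <- function(x, ...) {
  image(x$phase_hz, x$amp_hz, x$mi, col = hcl.colors(64, "viridis"),
        xlab = "phase frequency (Hz)", ylab = "amplitude frequency (Hz)", ...)
  invisible(x)
}

#' Preferred theta phase of gamma amplitude
#'
#' For each narrow gamma band (default 10 Hz wide with 90% overlap between
#' 20 and 100 Hz), bins the Hilbert amplitude over the phase of the slow
#' band and reports the phase of maximal amplitude; the matrix is the polar
#' profile of phase-amplitude coupling.
#'
#' @param x signal.
#' @param fs_hz sampling frequency.
#' @param phase_band slow band providing the phase (default 3-9 Hz).
#' @param amp_range,amp_width,amp_overlap gamma band grid.
#' @param n_bins number of phase bins.
#' @return object of class `preferred_phase`: `amp_hz`, `phase_bins_rad`,
#'   `amplitude` (band x bin matrix), `preferred_rad` (argmax per band).
#' @export
preferred_phase <- function(x, fs_hz, phase_band = c(3, 9),
                            amp_range = c(20, 100), amp_width = 10,
                            amp_overlap = 0.9, n_bins = 72) {
  ph <- Arg(.analytic_signal(bandpass_fir(x, fs_hz, phase_band)))
  bin <- pmin(n_bins, floor((ph + pi) / (2 * pi) * n_bins) + 1L)
  centers <- seq(-pi + pi / n_bins, pi - pi / n_bins, length.out = n_bins)
  a0 <- .band_starts(amp_range, amp_width, amp_overlap)
  m <- matrix(0, length(a0), n_bins)
  for (j in seq_along(a0)) {
    am <- Mod(.analytic_signal(bandpass_fir(x, fs_hz, c(a0[j], a0[j] + amp_width))))
    m[j, ] <- vapply(seq_len(n_bins),
                     function(b) if (any(bin == b)) mean(am[bin == b]) else 0,
                     numeric(1))
  }
  structure(list(amp_hz = a0 + amp_width / 2, phase_bins_rad = centers,
                 amplitude = m, preferred_rad = centers[apply(m, 1, which.max)]),
            class = "preferred_phase")
}

#' @export
plot.preferred_phase <- function(x, ...) {
  r <- x$amplitude / max(x$amplitude)
  plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
       xlab = "", ylab = "", axes = FALSE, ...)
  for (j in seq_len(nrow(r)))
    lines(r[j, ] * cos(x$phase_bins_rad), r[j, ] * sin(x$phase_bins_rad),
          col = hcl.colors(nrow(r), "zissou")[j])
  abline(h = 0, v = 0, col = "grey80")
  text(1.05, 0, "peak", cex = 0.7); text(-1.05, 0, "trough", cex = 0.7)
  invisible(x)
}
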