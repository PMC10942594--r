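test_that("binned rates normalise counts by window and population", {
  # no spikes
  r0 <- binned_rate(numeric(0), 100, 1000)
  expect_true(all(r0$rate_hz == 0))
  expect_equal(attr(r0, "fs_hz"), 2000)   # 0.5 ms spacing

  # one spike in a 5 ms bin with 100 neurons: 2 Hz at the covering windows
  r1 <- binned_rate(500, 100, 1000)
  expect_equal(max(r1$rate_hz), 2)

  # total spike mass is conserved: each spike is seen bin/step times
  set.seed(2)
  sp <- runif(400, 100, 900)
  r <- binned_rate(sp, 50, 1000, bin_ms = 5, overlap = 0.9)
  windows_per_spike <- 5 / 0.5
  expect_equal(sum(r$rate_hz) * 0.005 * 50 / windows_per_spike, 400,
               tolerance = 1e-10)
  expect_error(binned_rate(1, 10, 100, overlap = 1), "overlap")
})

test_that("Welch spectrum locates tones, keeps 1 Hz resolution and Parseval", {
  fs <- 500
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 4 * t)
  psd <- welch_psd(x, fs)
  expect_equal(diff(psd$freq_hz)[1], 1)              # 1 s window -> 1 Hz
  expect_equal(psd$freq_hz[which.max(psd$psd)], 4)

  # Parseval-style check on broadband noise: integral of PSD ~ variance
  set.seed(1)
  w <- rnorm(fs * 30)
  psd <- welch_psd(w, fs)
  expect_equal(.simpson(psd$freq_hz, psd$psd), var(w), tolerance = 0.05)

  # band power of white noise scales with bandwidth
  b1 <- band_power(w, fs, band = c(50, 100))
  b2 <- band_power(w, fs, band = c(50, 200))
  expect_equal(b2 / b1, 3, tolerance = 0.25)
  expect_error(band_power(w, fs, band = c(100, 400)), "outside")
  expect_error(welch_psd(w[1:100], fs), "shorter")
})

test_that("spectrogram tracks stationary tones and chirps", {
  fs <- 1000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  sg <- spectrogram_stft(sin(2 * pi * 60 * t), fs)
  expect_equal(diff(sg$freq_hz)[1], 10)              # 100 ms -> 10 Hz bins
  ridge <- sg$freq_hz[apply(sg$power, 1, which.max)]
  expect_true(all(ridge == 60))

  # linear chirp 20 -> 120 Hz: the ridge follows instantaneous frequency
  f0 <- 20; f1 <- 120
  finst <- f0 + (f1 - f0) * t / 4
  chirp <- sin(2 * pi * (f0 * t + (f1 - f0) * t^2 / 8))
  sg <- spectrogram_stft(chirp, fs)
  ridge <- sg$freq_hz[apply(sg$power, 1, which.max)]
  fexp <- f0 + (f1 - f0) * sg$time_ms / 4000
  expect_lt(median(abs(ridge - fexp)), 10)           # within one bin
})

test_that("histogram modulation index is the normalised KL divergence", {
  expect_equal(mi_from_histogram(rep(3.7, 72)), 0)
  expect_equal(mi_from_histogram(c(5, rep(0, 71))), 1)
  expect_equal(mi_from_histogram(rep(0, 72)), 0)
  # intermediate case against a direct evaluation
  m <- c(rep(2, 36), rep(1, 36))
  p <- m / sum(m)
  expect_equal(mi_from_histogram(m),
               sum(p * log(p * 72)) / log(72), tolerance = 1e-12)
  expect_error(mi_from_histogram(c(-1, 1)), "non-negative")
})

test_that("modulation index detects constructed phase-amplitude coupling", {
  mod <- pac_signal(duration_s = 8, depth = 1, seed = 3)
  flat <- pac_signal(duration_s = 8, depth = 0, seed = 3)
  fs <- attr(mod, "fs_hz")
  mi_mod <- modulation_index(mod$x, fs)
  mi_flat <- modulation_index(flat$x, fs)
  expect_gt(mi_mod$modulation_index, mi_flat$modulation_index)
  expect_gt(mi_mod$modulation_index, 0.02)
  expect_lt(mi_flat$modulation_index, 0.01)
  expect_true(mi_mod$modulation_index <= 1 && mi_mod$modulation_index >= 0)

  # gamma envelope proportional to (1 + cos theta): amplitude peaks at the
  # phase-signal peak (phase 0)
  pk <- mi_mod$phase_bins_rad[which.max(mi_mod$amplitude_by_phase)]
  expect_lt(abs(pk), 0.5)

  # invariance to overall amplitude scaling
  mi_scaled <- modulation_index(25 * mod$x, fs)
  expect_equal(mi_scaled$modulation_index, mi_mod$modulation_index,
               tolerance = 1e-10)

  # degenerate input flagged with index 0
  z <- modulation_index(rep(1, 4000), fs)
  expect_true(z$degenerate)
  expect_equal(z$modulation_index, 0)
})

test_that("uniform-noise injection suppresses the flat-band artifact", {
  # a pure slow tone has no genuine gamma modulation, but band-passing an
  # (almost) flat band produces a spurious index; injected noise removes it
  fs <- 500
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  x <- 2 + sin(2 * pi * 5 * t)
  raw <- comodulogram(x, fs, phase_range = c(4, 7), amp_range = c(40, 70),
                      phase_overlap = 0, amp_overlap = 0, noise_fraction = 0)
  fixed <- comodulogram(x, fs, phase_range = c(4, 7), amp_range = c(40, 70),
                        phase_overlap = 0, amp_overlap = 0,
                        noise_fraction = 0.2, seed = 4)
  expect_gt(max(raw$mi), 10 * max(fixed$mi))
  expect_lt(max(fixed$mi), 0.05)
})

test_that("comodulogram localises constructed coupling and nests plain MI", {
  sig <- pac_signal(duration_s = 8, f_phase_hz = 5, f_amp_hz = 60, depth = 1,
                    seed = 7)
  fs <- attr(sig, "fs_hz")
  cm <- comodulogram(sig$x, fs, phase_range = c(3, 8), amp_range = c(30, 90),
                     phase_overlap = 0.5, amp_overlap = 0.5,
                     noise_fraction = 0.2, seed = 2)
  idx <- which(cm$mi == max(cm$mi), arr.ind = TRUE)
  expect_lt(abs(cm$phase_hz[idx[1]] - 5), 1.01)
  expect_lt(abs(cm$amp_hz[idx[2]] - 60), 10.01)

  # noise_fraction = 0 reduces every cell to the plain modulation index
  cm0 <- comodulogram(sig$x, fs, phase_range = c(4, 6), amp_range = c(50, 70),
                      phase_width = 2, amp_width = 20,
                      phase_overlap = 0, amp_overlap = 0, noise_fraction = 0)
  mi0 <- modulation_index(sig$x, fs, phase_band = c(4, 6),
                          amp_band = c(50, 70))
  expect_equal(cm0$mi[1, 1], mi0$modulation_index, tolerance = 1e-12)
})

test_that("preferred phase follows the constructed modulation phase", {
  fs <- 1000
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  th <- 2 * pi * 6 * t
  for (shift in c(0, pi / 2)) {
    x <- (1 + cos(th - shift)) / 2 * sin(2 * pi * 60 * t) + cos(th) +
      0.02 * sin(2 * pi * 31 * t)
    pp <- preferred_phase(x, fs, amp_range = c(50, 70), amp_overlap = 0)
    expect_lt(abs(.wrap_pi(pp$preferred_rad[1] - shift)), 0.3)
  }
})
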