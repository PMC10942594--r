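test_that("ensemble phase response matches the -sin form at small amplitude", {
  p <- kuramoto_params(n_oscillators = 60, frequency_sd_hz = 0.1,
                       reset_gain = 4, seed = 9)
  phases <- seq(-pi, pi - pi / 4, by = pi / 4) + pi / 8
  prc <- compute_prc(function(ph, a) .kuramoto_prc_sim(p, ph, a),
                     amplitudes = 3, phases_rad = phases, lag_ms = 30)
  cv <- prc$curve
  # advance on the ascending slope, delay on the descending slope
  expect_true(all(cv$dphi_rad[cv$phase_rad < 0] > 0))
  expect_true(all(cv$dphi_rad[cv$phase_rad > 0] < 0))
  # shape: correlation with -sin(phase) close to 1
  expect_gt(stats::cor(cv$dphi_rad, -sin(cv$phase_rad)), 0.98)
})

test_that("zero reset gain yields a flat phase-response curve", {
  p <- kuramoto_params(n_oscillators = 60, frequency_sd_hz = 0.1,
                       reset_gain = 0, seed = 9)
  prc <- compute_prc(function(ph, a) .kuramoto_prc_sim(p, ph, a),
                     amplitudes = 5,
                     phases_rad = c(-3 * pi / 4, -pi / 4, pi / 4, 3 * pi / 4),
                     lag_ms = 30)
  expect_true(all(abs(prc$curve$dphi_rad) < 0.02))
})

test_that("phase-response magnitude grows with perturbation amplitude", {
  p <- kuramoto_params(n_oscillators = 60, frequency_sd_hz = 0.1,
                       reset_gain = 4, seed = 9)
  phases <- c(-pi / 2, pi / 2)
  prc <- compute_prc(function(ph, a) .kuramoto_prc_sim(p, ph, a),
                     amplitudes = c(1, 3, 9), phases_rad = phases,
                     lag_ms = 30)
  for (ph in phases) {
    cv <- prc$curve[prc$curve$phase_rad == ph, ]
    cv <- cv[order(cv$amplitude), ]
    expect_true(all(diff(abs(cv$dphi_rad)) > -1e-3))
  }
})
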