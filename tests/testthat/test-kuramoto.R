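test_that("ensemble initialisation follows the stated distributions", {
  # degenerate frequency spread
  p0 <- kuramoto_params(n_oscillators = 40, frequency_sd_hz = 0, seed = 1)
  st <- init_ensemble(p0)
  expect_equal(st$natural_freqs_rad_s, rep(2 * pi * 6, 40))

  # sample mean within 3 standard errors of the centre frequency
  p <- kuramoto_params(seed = 11)
  st <- init_ensemble(p)
  expect_length(st$phases_rad, 250)
  se <- 0.5 / sqrt(250)
  expect_lt(abs(mean(st$natural_freqs_rad_s) / (2 * pi) - 6), 3 * se)
  expect_true(all(st$phases_rad >= -pi & st$phases_rad <= pi))

  # determinism and parameter validation
  expect_identical(init_ensemble(p), init_ensemble(kuramoto_params(seed = 11)))
  expect_error(kuramoto_params(n_oscillators = 0), "n_oscillators")
})

test_that("order parameter is the modulus/argument of the complex mean", {
  mk <- function(ph) structure(list(phases_rad = ph,
                                    natural_freqs_rad_s = rep(0, length(ph))),
                               class = "kuramoto_state")
  op <- order_parameter(mk(rep(0.7, 9)))
  expect_equal(op$amplitude, 1)
  expect_equal(op$phase_rad, 0.7)
  expect_equal(order_parameter(mk(c(0, pi)))$amplitude, 0, tolerance = 1e-12)
  expect_equal(order_parameter(mk(c(0, pi / 2, pi, 3 * pi / 2)))$amplitude, 0,
               tolerance = 1e-12)
  expect_error(order_parameter(mk(numeric(0))), "empty")
})

test_that("theta drive is the bounded rectified cosine", {
  g <- 0.3
  expect_equal(theta_drive(list(amplitude = 1, phase_rad = 0), g), g)
  expect_equal(theta_drive(list(amplitude = 1, phase_rad = pi), g), 0)
  expect_equal(theta_drive(list(amplitude = 0, phase_rad = 2.1), g), g / 2)
  expect_error(theta_drive(list(amplitude = 0.5, phase_rad = 0), -1), ">= 0")
  # bounded for arbitrary states
  a <- runif(50); ph <- runif(50, -pi, pi)
  d <- mapply(function(a, p) theta_drive(list(amplitude = a, phase_rad = p), g),
              a, ph)
  expect_true(all(d >= 0 & d <= g))
})

test_that("phase-response function is the biphasic -sin form", {
  expect_equal(phase_response_fn(0.4 + 0.2, 0.4, 0.2), 0)
  expect_equal(phase_response_fn(-pi / 2, 0, 0), 1)
  th <- seq(-3, 3, by = 0.1)
  z <- phase_response_fn(th)
  expect_true(all(z[th > -pi & th < 0] > 0))   # advance on ascending slope
  expect_true(all(z[th > 0 & th < pi] < 0))    # delay on descending slope
})

test_that("decoupled oscillators drift at their natural frequencies", {
  p <- kuramoto_params(n_oscillators = 30, sync_ratio = 0, reset_gain = 0,
                       seed = 4)
  st <- init_ensemble(p)
  st1 <- step_ensemble(st, p, ca1_rate = 0, dt_ms = 0.1)
  expect_equal(.wrap_pi(st1$phases_rad - st$phases_rad),
               st$natural_freqs_rad_s * 1e-4, tolerance = 1e-12)
})

test_that("two-oscillator locking boundary sits at |domega| = k", {
  # closed form: d(Delta)/dt = domega - k sin(Delta); locked iff |domega| <= k
  k <- 6
  locked <- function(domega) {
    st <- structure(list(phases_rad = c(0, 1),
                         natural_freqs_rad_s = c(0, domega)),
                    class = "kuramoto_state")
    p <- kuramoto_params(n_oscillators = 2, sync_ratio = k, reset_gain = 0)
    for (i in 1:15000) st <- step_ensemble(st, p, 0, 1)
    d1 <- .wrap_pi(diff(st$phases_rad))
    for (i in 1:3000) st <- step_ensemble(st, p, 0, 1)
    d2 <- .wrap_pi(diff(st$phases_rad))
    abs(d2 - d1) < 5e-3
  }
  expect_true(locked(0.8 * k))
  expect_false(locked(1.2 * k))

  # bisection localises the boundary within 5%
  lo <- 0.5 * k; hi <- 1.5 * k
  for (i in 1:6) {
    mid <- (lo + hi) / 2
    if (locked(mid)) lo <- mid else hi <- mid
  }
  expect_lt(abs((lo + hi) / 2 - k) / k, 0.05)
})

test_that("reference ensemble synchronises under its default coupling", {
  p <- kuramoto_params(seed = 8)   # defaults: 250 oscillators, k = 15
  run <- run_ensemble(p, n_steps = 20000, dt_ms = 0.5)
  expect_gt(mean(tail(run$amplitude, 2000)), 0.9)
  # wrapped phases stay in range, amplitude in [0, 1]
  expect_true(all(run$amplitude >= 0 & run$amplitude <= 1))
})

test_that("amplitude and drive are invariant under rotation of all phases", {
  p <- kuramoto_params(n_oscillators = 25, seed = 2)
  st <- init_ensemble(p)
  shift <- 1.23
  st2 <- st
  st2$phases_rad <- .wrap_pi(st$phases_rad + shift)
  o1 <- order_parameter(st); o2 <- order_parameter(st2)
  expect_equal(o2$amplitude, o1$amplitude, tolerance = 1e-12)
  # drive computed against a peak phase shifted by the same constant
  d1 <- o1$amplitude * cos(o1$phase_rad - 0) # peak at 0
  d2 <- o2$amplitude * cos(o2$phase_rad - shift)
  expect_equal(d2, d1, tolerance = 1e-12)
})
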