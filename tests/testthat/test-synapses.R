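test_that("silent synapses stay silent and spikes add fixed increments", {
  p <- synapse_params("excitatory")
  s <- list(g = 0, h = 0)
  for (i in 1:100) s <- synapse_step(s$g, s$h, 0.1, p)
  expect_identical(c(s$g, s$h), c(0, 0))
  expect_equal(on_presynaptic_spike(0.5, 180e-6), 0.5 + 180e-6)
})

test_that("single-spike response matches the closed-form biexponential", {
  for (kind in c("excitatory", "inhibitory")) {
    p <- synapse_params(kind)
    w <- 1800e-6
    dt <- 0.1
    n <- 600
    g <- numeric(n)
    s <- list(g = 0, h = on_presynaptic_spike(0, w))
    for (i in seq_len(n)) {
      s <- synapse_step(s$g, s$h, dt, p)
      g[i] <- s$g
    }
    expected <- biexp_profile((1:n) * dt, p, w)
    expect_equal(g, as.numeric(expected), tolerance = 1e-9)

    # peak location: tg*th/(th-tg) * log(th/tg)
    tpk <- attr(expected, "peak_ms")
    expect_equal(tpk, p$rise_ms * p$decay_ms / (p$decay_ms - p$rise_ms) *
                   log(p$decay_ms / p$rise_ms))
    expect_equal((which.max(g)) * dt, tpk, tolerance = dt)
  }
})

test_that("wiring tables carry the reference conductance increments", {
  w <- wiring_defaults()
  expect_equal(w$intra_increment_ps["DG", "EI"], 180)
  expect_equal(w$intra_increment_ps["DG", "IE"], 1800)
  expect_equal(w$intra_increment_ps["CA1", "II"], 1800)
  expect_equal(w$intra_increment_ps["EC", "EI"], 20)
  expect_equal(w$inter_increment_ps["DG", "CA3"], 180)
  expect_equal(w$inter_increment_ps["CA1", "EC"], 60)
  expect_equal(w$intra_prob["CA1", "II"], 0.70)
  expect_equal(w$intra_prob["CA3", "EE"], 0.56)
  expect_equal(unname(w$sigma_um), c(2500, 350, 1000))
  # empty table cells mean no connection at all
  expect_equal(w$intra_prob["EC", "EE"], 0)
  expect_equal(w$inter_gain["DG", "CA1"], 0)
})

test_that("synapse parameter validation rejects degenerate kinetics", {
  expect_error(synapse_params("excitatory", rise_ms = 0), "> 0")
  expect_error(synapse_params("excitatory", rise_ms = 5, decay_ms = 5),
               "differ")
})
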