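exc <- cell_class("excitatory")
inh <- cell_class("inhibitory")

test_that("gating rates evaluate the printed expressions with analytic limits", {
  # interneuron Na activation at the 0/0 point: limit of 0.1x/(1-e^-x) is 1
  r <- gating_rates(-35, "m", inh)
  expect_equal(r$alpha, 1, tolerance = 1e-6)
  # just off the singularity the formula itself must agree
  eps <- 1e-3
  expect_equal(gating_rates(-35 + eps, "m", inh)$alpha,
               0.1 * eps / (1 - exp(-0.1 * eps)), tolerance = 1e-9)

  # M-current gate: sigmoid midpoint at -35 mV
  p <- gating_rates(-35, "p", exc)
  expect_equal(p$x_inf, 0.5)
  # tau_p at the midpoint: tau_max / (3.3 + 1) with tau_max = 1 s
  expect_equal(p$tau_ms, 1000 / 4.3, tolerance = 1e-9)

  # excitatory K activation at its removable singularity (-40 mV)
  expect_equal(gating_rates(-40, "n", exc)$alpha, 0.032 * 5, tolerance = 1e-6)

  # time constants follow the 0.2/(alpha+beta) convention
  r2 <- gating_rates(-60, "n", inh)
  expect_equal(r2$tau_ms, 0.2 / (r2$alpha + r2$beta), tolerance = 1e-12)
  expect_equal(r2$x_inf, r2$alpha / (r2$alpha + r2$beta), tolerance = 1e-12)

  expect_error(gating_rates(-60, "p", inh), "unknown channel")
})

test_that("ionic currents follow the gating-power laws and sign convention", {
  st <- list(vm_mv = -100, n = 0.6, m = 0.2, h = 0.5,
             m_ca = 0.1, h_ca = 0.2, p = 0.3, m_can = 0.1)
  cur <- ionic_currents(st, exc)
  expect_equal(cur$i_k, 0)               # V = E_K: zero driving force
  st$n <- 0; st$vm_mv <- -50
  expect_equal(ionic_currents(st, exc)$i_k, 0)   # closed gate

  # hand unit conversion: n = 1, Vm = -50 =>
  # I_K = 5 mS/cm2 * 29e3 um2 * 50 mV = 5e-3 S/cm2 * 29e-5 cm2 * 5e-2 V
  #     = 7.25e-8 A = 72.5 nA
  st$n <- 1
  expect_equal(ionic_currents(st, exc)$i_k, 72.5, tolerance = 1e-9)

  expect_error(ionic_currents(list(vm_mv = -50, n = 1.2), inh), "outside")
})

test_that("calcium pool has the stated fixed point and relaxation", {
  # zero current at the resting concentration: exact fixed point
  expect_equal(calcium_update(exc$ca_inf, 0, 0.1, exc), exc$ca_inf)

  # relaxation from above with zero current: time constant 1 s
  ca <- 1.0
  for (i in 1:10000) ca <- calcium_update(ca, 0, 0.1, exc)   # 1 s
  expect_equal(ca, exc$ca_inf + (1 - exc$ca_inf) * exp(-1), tolerance = 1e-3)

  # constant depolarising (negative) current: steady state ca_inf + tau*gamma
  faraday <- 96485.33212
  i_ca <- -0.5
  gamma_ms <- -exc$k_u * (i_ca * 1e-6 / exc$area_cm2) /
    (2 * faraday * exc$depth_um) * 1e3
  expected <- exc$ca_inf + exc$tau_ca_ms * gamma_ms
  ca <- exc$ca_inf
  for (i in 1:80000) ca <- calcium_update(ca, i_ca, 0.1, exc)  # 8 s >> tau
  expect_equal(ca, expected, tolerance = 1e-3 * expected)

  # floored at zero for extreme outward current
  expect_equal(calcium_update(0.001, 1e6, 0.1, exc), 0)
})

test_that("a channel-free membrane is the analytic leaky integrator", {
  lk <- cell_class("inhibitory", g_k = 0, g_na = 0)
  i0 <- 0.05
  out <- simulate_neuron(lk, rep(i0, 5000), dt_ms = 0.1, v0_mv = lk$e_l)
  # V(t) = E_L + (I/gL)(1 - e^(-t/tau)), tau = C/gL
  g_us <- lk$g_l * lk$area_cm2 * 1e3
  c_nf <- lk$capacitance_uf_cm2 * lk$area_cm2 * 1e3
  tau <- c_nf / g_us
  t <- (1:5000) * 0.1
  expect_equal(out$vm_mv, lk$e_l + (i0 / g_us) * (1 - exp(-t / tau)),
               tolerance = 1e-3)
})

test_that("isolated neurons rest stably and fire under tonic drive", {
  for (cl in list(exc, inh)) {
    out <- simulate_neuron(cl, rep(0, 20000), v0_mv = cl$e_l)
    expect_length(out$spike_times_ms, 0)
    expect_lt(abs(out$vm_mv[20000] - out$vm_mv[10000]), 0.5)
  }
  # strong tonic input: periodic spiking; the reported spike count matches an
  # independent count of upward threshold crossings of the voltage trace
  out <- simulate_neuron(exc, rep(0.6, 20000))
  v <- out$vm_mv
  up <- which(v[-1] >= -20 & v[-length(v)] < -20)
  up <- up[c(TRUE, diff(up) > 20)]   # 2 ms hold-off, as in the detector
  expect_gt(length(out$spike_times_ms), 10)
  expect_equal(length(out$spike_times_ms), length(up))
  # gates and calcium stay in range throughout
  expect_true(all(out$ca_molar >= 0))
  st <- out$state
  gates <- unlist(st[c("n", "m", "h", "m_ca", "h_ca", "p", "m_can")])
  expect_true(all(gates >= 0 & gates <= 1))
})

test_that("noise-free trajectories are bitwise reproducible", {
  a <- simulate_neuron(exc, rep(0.3, 5000))
  b <- simulate_neuron(exc, rep(0.3, 5000))
  expect_identical(a$vm_mv, b$vm_mv)
  # and noisy ones reproduce under the same seed
  c1 <- simulate_neuron(inh, rep(0.1, 5000), noise = TRUE, seed = 5)
  c2 <- simulate_neuron(inh, rep(0.1, 5000), noise = TRUE, seed = 5)
  expect_identical(c1$vm_mv, c2$vm_mv)
})

test_that("I-F curves are monotone and reach the gamma range", {
  grid <- seq(0, 1, by = 0.2)
  for (cl in list(exc, inh)) {
    ifc <- if_curve(cl, grid, duration_ms = 600)
    expect_equal(ifc$rate_hz[1], 0)                  # far below rheobase
    # non-decreasing within one-spike tolerance (1 spike / 0.5 s = 2 Hz)
    expect_true(all(diff(ifc$rate_hz) >= -2))
    expect_true(any(ifc$rate_hz >= 30 & ifc$rate_hz <= 120))
  }
  expect_error(if_curve(exc, numeric(0)), "non-empty")
})

test_that("removing the CAN conductance abolishes the calcium-gated current", {
  nocan <- cell_class("excitatory", g_can = 0)
  out <- simulate_neuron(nocan, rep(0.5, 10000))
  expect_true(all(out$i_can_na == 0))
  # and its class parameters reject negative conductances
  expect_error(cell_class("excitatory", g_can = -1), "conductances")
  expect_error(cell_class("excitatory", bogus = 1), "unknown")
})
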