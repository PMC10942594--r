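# thetanest

Theta-nested gamma oscillations — gamma-band (30–120 Hz) activity whose
amplitude waxes and wanes with the phase of the underlying theta rhythm
(4–12 Hz) — are a core electrophysiological signature of hippocampal memory
processing, and a prime readout for hippocampal neurostimulation.  Studying
stimulation computationally requires a theta source whose *phase can be
reset* by network activity, which rules out the fixed sinusoidal drives of
classical models.

`thetanest` implements a hybrid closed-loop model of the septo-hippocampal
system for exactly this purpose, aimed at computational neuroscientists and
neuroengineers who want to prototype stimulation protocols against
biophysically grounded oscillations:

* **Medial septum** — an ensemble of Kuramoto phase oscillators
  (`kuramoto_params()`, `init_ensemble()`, `step_ensemble()`):

  dθᵢ/dt = ωᵢ + (k/N) Σⱼ sin(θⱼ − θᵢ) + G_reset · X(t) · Z(θᵢ),

  whose order parameter r = N⁻¹ Σ e^{jθᵢ} yields a rectified-cosine theta
  drive I_θ = G_θ (A cos φ + 1)/2.  The biphasic phase-response function
  Z(θ) = −sin(θ − θ_peak) lets the CA1 population rate X(t) reset the
  rhythm toward its peak — phase advance on the ascending slope, delay on
  the descending slope.

* **Hippocampal formation** — EC, DG, CA3 and CA1, each one excitatory and
  one fast-spiking inhibitory population of single-compartment
  Hodgkin–Huxley neurons (Na, K, Ca, CAN and M currents for pyramidal and
  granule cells; Wang–Buzsáki kinetics for basket cells), spatially
  embedded in a parametric slice and wired by distance-dependent rules
  (`build_network()`, `run_simulation()`).  Gamma arises from the
  pyramidal–interneuron (PING) loop; the slow CAN/M current interplay
  produces rebound responses to stimulation.

* **Stimulation protocols** (`stim_protocol()`) — single pulses, pulses
  triggered at a target theta phase, and theta-frequency pulse trains.

* **Analysis stack** — instantaneous rates, Welch spectra and Simpson band
  power, spectrograms, the Kullback–Leibler modulation index with
  uniform-noise correction, comodulograms, preferred-phase profiles, and
  phase-response curves (`modulation_index()`, `comodulogram()`,
  `compute_prc()`, …).

* **Tuning** (`tune_gains()`) — the six-step sequential heuristic that sets
  the theta gain and inter-area connection strengths against the 6 Hz
  firing/oscillation targets.

* A **Wilson–Cowan neural-mass variant** of the same loop
  (`run_mass_model()`), demonstrating that theta reset by an activity-fed
  Kuramoto ensemble generalises across model classes.

## Worked example: gamma from a ramp-driven E-I circuit

The elementary building block is one excitatory–inhibitory circuit.  Under
a current ramp to both populations, oscillations emerge once the input
overcomes interneuron-mediated inhibition, and settle in the gamma band:

```r
library(thetanest)

net <- ei_circuit(n_exc = 1000, n_inh = 100,
                  config = network_config(seed = 7))
n_steps <- 50000                                    # 5 s at dt = 0.1 ms
ramp <- list(current_na = matrix(seq(0, 1, length.out = n_steps), ncol = 1),
             groups = list(seq_len(nrow(net$layout))))
tr <- run_simulation(net, duration_s = 5, ext = ramp, seed = 11)

r  <- trace_rate(tr, cell = "exc")                  # 5 ms bins, 90% overlap
fs <- attr(r, "fs_hz")
dominant_frequency(tail(r$rate_hz, 2000), fs, band = c(20, 120))
#> [1] 57
population_rate(tr, cell = "exc", window_ms = c(4000, 5000))
#> [1] 18.637
population_rate(tr, cell = "inh", window_ms = c(4000, 5000))
#> [1] 41.31
```

In the final second of the ramp the excitatory population rate oscillates
at 57 Hz (spectrogram ridge at 60 Hz) — the PING rhythm — while individual
pyramidal cells fire at ~19 Hz and interneurons at ~41 Hz: the population
oscillates faster than any single excitatory cell fires, the hallmark of
sparse gamma.  Decoupling the populations (`ei_circuit(coupled = FALSE)`)
abolishes the rhythm.

The closed-loop model is built the same way at any scale:

```r
net <- build_network(network_config(scale = 0.1, seed = 5))
tr  <- run_simulation(net, duration_s = 8, seed = 42)
plot(tr)                      # raster + theta drive
summary(tr, window_ms = c(2000, 8000))
```

A thin command-line front end over these functions is installed at
`inst/cli/thetanest.R` (subcommands `simulate`, `tune`, `analyze`,
`mass-demo`, `fixtures`).

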