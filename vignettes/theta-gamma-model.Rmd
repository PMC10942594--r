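---
title: "A hybrid septo-hippocampal model of theta-nested gamma oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid septo-hippocampal model of theta-nested gamma oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(thetanest)
```

## The model

`thetanest` couples two levels of description into one closed loop:

* **Medial septum.** An ensemble of `N` Kuramoto phase oscillators stands in
  for the septal pacemaker population.  Each phase obeys
  $$\dot\theta_i = \omega_i + \frac{k}{N}\sum_j \sin(\theta_j - \theta_i)
    + G_{reset}\, X(t)\, Z(\theta_i),$$
  with natural frequencies $\omega_i \sim \mathcal N(2\pi f_0, 2\pi\sigma)$
  ($f_0 = 6$ Hz, $\sigma = 0.5$ Hz, $N = 250$, $k = 15$ by default).  The
  collective state is summarised by the order parameter
  $r = N^{-1}\sum_i e^{j\theta_i}$; its modulus $A$ and argument $\phi$
  define the theta drive delivered to the entorhinal cortex as a rectified
  cosine, $I_\theta = G_\theta (A\cos\phi + 1)/2 \in [0, G_\theta]$.  The
  feedback signal $X(t)$ is the instantaneous CA1 pyramidal population rate
  (exponential kernel, $\tau_{FR} = 10$ ms), and the biphasic phase-response
  function $Z(\theta) = -\sin(\theta - (\theta_{peak} + \phi_{offset}))$
  advances the rhythm when CA1 fires on the ascending slope of theta and
  delays it on the descending slope.  This is what produces theta phase
  reset: a strong CA1 volley pulls every oscillator toward the theta peak.

* **Hippocampal formation.** Four areas (EC, DG, CA3, CA1), each with one
  excitatory population (pyramidal cells; granule cells in DG) and one
  population of fast-spiking basket cells, placed on a parametric coronal
  slice and wired by distance-dependent probabilistic rules.  Excitatory
  cells are single-compartment Hodgkin-Huxley neurons with leak, transient
  Na, delayed-rectifier K, high-threshold Ca, calcium-activated non-specific
  cation (CAN) and M-type K currents; interneurons carry the Wang-Buzsaki
  Na/K set.  Synapses are conductance-based with biexponential kinetics;
  a presynaptic spike increments the driver variable by a fixed amount set
  per connection type by the wiring tables (`wiring_defaults()`).

Gamma oscillations arise within each area from the pyramidal-interneuron
(PING) loop; the theta drive gates them cyclically, yielding theta-nested
gamma; the CA1→septum feedback closes the loop and adds phase reset.

## Parameter provenance and interpretation choices

The cell, synapse and wiring constants are the reference values of the
conductance-based septo-hippocampal model this package implements.  A few
entries of that parameterisation are internally ambiguous, and the package
resolves them toward the canonical source formalisms the model descends
from (Traub-Miles/Pospischil pyramidal kinetics, Wang-Buzsaki interneurons,
Destexhe calcium pool and CAN gate).  These choices were made once, on
mechanistic grounds, and are recorded here:

* **Gate time constants.**  The steady-state/time-constant form
  $\tau = 0.2/(\alpha+\beta)$ is used for the interneuron gates and the CAN
  gate, where the $0.2$ is exactly the conventional $\phi = 5$ temperature
  factor of those formalisms.  The pyramidal-cell voltage gates use
  $\tau = 1/(\alpha+\beta)$, as in their source models.  With $\phi = 5$
  applied to pyramidal gates as well, spikes become ~0.5 ms wide, calcium
  entry per spike drops several-fold, and the CAN/M rebound (below) cannot
  occur at all.
* **The M current** uses $p_\infty = 1/(1+e^{-(V+35)/10})$ and
  $\tau_p = 1000/(3.3 e^{(V+35)/20} + e^{-(V+35)/20})$ ms (about 233 ms near
  rest).  This slow time constant is what sets the ~200 ms silent window
  between the immediate and the rebound response to a strong pulse.
* **The calcium pool** is expressed in micromolar (resting value
  $0.24\,\mu$M, removal time constant 1 s) with the standard
  submembrane-shell influx $\gamma = -k_u\, (I_{Ca}/A) / (2 F d)$, and the
  CAN gate opens with the quadratic activation law
  $\alpha = \beta\,([Ca]/0.5\,\mu\mathrm{M})^2$.  One action potential
  admits roughly $0.5$-$0.8\,\mu$M, so a stimulation-evoked volley pushes
  the CAN conductance from near-closed to more than half-open while the
  M current is still saturating - the competition that shapes the rebound.
* **Membrane noise** is a per-step Gaussian voltage perturbation scaled as
  $\sqrt{dt/1\,\mathrm{ms}}$ with SD 1000 uV (excitatory) and 100 uV
  (inhibitory) at the 1 ms reference step.  This makes the stationary
  voltage fluctuation about 5 mV in pyramidal cells: strong enough to break
  the artificial input-locked synchrony of uncoupled populations, weak
  enough that undriven populations stay silent (quoting the printed SDs at
  a 0.1 ms reference instead produces ~15 mV fluctuations and tonic
  spurious firing, contradicting the silent baseline that the stimulation
  experiments require).
* **Synaptic kinetics** (not part of the reference tables) default to
  textbook values: AMPA-like rise 0.3 ms / decay 5 ms, GABA-A-like rise
  1 ms / decay 10 ms, reversal 0 / -80 mV.  All four constants are exposed
  in `synapse_params()` and the run configuration.

## Numerical scheme

All components share one clock (default $dt = 0.1$ ms).  Gates use
exponential Euler (exact for a frozen voltage); the membrane potential and
the calcium pool use explicit Euler; the synaptic cascade uses the *exact*
solution of its linear ODEs over one step, so a single-spike conductance
transient matches the closed-form biexponential to machine precision at any
step size.  Oscillator phases advance by explicit Euler with the CA1 rate
of the previous step (one-step lag).  Within the compiled integrator the
gate steady states and decay factors are tabulated on a 0.02 mV grid and
linearly interpolated; the exact rate functions remain the single source of
truth (they are re-tabulated for each run's $dt$, and `gating_rates()`
always evaluates them exactly).  Runs are bit-reproducible for a given
seed; membrane noise uses a fast counter-based generator seeded from R's
RNG stream.

## Spatial embedding and the desk-scale harness

Neurons are placed by blue-noise (Poisson-disk) sampling inside each
stratum polygon, relaxed toward a centroidal Voronoi configuration by
discrete Lloyd iterations (capped at 1000, early stop at $10^{-6}$ relative
energy change), and given a uniform third coordinate across the 15 mm
slice.  Intra-area connection probabilities decay with full 3D distance
($\sigma = 2500\,\mu$m excitatory, $350\,\mu$m inhibitory); inter-area
projections are excitatory only and depend on the z-distance alone
($\sigma = 1000\,\mu$m, probability clipped at 1).

The reference network has 32,200 neurons; most experiments here run at a
reduced scale.  Two properties must survive scaling for the dynamics to be
comparable: the *coverage* of the narrow inhibitory kernel (every pyramidal
cell should keep inhibitory partners) and the *mean drive* each neuron
receives per population spike.  Subsampling neurons inside the fixed
geometry destroys the former (at 10% scale almost no inhibitory pairs
remain within 350 um).  The scaled harness therefore shrinks the slice
thickness together with the populations - preserving volumetric density
and kernel coverage - and multiplies the conductance increments of each
wiring rule by the closed-form ratio of expected kernel masses
(`z_kernel_mean()`), which restores the expected in-degree x weight
product of every rule exactly.  The reduced E-I circuit used for the ramp
and pulsed-drive experiments is instead wired point-locally (probabilities
at zero distance): it represents one local module, not a thinned slice.

## Tuning

`tune_gains()` implements the sequential heuristic that sets the theta gain
and the five inter-area connection strengths against the 6 Hz targets
(each excitatory cell one spike per theta cycle; collective rhythm at the
driving frequency), minimising the Euclidean distance
$J = \sqrt{(f_{exc}-6)^2 + (f_{osc}-6)^2}$ step by step: theta gain on
uncoupled EC; EC→DG; the joint (EC, DG)→CA3 pair; the joint
(EC, CA3)→CA1 pair; CA1→EC under a temporary 6 Hz sinusoidal drive with
CA1 decoupled; then the feedback strength is halved, the loop restored and
the theta gain re-tuned.  Tuning runs without membrane noise and ties are
broken toward the smaller value (the weakest sufficient drive).  The
reference grids are 0-0.5 nA in 0.01 nA steps for the gain, 0-20 in 0.1
steps for EC→DG and 0-5 in 0.1 steps for the rest.  At desk scale the
same argmin is found with coarse grids plus successive local refinement
around the running argmin (`refine_points`); this matters because a
population's recruitment can switch on over a gain window narrower than
any affordable uniform grid.

## What the analyses compute

* `binned_rate()`: spike counts in 5 ms windows with 90% overlap,
  normalised to spikes/s per neuron (2 kHz series).
* `welch_psd()` / `band_power()`: Welch average of Hann-tapered 1 s
  segments with 90% overlap (1 Hz resolution); band power by Simpson
  integration.
* `spectrogram_stft()`: Hann short-time Fourier transform, 100 ms windows,
  99% overlap (10 Hz resolution).
* `modulation_index()`: zero-phase FIR band-pass of the phase (3-9 Hz) and
  amplitude (40-80 Hz) bands, Hilbert phase/amplitude, mean amplitude in 72
  phase bins of 5 degrees, and the Kullback-Leibler divergence of that
  histogram from uniform, normalised by $\log 72$ so the index lies in
  $[0, 1]$.
* `comodulogram()`: the same index over 1 Hz-wide phase bands (80% overlap)
  and 10 Hz-wide amplitude bands (90% overlap).  Band-limited simulated
  rates can be flat inside a narrow band, which makes the raw index
  spuriously large; uniform noise with amplitude 20% of the signal maximum
  is added first (the seed is recorded in the result).
* `preferred_phase()`: amplitude-by-phase profiles for 10 Hz-wide gamma
  bands between 20 and 100 Hz, reporting the phase of maximal amplitude.
* `compute_prc()` / `prc_network()`: the empirical phase-response curve -
  paired stimulated/unstimulated runs per phase bin (width $\pi/8$) and
  amplitude, comparing the theta phase 2.5 ms after the pulse; positive
  differences are phase advances.

## A worked desk-scale example

A small closed-loop run (5% scale, for speed; the shapes sharpen with
size):

```{r example, eval = FALSE}
net <- build_network(network_config(scale = 0.05, seed = 5))
tr <- run_simulation(net, duration_s = 4, seed = 42, theta_gain_na = 0.25)
summary(tr, window_ms = c(1000, 4000))

r <- trace_rate(tr, "CA1", "exc")
fs <- attr(r, "fs_hz")
psd <- welch_psd(r$rate_hz[r$time_ms > 1000], fs)
plot(psd$freq_hz, psd$psd, type = "l", xlim = c(0, 100), log = "y")
modulation_index(r$rate_hz[r$time_ms > 1000], fs)
```

## What the synthetic generators do and do not show

`pac_signal()` builds a gamma carrier whose envelope follows the phase of a
slow cosine with a controllable depth, plus the slow component and white
noise; it is the ground-truth input for validating the coupling analyses
(a depth of 0 must give an index near 0, a depth of 1 must put the
comodulogram maximum at the constructed band pair).  `poisson_spikes()`
provides rate-calibrated spike tables for the rate estimators.  Passing
these checks shows that the analysis stack measures what it claims on
signals with known structure; it does not by itself validate the network
model, whose checks are the emergent-behaviour experiments (ramp-driven
gamma, theta-nested gamma, CAN rebound, phase reset) in the test suite and
the acceptance script.

## Problem sizes used by the reproduction script

`scripts/acceptance.R` re-runs every experiment from scratch: the ramp and
pulsed-drive experiments use the printed reduced-circuit size (1000
excitatory, 100 inhibitory neurons); the closed-loop experiments use the
desk-scale harness at 10% scale (3,220 neurons), with the tuning procedure
run at 5% scale with coarse-plus-refinement grids and 2 s evaluation runs
(final second analysed).  These sizes are the package's reference
desk-scale configuration; the full 32,200-neuron, 15 mm parameterisation
is what `network_config(scale = 1)` builds.

## Known limitations

* One theta generator, one interneuron class; no OLM cells, no synaptic
  plasticity, no conduction delays, no extracellular stimulation physics -
  all outside the model class.
* The rebound response to single pulses is reproduced mechanistically
  (CAN-dependent, ~200 ms), but its amplitude sits close to threshold in
  this reconstruction: the rebound is noise-assisted, weaker than the
  immediate burst, and followed by low-rate sputter on the CAN plateau, so
  burst *counts* are sensitive to the detection threshold in a way the
  published figure is not.
* The anatomical slice is parametric (nested annular bands), not traced
  from an atlas; only distance statistics, not shapes, are meaningful.
* Desk-scale runs preserve mean drive and kernel coverage but not
  finite-size fluctuation statistics; quantities tied to population counts
  (e.g. absolute rate variance) differ from the full-scale model.
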