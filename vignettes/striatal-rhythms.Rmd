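---
title: "Modelling striatal gamma, beta and delta/theta rhythms with striatr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling striatal gamma, beta and delta/theta rhythms with striatr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`striatr` is a conductance-based simulator of striatal microcircuits built to
study how dopamine reshapes the interplay of three rhythms recorded in
striatal local field potentials: gamma (40-100 Hz), beta (8-30 Hz), and a
slow delta/theta (1-10 Hz) modulation. This vignette describes the model, its
assumptions, the tunable parameters, the background-drive (noise) model, the
analysis layer, and the numerical and design choices a user should know
before trusting — or extending — the results.

## The cells

**Fast-spiking interneurons (FSIs)** are two-compartment Hodgkin-Huxley
models (soma + dendrite). Each compartment carries a transient sodium
current (activation treated as instantaneous, `m = m_inf(V)`, cubed, with one
inactivation gate), a fast potassium current (two activation gates), a leak,
and a D-type potassium current with three fast activation gates
(`tau_a` = 2 ms) and one slowly inactivating gate (`tau_b` = 150 ms).
Dendritic maximal conductances are one tenth of the somatic values, and the
compartments are coupled ohmically (0.5 mS/cm^2), exchanging equal and
opposite currents. External drive — a tonic, dopamine-dependent current plus
Poisson noise — enters the dendrite; GABA-A inhibition targets the soma;
gap junctions couple dendrites.

The D-current is the interesting piece. Burst spiking activates it; its slow
inactivation variable then hyperpolarises the cell for hundreds of
milliseconds, producing gamma-frequency spike bursts recurring at
delta/theta frequency, and a *minimum firing rate*: at the default
conductance (6 mS/cm^2) the cell cannot fire sustained rhythms below about
40 Hz. Removing the D-current (`g_D = 0`) abolishes both the bursting and
the minimum rate:

```{r, eval = FALSE}
library(striatr)
mfr <- minimum_firing_rate()                      # ~44 Hz at rheobase
mfr0 <- minimum_firing_rate(fsi_params(g_D = 0),
                            I_grid = seq(0, 8, by = 0.1), refine = TRUE)
mfr0$rate                                         # falls towards zero
```

**Spiny projection neurons (SPNs)** are single-compartment cells with
sodium, potassium, leak, and an M-type (slow, non-inactivating) potassium
current. M-current kinetics are scaled from their 23 degree reference
temperature to 37 degrees by `Qs = Q10^((37-23)/10) = 2.3^1.4 = 3.209`. The
M-current's recovery timescale (~50 ms rebound) is what gives SPN networks
their beta rhythm: inhibition (or its release) is followed by rebound
spiking paced at beta. D1- and D2-receptor SPNs are identical except for
their tonic drive under high dopamine.

## The network

Default populations: 50 FSIs, 100 D1 SPNs, 100 D2 SPNs. Each unordered FSI
pair has an independent 33% chance of a dendro-dendritic gap junction and a
58% chance of a (reciprocal) somato-somatic inhibitory synapse; each FSI
contacts each SPN with probability 37.5%; SPNs inhibit all other SPNs of the
same receptor type, with no D1-D2 cross-inhibition and no SPN-to-FSI
feedback. GABA-A synapses have a 13 ms decay everywhere; FSI-sourced
synapses open with a fast 0.25 ms rise constant. Conductances onto SPNs are
normalised by the target population size (0.6/n feedforward, 0.1/n
recurrent), preserving a 6:1 ratio of feedforward to recurrent inhibition at
any size; the FSI-FSI conductance is not normalised.

Because every directed GABA-A synapse from a given presynaptic cell obeys
the same gate equation driven by the same presynaptic voltage (and starts
closed), the engine integrates one gate per presynaptic cell and forms
postsynaptic sums through the adjacency matrix. This is an exact reduction,
not an approximation.

**Dopamine** is a bundle of five parameter changes (see
`dopamine_condition()`): FSI tonic drive 7 vs 14 uA/cm^2, gap-junction
conductance 0.15 vs 0.3 mS/cm^2, FSI-FSI inhibition 0.1 vs 0.005 mS/cm^2,
and D1/D2 drives 1.19/1.19 vs 1.29/1.09 uA/cm^2.

## Background drive and what "noise" means here

Each FSI receives an independent 100 events/s Poisson train on its dendrite.
The event waveform is not constrained by the modelling literature this
implements, so it is configurable: the default is a single-integration-step
rectangular pulse of amplitude 1200 uA/cm^2 (i.e. 12 uA*ms/cm^2 of charge
per event, a ~1.2 mV dendritic kick); a one-sided exponential kernel (1 ms
decay) is available. The default amplitude was calibrated once, before any
network-level measurement, against two stated behaviours of the reference
system: (i) a single FSI at baseline drive (7 uA/cm^2) with 100/s input
shows theta-range (4-7 Hz) interburst frequencies — amplitudes from roughly
400 to 1500 satisfy this; and (ii) within that admissible range, the upper
part was chosen because the baseline FSI *network* is then asynchronous
(sparse, independent bursting), as described for the modelled system;
with much weaker noise the gap junctions lock all cells into synchronized
slow population bursts even at baseline. This amplitude was then frozen.

SPNs receive additive Gaussian current noise of mean zero, unit standard
deviation, and amplitude `4*dt` per step — implemented literally as printed
in the source description, although the scaling is dimensionally suspect
(its effect vanishes as `dt` shrinks; at `dt` = 0.01 ms it is negligible).
A `sqrt_dt` switch is provided for the diffusion-consistent reading.
Desynchronisation of SPNs comes mainly from random initial voltages, drawn
per cell from U(-90, -50) mV with gates at steady state.

## Integration

The full state (cell compartments, gates, synapse gates) is advanced by
classical fixed-step RK4 at `dt` = 0.01 ms, in compiled code. Noise is held
constant across the four stages of a step. Gates are clamped to [0,1] only
against rounding-level overshoot (1e-12); anything larger raises an error,
as does any non-finite state or |V| > 500 mV, naming the offending
component. Spikes are detected online as upward 0 mV crossings with a 2 ms
refractory period. Traces are recorded at 10 kHz (stride 10) by default.
Self-convergence of the integrator on the smooth (subthreshold) FSI
trajectory has measured order ~4; halving `dt` moves voltage traces by well
under 1e-3 mV.

Determinism: all randomness (initial conditions, connectivity, noise) flows
from user-visible seeds through R's RNG; identical configuration + seed
reproduces results bit for bit.

## Analysis layer

The surrogate LFP is the sum of GABA-A synaptic currents over a chosen cell
set (gap-junction currents can be included via a flag; the default reads
"synaptic" as chemical synapses only). Spectra use Thomson's multitaper
method with DPSS tapers computed in-package from the symmetric tridiagonal
formulation (time-bandwidth 4, 7 tapers by default, demeaned series,
decimated to 1 kHz — all rhythms of interest are below 100 Hz). Integrated
PSD matches series variance to within 5% on the traces the pipeline
analyses (network LFPs and mean voltages; ~1% in practice). On very short
or impulse-like traces the taper energy profile under-weights the series
edges and the mismatch can exceed that — a generic property of multitaper
estimates, not of this implementation. Band peaks are argmaxes
restricted to the band definitions (delta/theta 1-10 Hz, beta 8-30 Hz,
gamma 40-100 Hz with low/high subdivisions).

Burst statistics segment a spike train at a 25 ms inter-spike-interval
threshold — an order of magnitude separates gamma-rate intraburst intervals
(~15-25 ms) from delta/theta interburst gaps (150-1000 ms), so the result
is insensitive to the exact cut. Band-limited traces and envelopes come from
a Morlet (omega0 = 6) continuous wavelet transform with standard
reconstruction constants; phase-amplitude coupling is summarised by the
envelope-weighted mean resultant vector of the slow-band phase.

## What the model reproduces, and what it does not

With default parameters the package reproduces, across seeds:

* single-FSI regimes: quiescence, periodic bursting (low-gamma intraburst
  near rheobase, high-gamma at strong drive), and tonic spiking; a ~44 Hz
  minimum firing rate at `g_D` = 6 and none at `g_D` = 0;
* the high-dopamine FSI network: a ~75 Hz gamma rhythm whose amplitude is
  modulated at ~3 Hz, visible in raster, LFP, spectrogram and
  phase-modulation depth;
* isolated driven D1 SPN networks: a 20 Hz beta peak; and the combined
  high-dopamine network: D1 beta near 19-20 Hz, D2 low beta near 11 Hz,
  FSI gamma near 74 Hz, with the SPN beta envelope anticorrelated with the
  FSI gamma envelope and gamma locked to the delta/theta phase;
* paradoxical excitation: SPN populations under FSI inhibition fire more
  than warranted by their tonic drive, via M-current rebound.

Three quantitative discrepancies against the reference system are
documented rather than patched, since every printed constant has been
verified:

* the *baseline* FSI network's gamma sits at 43-47 Hz rather than ~60 Hz.
  In this implementation the baseline network rhythm is paced by the cells'
  D-current minimum rate (cells hover near effective rheobase under strong
  mutual inhibition), not by the inhibitory decay constant; the reference
  behaviour is an inhibition-paced rhythm some 15 Hz faster. Gap-junction
  strength, inhibition scaling, and noise settings within the calibrated
  range were all explored without closing the gap.
* the SPN rheobase falls at ~1.17 uA/cm^2, a hair below the baseline drive
  of 1.19, so isolated SPN populations fire slowly at baseline instead of
  staying silent. The beta-frequency results are unaffected.
* the D2 subpopulation's beta under high dopamine sits near 11 Hz rather
  than ~15 Hz: in this implementation beta frequency falls more steeply
  with decreasing tonic drive than in the reference system (D1 at
  1.29 uA/cm^2 gives exactly 20 Hz; the combined-baseline SPNs at 1.19
  give 12-13 Hz; D2 at 1.09 gives ~11 Hz).

The synthetic background drive emulates in-vivo-like irregular excitation
only in a minimal sense (homogeneous Poisson, stationary Gaussian); real
striatal input is patterned and state-dependent, so passing tests here says
nothing about responses to structured cortical input, which is out of scope.
Other intentional exclusions: SPN inward-rectifier (Kir) currents and
up/down states (the modelled regime is the awake state), D1-D2
cross-inhibition, SPN-to-FSI feedback, and distance-dependent connectivity.

## Problem sizes and reproducibility

`make_fixture()` pins three scales: `tiny` (5 FSI, 10+10 SPN, 0.5 s) for
unit tests, `small` (20, 40+40, 2 s) for integration-level checks, and
`paper` (50, 100+100, 4 s with a 1 s discarded transient) for full
experiments. Network spectra in the test-suite and in
`scripts/acceptance.R` are medians over five seeds at the `paper` scale;
single-cell sweeps use 3-6 s noise-free runs. The 1 s transient is excluded
from every spectral estimate; noise stays on during the transient.

## Worked example

```{r, eval = FALSE}
library(striatr)
spec <- network_spec(n_fsi = 50, n_d1 = 1, n_d2 = 1, seed = 17)
sim <- simulate_network(spec, dopamine_condition("high"),
                        integration_settings(t_total = 4000, seed = 17),
                        noise_spec(), populations = "fsi_only")
ps <- multitaper_psd(surrogate_lfp(sim, "fsi"))
tidy(ps)          # band peaks: gamma near 75 Hz, delta/theta near 3 Hz
autoplot(ps)
autoplot(sim)     # raster: gamma bursts recurring at delta/theta
```

## Known limitations

Beyond the two documented discrepancies: the rectangular event kernel is a
modelling convenience (a conductance-based synaptic drive would interact
with membrane potential); per-directed-edge FSI-FSI inhibition is available
behind a switch but reciprocal-per-pair is the default reading of the
pairwise connection probability; and the assembly-pulse protocol reports a
pairwise coincidence synchrony index within 5 ms windows, one of several
defensible coherence definitions.
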