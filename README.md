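# striatr

Biophysical simulation of striatal microcircuit rhythms in R.

Striatal local field potentials show dopamine- and reward-dependent
transitions between a "spontaneous" state carrying beta (~15-30 Hz) and low
gamma (~40-60 Hz) oscillations and an activated state in which high gamma
(~60-100 Hz) is nested inside a delta/theta (~1-10 Hz) modulation. `striatr`
implements a conductance-based model of the circuits thought to generate
these rhythms — networks of striatal fast-spiking interneurons (FSIs) and
spiny projection neurons (SPNs) — together with the measurement pipeline
needed to quantify them, for computational neuroscientists studying basal
ganglia dynamics and for anyone needing a compact, fully reproducible
spiking-network testbed with a spectral analysis layer.

## The model

All cells follow Hodgkin-Huxley dynamics,

```
c_m dV/dt = - sum I_memb - sum I_syn + I_app,
I = g_max * m^n h^k * (V - E_ion),
```

with voltages in mV, currents in uA/cm^2, conductances in mS/cm^2 and time
in ms.

* **FSI**: two compartments (soma, dendrite; dendritic conductances scaled
  by 1/10, ohmic coupling 0.5 mS/cm^2) with transient Na (m_inf^3 h), fast
  K (n^2), leak, and a D-type potassium current (a^3 b) whose slow
  inactivation (tau_b = 150 ms) produces gamma-frequency spike bursts
  recurring at delta/theta and imposes a ~40 Hz minimum firing rate.
* **SPN**: one compartment with Na (m^3 h), K (n^4), leak, and an M-type
  potassium current (w) with rates scaled by Qs = 2.3^1.4 = 3.209 for body
  temperature; the M-current's ~50 ms rebound timescale paces the beta
  rhythm.
* **Coupling**: GABA-A synapses `g * s * (V - E_i)` with 13 ms decay
  (FSI-FSI 58%/pair reciprocal, FSI->SPN 37.5%, SPN->SPN all-to-all within
  receptor type), and dendro-dendritic gap junctions `g_gj (V_dj - V_di)`
  (33%/pair).
* **Dopamine** is a five-parameter bundle: baseline = FSI drive 7, g_gj
  0.15, FSI-FSI inhibition 0.1, D1 = D2 drive 1.19; high = 14, 0.3, 0.005,
  1.29, 1.09.

The integrator is fixed-step classical RK4 at dt = 0.01 ms (compiled, with
online spike detection); the analysis layer provides the surrogate LFP
(summed synaptic currents), multitaper spectra and spectrograms on DPSS
tapers, burst statistics, minimum-firing-rate estimation, Morlet wavelet
band envelopes, and phase-amplitude coupling summaries. Everything is
deterministic given a seed.

## Worked example

A 50-FSI network under high dopaminergic tone, and the spectrum of its
surrogate LFP:

```r
library(striatr)
spec <- network_spec(n_fsi = 50, n_d1 = 1, n_d2 = 1, seed = 17)
sim <- simulate_network(spec, dopamine_condition("high"),
                        integration_settings(t_total = 4000, seed = 17),
                        noise_spec(), populations = "fsi_only")
glance(sim)
#> # A tibble: 1 × 10
#>   t_total    dt n_fsi  n_d1  n_d2 condition n_spikes rate_fsi rate_d1 rate_d2
#>     <dbl> <dbl> <int> <int> <int> <chr>        <int>    <dbl>   <dbl>   <dbl>
#> 1    4000  0.01    50     1     1 high          5247     27.4       0       0

ps <- multitaper_psd(surrogate_lfp(sim, "fsi"))
tidy(ps)[, 1:5]
#> # A tibble: 5 × 5
#>   band         f_lo  f_hi peak_frequency peak_power
#>   <chr>       <dbl> <dbl>          <dbl>      <dbl>
#> 1 delta_theta     1    10           3.33     354.
#> 2 beta            8    30           8         22.5
#> 3 low_gamma      40    60          59.3        2.22
#> 4 high_gamma     60   100          75.7       29.2
#> 5 gamma_wide     40   100          75.7       29.2
```

Each FSI fires ~27 Hz; the network rhythm is a ~76 Hz gamma (the
`gamma_wide` argmax) whose amplitude waxes and wanes with a ~3.3 Hz
delta/theta modulation (the `delta_theta` peak, dominating the spectrum) —
the nested dual rhythm of the high-dopamine state. Under
`dopamine_condition("baseline")` the delta/theta peak shrinks towards the
band median and single cells fire sparsely instead. `autoplot(sim)` draws
the spike raster, `autoplot(ps)` the spectrum.

Isolated SPN populations and the full 250-cell microcircuit run the same
way (`simulate_spn_population()`, `populations = "combined"`), and
`run_condition_experiment()` bundles simulation + band summaries for the
canonical configurations.

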