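# gammaflow

Cortical circuits of recurrently coupled excitatory pyramidal cells and
fast-spiking inhibitory interneurons resonate in the gamma band
(30–90 Hz), and that resonance acts as a temporal filter: time-varying
excitatory input that is coherent with the circuit's intrinsic rhythm is
transmitted to spike output preferentially, while non-coherent components
are attenuated. `gammaflow` is an R package for studying this phenomenon
in silico. It is aimed at computational and systems neuroscientists who
want to simulate the standard model circuits, drive them with
optogenetic-style stimulus protocols, and push the output through the same
spectral analysis chain used on real recordings.

## What is inside

**Simulators** (Rcpp cores, bit-for-bit reproducible under a seed):

* `simulate_ping()` — the pyramidal–interneuron network gamma (PING)
  model: 200 reduced Traub–Miles pyramidal cells and 50 Wang–Buzsáki
  basket cells, Hodgkin–Huxley dynamics, two-variable synaptic gating,
  4th-order fixed-step integration at 0.02 ms. Variants: `ping_m` adds a
  non-inactivating M-type potassium current (g_M = 0.4 mS/cm²) to the
  excitatory cells, producing spike-frequency adaptation and hysteresis;
  `no_II` removes I-to-I coupling.
* `simulate_lif()` — a leaky integrate-and-fire E–I network with
  instantaneous synapses (forward Euler, `V = V + dt(-(V-E) + IR)/tau`,
  tau = 24 ms exactly).
* `simulate_gated()` — two excitatory populations sharing one inhibitory
  pool: E1↔I generates the rhythm, I→E2 gates a second population that
  projects to nothing.

**Stimulus protocols** (`generate_stimulus()`): constant, 3-s ramps, 10-s
single slow sines, slow Gaussian profiles, 5–80 Hz sinusoids, and
truncated Gaussian white noise updated at 1017.1 Hz with sd = mean/2
(`generate_white_noise()`).

**Analysis chain**: Gaussian spike densities, 4-cycle sliding-window
time–frequency power (`tf_power()`), stimulation/baseline power ratios,
gamma peak tracking, rising-vs-falling hysteresis curves and loop areas,
spike-triggered averages with null bands, pairwise phase consistency
(`ppc()`, the spike-count-unbiased locking measure
`(|Σe^{iθ}|² − n)/(n(n−1))`), Pearson cross-correlation modulation depth,
phase-slope latency (latency = −slope/2π of the relative-phase spectrum),
nonparametric spectral Granger causality via Wilson factorization of the
cross-spectral matrix (`estimate_csd()` → `factorize_spectral_matrix()` →
`granger_from_csd()`, with a 30%-of-trials bootstrap), and cluster-based
permutation tests of paired spectra (`cluster_permutation_test()`).

**Ground-truth fixtures**: bivariate autoregressions with closed-form
spectra and Geweke influence (`var_spec()`, `var_granger()`), von
Mises phase-locked spike trains whose population PPC is `(I₁(κ)/I₀(κ))²`
(`gen_locked_spikes()`), and delayed noisy responses
(`gen_lagged_response()`). Every estimator is validated against these.

Results are tibbles or small S3 objects with `tidy()`, `glance()` and
`autoplot()` methods, so everything composes with the tidyverse.

## Worked example

```r
library(gammaflow)

sim <- simulate_ping(duration = 2, seed = 1)   # default constant drive
glance(sim)
#> # A tibble: 1 × 6
#>   model duration n_spikes rate_e rate_i peak_freq
#>   <chr>    <dbl>    <int>  <dbl>  <dbl>     <dbl>
#> 1 ping         2    24179   48.7   46.9      48.5

re <- pop_rate(sim, "E")
spectral_peak(re$rate, sim$fs_out, band = c(10, 200), transient = 0.5)$freq
#> [1] 48.5
```

The default network fires at ≈ 49 spikes/s per excitatory cell and locks
into a collective rhythm at ≈ 48.5 Hz — one population volley per gamma
cycle; the field proxy (negated synaptic current onto the E pool) peaks at
the same frequency. Estimator calibration looks like this:

```r
g <- gen_locked_spikes(f_gamma = 40, kappa = 2, rate = 800,
                       duration = 5, seed = 1)
ppc(g$spike_times, g$signal, freqs = c(20, 40, 60))
#> # A tibble: 3 × 4
#>    freq   ppc n_spikes epoch_halfwidth
#>   <dbl> <dbl>    <int>           <dbl>
#> 1    20 0.533     3297            0.5
#> 2    40 0.488     3666            0.25
#> 3    60 0.505     3666            0.25
g$ppc_true
#> [1] 0.487
```

At the locking frequency (40 Hz) the measured PPC (0.488) matches the
analytic von Mises value (0.487). Canned scenarios — gamma resonance,
drive sweeps, hysteresis, sinusoidal entrainment and latency, white-noise
Granger causality, and the gated two-population circuit — are one call
away via `reproduce("hysteresis")` etc., and `run_protocol()` persists
fully provenanced CSV/JSON bundles from a YAML-round-trippable
`run_config()`.

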