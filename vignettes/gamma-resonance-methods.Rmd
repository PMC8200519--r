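---
title: "Models and estimators for gamma-band resonance and selective transmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators for gamma-band resonance and selective transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`gammaflow` implements the computational core of a line of work on how the
gamma-band (30–90 Hz) resonance of recurrently coupled excitatory–inhibitory
(E–I) cortical circuits filters time-varying excitatory drive: circuits
transmit input components that are coherent with their intrinsic rhythm and
attenuate the rest. The package has two halves:

* **simulators** — a conductance-based pyramidal–interneuron gamma (PING)
  network, its adapting variant with an M-current (PING+M), a leaky
  integrate-and-fire (LIF) network, and a gated circuit with two excitatory
  populations; and
* **estimators** — the analysis chain used on optogenetic recordings:
  stimulus protocols, Gaussian spike densities, sliding-window
  time–frequency power, hysteresis curves, spike-triggered averages (STA),
  pairwise phase consistency (PPC), phase-slope latency, nonparametric
  spectral Granger causality (GC) with bootstrap uncertainty, and
  cluster-based permutation statistics.

Every estimator can be validated against a synthetic fixture with a known
answer (`var_spec()`/`var_granger()`, `gen_locked_spikes()`,
`gen_lagged_response()`) without running any network model.

# The models

## PING

The excitatory pool consists of 200 reduced Traub–Miles (RTM)
single-compartment Hodgkin–Huxley cells (parameters `C = 1` µF/cm²,
`v_Na = 50`, `v_K = -100`, `v_L = -67` mV, `g_Na = 100`, `g_K = 80`,
`g_L = 0.1` mS/cm²), the inhibitory pool of 50 Wang–Buzsáki (WB) basket
cells (`v_Na = 55`, `v_K = -90`, `v_L = -65` mV, `g_Na = 35`, `g_K = 9`,
`g_L = 0.1`). Synapses use a two-variable gating scheme: presynaptic
depolarization charges an auxiliary variable (0.1 ms rise) that decays with
a constant solved numerically so the gate peaks exactly `tau_peak` after a
spike; the gate itself rises with `tau_r` and decays with `tau_d`
(excitatory 0.5/0.5/3 ms toward 0 mV; inhibitory 0.5/0.5/9 ms toward
−75 mV). Connectivity is Bernoulli(0.5) for E→I, I→E and I→I with aggregate
conductance scales `g_EI = g_II = 0.25` mS/cm² and no recurrent excitation;
an individual synapse carries `g/(p·N_pre)` so the expected aggregate input
is independent of pool size. **`g_IE` is not part of the printed table the
other defaults come from; the package defaults it to 0.25 mS/cm², matching
`g_EI` and `g_II`, and documents it loudly** — it is the one structural
parameter a user should treat as free.

External drive to E cell *i* is `I_E + eta_i + drive_gain·stimulus(t)` with
`I_E = 1.5` µA/cm² and `eta_i` a frozen Gaussian offset of spread
`sigma_E = 0.05` µA/cm² — deterministic heterogeneity, not temporal noise;
the networks contain no stochastic elements beyond the seeded wiring,
heterogeneity and initial voltages, so identical seeds reproduce rasters
bit-for-bit. Stimulus units are abstract drive units; `drive_gain = 1` maps
one drive unit to 1 µA/cm² (PING) or 1 nA (LIF). No physical light-intensity
calibration is possible (the optical scale has no model-side anchor), so
protocol amplitudes are calibrated per model to its dynamic range, the same
way stimulation intensity is titrated per recording site in experiments.

Integration is a classical fixed-step 4th-order scheme at `dt = 0.02` ms.
Three numerical shortcuts keep the integrator fast without changing the
science, and all three refine with `dt`: gating-rate functions are
tabulated on a 0.05 mV grid with linear interpolation; aggregate synaptic
conductances are refreshed on a 0.1 ms subgrid and held in between
(synaptic time constants are ≥ 0.5 ms); and the stimulus is frozen across
the four sub-stages of a step. Halving `dt` moves the network's gamma peak
by well under 1 Hz (asserted in the test suite). Spikes are upward
crossings of −20 mV.

## PING+M

The PING+M variant adds a non-inactivating, slow potassium current
(`g_M = 0.4` mS/cm², E cells only) with gate kinetics
`w_inf(v) = 1/(1+exp(-(v+35)/10))` and
`tau_w(v) = 400/(3.3·e^{(v+35)/20} + e^{-(v+35)/20})` ms — the standard
muscarinic-sensitive M-current formulation used with adaptation-based PING
models; the source the network tables come from cites the model book
chapter without reprinting equations, so these kinetics are the package's
explicit choice, exposed as code. At equal drive the M-current lowers both
the firing rate (≈ 15 vs ≈ 49 spikes/s per E cell at the default drive) and
the resonance frequency, as the underlying study reports qualitatively.
Because adaptation raises the effective rheobase, the PING+M rhythm at the
default `I_E = 1.5` µA/cm² sits below the gamma band (≈ 18 Hz); it enters
the gamma range at stronger drive. Tests therefore assert the *relative*
statements (lower rate, lower frequency) rather than an absolute band for
this variant.

## LIF

The LIF network implements the printed forward-Euler rule exactly:
`V = V + dt·(-(V - E) + I·R)/tau` with `dt = 0.5` ms, `R = 40` MΩ,
`C = 0.6` nF, `tau = R·C = 24` ms exactly, `E = V_leak = -60` mV, threshold
−40 mV, reset −75 mV. Synapses are instantaneous voltage jumps delivered at
the next step; each ordered pair's magnitude is a frozen uniform draw in
`[0, PSP]`. The printed PSP table is sign-consistent only under
postsynaptic-first subscripts (`PSP_EI = -0.8` mV is the jump onto an E
cell when an I cell fires), and that is how the package reads it;
excitatory cells are never mutually connected. One further printed
statement ("evaluated numerically at a resolution of tau") conflicts with
the printed `dt = 0.5` ms; the printed `dt` wins.

With these parameters the LIF units are intrinsically suprathreshold at the
default drive (`I·R = 60` mV against a 20 mV threshold distance), and the
network settles into a fast, partially clustered state whose population
rhythm sits near 250 Hz; its coherent gamma-band regime lies at roughly
0.5–1 nA of drive (the single-unit rheobase is exactly 0.5 nA). Analyses of
the LIF model therefore use sweep amplitudes within that range.

## Gated two-population circuit

`simulate_gated()` couples E1↔I exactly as in PING and adds a second
excitatory pool E2 that receives the same kind of inhibition (I→E2) but
projects to nothing. E1 is driven by one white-noise stream on top of the
default tonic drive; E2 is driven by an independent stream with **zero
tonic drive** (`I_E2 = 0`), keeping E2 below rheobase on average so its
spikes are fluctuation-driven: any rhythmicity in E2's output then comes
from the gating inhibition, not from intrinsic pacemaking. This matters for
the control condition — with the gate removed, a tonically driven E2 would
be an intrinsic oscillator whose own rhythm contaminates the
spike-triggered average.

# The stimulus protocols

`generate_stimulus()` provides constant light, a linear ramp (3 s default
usage), a single slow sine (one half-period raised cosine, 10 s), a slow
Gaussian profile (sd defaulting to duration/6), fast sinusoids oscillating
between 0 and a maximum (5–80 Hz), and Gaussian white noise updated at
1017.1 Hz with sd equal to half the mean, truncated at ±3.5 sd *by
rejection resampling* (clipping would put point masses at the bounds) and
strictly positive. Note one consequence: with sd = mean/2 the positivity
bound sits only 2 sd below the mean, so the delivered sample sd is ≈ 12%
below the nominal sd; the tests check the sample sd against the closed-form
doubly-truncated value. Traces are zero-order held onto finer integration
grids, preserving per-tick values exactly.

# The estimators

* **Spike density**: Gaussian kernel (sd 12.5 ms, or 1.25 ms for pulse and
  sinusoid protocols), truncated at ±2 sd and renormalized to unit mass, so
  the density integrates exactly to the spike count.
* **Time–frequency power** (`tf_power()`): per frequency, a 4-cycle Hann
  window slid in 1 ms steps; each epoch is Fourier transformed at the
  window's own frequency, squared and divided by the window length.
  Windows are interior-only; the common time axis is the intersection of
  per-frequency valid ranges. Power ratios use a −0.5 to −0.2 s pre-onset
  baseline.
* **Peak tracking** (`track_peak()`): per time step, the argmax of band
  power in 25–95 Hz (configurable); tracking is suppressed below a floor of
  5× the median baseline band power (or 5× the whole-recording median when
  no baseline exists, the situation of the slow unimodal sweeps).
* **Hysteresis** (`hysteresis_curves()`): time points are assigned to the
  rising or falling phase by the stimulus derivative (the single extremal
  sample belongs to neither); tracked power and frequency are averaged in
  20 equal-width intensity bins per phase. The loop area
  (`hysteresis_area()`) is the mean rising-minus-falling gap over bins in
  which *both* phases show an established resonance (binned power ≥ 10% of
  the maximum binned power): near onset the tracked peak is noise-dominated
  and a gap there is not evidence of memory. A memoryless synthetic
  response gives area ≈ 0; a synthetic response with a slow first-order
  adaptation state gives a positive area (both asserted against
  constructions with known answers).
* **STA** (`spike_triggered_average()`): mean of signal windows centered on
  spikes (default ±100 ms), with a ±3 SE null band; `sta_side_lobes()`
  counts pre-spike local maxima above the band and `sta_band_amplitude()`
  measures modulation at one frequency.
* **PPC** (`ppc()`): per spike, a Hann-tapered field epoch (±0.5 s at
  ≤ 20 Hz, ±0.25 s above) is transformed at each frequency to get the
  spike's field phase; PPC is the closed-form average over all unordered
  spike pairs of the cosine of phase differences,
  `(|Σe^{iθ}|² − n)/(n(n−1))`, whose expectation is free of spike-count
  bias. For spikes locked with von Mises concentration κ the population
  value is `(I₁(κ)/I₀(κ))²`.
* **Phase-slope latency** (`phase_slope_latency()`): one relative phase per
  stimulation frequency from the cross-spectrum over the steady-state
  period (the first 0.5 s of each trial is discarded as onset transient);
  phases are unwrapped progressively — each new frequency takes the 2π
  branch nearest the prediction of the line fitted so far, which also
  resolves steps larger than π (a 20 ms delay wraps between 40 and 80 Hz) —
  and latency is −slope/(2π), with a free intercept absorbing non-delay
  offsets. A flag reports when any unwrapped step exceeded π.
* **Nonparametric GC** (`estimate_csd()`, `factorize_spectral_matrix()`,
  `granger_from_csd()`): trials are cut into non-overlapping 500 ms epochs,
  demeaned (avoiding DC leakage through the taper), Hann-tapered,
  zero-padded to 1000 ms and transformed; the averaged 2×2 spectral matrix
  is factorized by the Wilson iteration (initialized from the Cholesky
  factor of the frequency-averaged spectrum; tolerance 1e-8, cap 100
  iterations, non-convergence flagged with the achieved error) into a
  minimum-phase transfer function and innovation covariance, from which the
  Geweke frequency-resolved influence is computed in both directions.
  Spike trains enter as binned counts on the stimulus grid. On sharply
  peaked spectra the iteration converges to the accuracy permitted by the
  finite lag grid (typically 1e-4 – 1e-6 relative) rather than 1e-8; the
  effect on the influence spectra is orders of magnitude below the
  estimation noise. The bootstrap (`bootstrap_gc()`) re-estimates from 100
  random 30% subsets of trials (without replacement, switchable) and
  reports the central 95% region.
* **Cluster permutation test** (`cluster_permutation_test()`): paired
  t-values across sites per frequency serve purely as a normalized
  difference metric; clusters are maximal runs of adjacent significant
  frequencies (two-tailed p < 0.05), their t-sums are compared with the
  2.5th/97.5th percentiles of min/max null distributions built from 10,000
  per-site condition swaps; ties count as non-significant.

# Synthetic ground truth

The fixture generators give every estimator a known answer at the same
1017.1 Hz default grid as the stimulus module, so estimator code paths are
identical to production paths. The GC oracle fixture used throughout is a
mild bivariate AR(2) (diagonal lag-1 coefficient 0.5, lag-2 −0.36, x→y
coupling 0.1 at lag 1, unit innovations, nominal 200 Hz), chosen with
spectral radius 0.6 so that the 500-epoch estimation noise (~±0.015) stays
inside the 0.02 agreement band against the closed-form Geweke spectrum; a
sharper resonance would be smoothed measurably by the 500 ms Hann window.
What the fixtures do *not* emulate: real recordings have non-stationary
rates, correlated background activity, and measurement noise, so passing
these calibrations demonstrates correctness of the estimators, not
robustness to every in-vivo nuisance.

# Study sizes and what the model analyses show

The default analysis sizes are: 5 s constant-drive runs for resonance; five
constant-drive levels from 1× to 2× the default for the drive sweep
(3 s each); 10-s slow-sine runs with 8 seeds per model for the hysteresis
comparison (sine peak 2.0 µA/cm² for PING/PING+M and 1.0 nA for the LIF,
each spanning from below resonance onset through the model's coherent
regime); 20 two-second white-noise trials (one continuous run, segmented)
for the transmission analysis; and 30-s gated runs. The estimator
calibrations use 500 epochs (GC), 10⁴ spikes and 200 replicates (PPC), and
500 null simulations of 20 sites × 500 permutations (cluster test).

Three places where this implementation of the printed parameters does
**not** reproduce a qualitative claim deserve to be called out rather than
hidden:

1. **Gamma power is not monotone up to 2× drive.** Peak *frequency* grows
   monotonically with constant drive (≈ 49 Hz at 1.5 µA/cm² to ≈ 84 Hz at
   3.0), but above ≈ 1.4× the default drive the one-spike-per-cycle volley
   state gives way, seed-robustly, to a partially clustered state whose
   collective power is an order of magnitude weaker; gamma power therefore
   rises and then collapses across the sweep. The hysteresis protocol's
   sine amplitude (2.0 µA/cm²) was chosen to stay at the edge of the
   coherent regime for this reason. The corresponding acceptance test is
   expected to fail on the power clause and is left failing: the
   synchrony-breakdown transition is a real property of this network at
   these conductances, and the unprinted `g_IE` only shifts, not removes,
   it.
2. **The LIF default-drive rhythm is not in the gamma band** (see above);
   the drive-monotonicity test includes the LIF as specified and fails for
   it inside the 25–95 Hz tracking band.
3. **Granger causality from white-noise input to spikes is largest below
   30 Hz.** The deterministic circuit transmits slow and subharmonic
   (≈ f₀/2) input components with very high coherence — there is no
   intrinsic slow background variability, unlike in vivo, where ongoing
   activity decoheres the low frequencies. The GC spectrum does show
   resonance structure in the gamma band, and the reverse direction
   (spikes→input) stays below 10% of the forward peak, but the *global*
   GC maximum falls below the gamma band at every operating point we
   examined (tonic/noise splits with means 0.4–2.5 µA/cm²); the
   corresponding acceptance clause is left failing with this analysis
   attached. The STA, which conditions on spikes rather than measuring
   frequency-resolved prediction, shows the gamma-rhythmic pre-spike input
   pattern cleanly (≥ 3 side lobes at the resonance period, absent under
   trigger shuffling).

The hysteresis dissociation itself reproduces: PING+M opens a consistent
positive frequency loop (rising branch above falling at matched mid-range
intensity, ≈ +0.5 Hz mean gap with the 10-s sine), while PING's loop is
statistically indistinguishable from zero — even though the M-current gate
(τ ≈ 0.1 s) is fast relative to the sweep, the adaptation state interacts
with the onset nonlinearity to displace the two branches. The LIF's loop
areas are noisy around zero (its cluster-state memory adds variance), and
one-sided rank tests across seeds place PING+M above both.

# Degenerate inputs and edge rules

Empty rasters give zero spike densities (not errors); frequencies whose
4-cycle window does not fit are dropped with a warning; zero baseline power
flags the power ratio as undefined at that frequency; constant inputs make
correlation-based estimators error loudly; fewer than two valid spike
epochs make PPC error; voltage divergence in the HH integrator reports the
step size; identical noise seeds for the two gated streams warn; the
stimulus extremum sample belongs to neither hysteresis phase; cluster
p-values are bounded below by 1/n_perm.
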