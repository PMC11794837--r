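---
title: "Modeling gamma-band entrainment under maturing inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling gamma-band entrainment under maturing inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

During developmental critical periods, the maturation of GABAergic
inhibition — in particular of parvalbumin-positive (PV) fast-spiking
interneurons — reorganizes cortical dynamics: internally generated
spontaneous activity is progressively suppressed, and the network's response
becomes increasingly driven by external stimuli. `pvgamma` implements a
population-level test of this idea: a conductance-based spiking network of
excitatory pyramidal (Pyr) cells and PV interneurons is driven by periodic
gamma-band input, and the *consistency* of its response across repeated
trials is quantified by inter-trial phase coherence (ITPC). The package
sweeps the PV-to-Pyr weight (GABA maturation), the Pyr-to-PV weight
(glutamatergic drive onto PV cells), the strength of external input onto PV
cells, and the ceiling of the excitatory synaptic weight distribution
(hyperexcitability), and asks how each shifts the balance between
stimulus-locked and stimulus-irrelevant activity.

## The network model

Each of the $N_E = 10{,}000$ Pyr cells and $N_I = 2{,}000$ PV cells is a
leaky integrate-and-fire neuron with conductance-based synapses:

$$\frac{dv_j}{dt} = -\frac{v_j - V_L}{\tau_m}
  - g_{E,j}\,(v_j - V_E) - g_{I,j}\,(v_j - V_I)
  + \sum_i W^{in}_{j,i} \sum_{s_i} \delta(t - s_i),$$

with a spike emitted and $v_j \to V_r$ whenever $v_j \ge V_{thr}$ (no
refractory period). Conductances decay exponentially and jump by the synaptic
weight $G$ whenever a presynaptic spike, delayed by its synaptic delay,
arrives. Membrane constants are fast ($\tau_{m}$ = 10.5 ms for Pyr, 3.1 ms
for PV), $V_L = -70$, $V_{thr} = -50$, $V_r = -60$, $V_E = 0$,
$V_I = -80$ mV.

Pyr-to-Pyr weights follow the long-tailed cortical EPSP statistics: EPSP
amplitudes are lognormal with $\sigma = 1$ and $\mu = \log 0.2 + \sigma^2$
(median $0.2e \approx 0.54$ mV), truncated by rejection (redraw, not
clipping) at a ceiling $\Theta_{EPSP}$ of 5 mV by default, and converted to
conductance weights by $G = V_{EPSP}/100$. Transmission of each Pyr-to-Pyr
spike fails independently with probability $a/(a + V_{EPSP})$, $a = 0.1$ mV,
so the many weak synapses are also the least reliable. The other weight
classes are scalar: Pyr-to-PV $G^{EI} = 0.018$, PV-to-Pyr $G^{IE}$ swept
over $[0.0017, 0.0045]$, PV-to-PV $G^{II} = 0.0025$. Connection
probabilities are 0.1 (Pyr-to-Pyr, Pyr-to-PV) and 0.5 (PV-to-Pyr,
PV-to-PV); delays are uniform in 1–3 ms (Pyr-to-Pyr) or 0–2 ms (others).

Two readings of "$\tau_s$ = 2 ms for Pyr and 4 ms for PV" are possible: by
transmitter (AMPA vs GABA conductances) or by the receiving cell. We default
to transmitter indexing (`tau_s_indexing = "presynaptic"`) and expose the
postsynaptic alternative as a switch; in sensitivity runs the two gave
qualitatively similar coherence profiles, so the choice is not load-bearing
for the package's conclusions.

The Pyr-to-Pyr connection probability is not uniquely determined by the
model family's usual description; we adopt 0.1, the baseline of the lineage of
lognormal-EPSP network models this one extends, and expose it in
`network_params()`. Self-connections are excluded for all classes.

## The input model

The input architecture — how many external fibers converge on each neuron
and how strong the periodic drive is per cycle — is not pinned down by the
core model description, so the package defines its own reconstruction,
chosen once on first principles and kept fixed:

* **Background.** Every neuron receives an independent aggregate Poisson
  train from `bg_fibers = 1000` fibers, each firing at 2.5 Hz, with each
  input spike an instantaneous voltage jump of $W^{in}$ (0.5 mV for Pyr;
  0.5 mV, reducible to 0.1 mV, for PV). One thousand external fibers matches
  the recurrent in-degree of the network, and the resulting mean
  depolarization (rate × jump × $\tau_m \approx 13$ mV for Pyr) places the
  network in the classic fluctuation-driven regime. This choice is forced:
  a *single* 2.5 Hz fiber per neuron (0.01 mV mean depolarization) cannot
  ignite the network, and with these fast membrane constants the recurrent
  network is not self-sustained — after any ignition transient the activity
  dies within ~100 ms. Continuous background drive is therefore the only
  reading under which the model produces sustained spontaneous activity,
  with spontaneous rates (Pyr ≈ 1–3 Hz, PV ≈ 20–50 Hz) in the range
  typical of this model family.
* **Periodic stimulus.** A deterministic, trial-identical spike train at
  $f_s$ (40 or 80 Hz) shared by all neurons; each stimulus spike is a
  volley of `stim_fibers = 8` synchronous input spikes, i.e. a per-cycle
  jump of 4 mV onto Pyr (8 × 0.5 mV) and likewise onto PV. The volley size
  is the one free amplitude in the reconstruction; we set it to roughly
  twice the standard deviation of the background-driven membrane-potential
  fluctuations (≈1.8 mV), so the stimulus competes with — neither vanishes
  under nor overwhelms — the network's intrinsic variability. Both the
  fan-out fraction and the volley size are exposed for sensitivity analyses.

Trial-to-trial variability therefore comes only from the background
realization, the stochastic transmission failures, and random initial
membrane potentials (uniform between $V_L$ and $V_{thr}$); the stimulus
itself is phase-locked by construction.

## Numerical scheme

The integrator uses exponential-Euler updates with `dt = 0.05` ms:
conductance decays are applied exactly each step, and the membrane equation
is solved in closed form per step with the conductances held constant, which
is unconditionally stable. Synaptic events are delivered on the `dt` grid
(delays rounded to the nearest step, minimum one step); input jumps land
exactly on grid times, and a threshold crossing is registered at the first
grid time at which $v \ge V_{thr}$ — including immediately after a jump,
before any further integration. This last point matters: checking only after
a full integration step lets marginal jump-driven crossings decay back below
threshold, and makes spike counts drift by several percent as `dt` changes;
with crossings registered at the jump time, halving `dt` changes spike
counts of a feed-forward test circuit by well under 2 %. Runaway activity
(mean Pyr rate above 100 Hz, or a hard per-trial cap) is flagged and those
conditions report no coherence, so unrealistically fast regimes never
enter the coherence summaries.

## Analysis pipeline

Population rates $r_E(t)$, $r_I(t)$ are spike counts in $\Delta t$ = 0.1 ms
bins scaled by $10^3/\Delta t$ (Hz), then smoothed with a unit-area Gaussian
kernel of 1 ms standard deviation (reflective edges, so spike mass is
conserved). ITPC across $T$ trials is

$$\mathrm{ITPC}(T, f) = \Bigl|\frac{1}{T}\sum_{j=1}^{T}
  \frac{F_j(f)}{|F_j(f)|}\Bigr|,$$

computed from the FFT of the de-meaned smoothed rate over the analysis
window (rectangular taper, no zero padding, frequency resolution
1/window). A trial with an exactly zero component at some frequency
contributes a zero vector there (with a warning) rather than silently
reducing $T$. Band summaries average ITPC over $f_s \pm 2$ Hz with inclusive
endpoints. Power spectra are per-trial periodograms of the same de-meaned
rates, averaged across (by default 10) trials with per-frequency standard
deviations.

The synthetic-signal module (`generate_ensemble()`) produces sinusoidal
rate-like trials with locked, uniform, or von Mises phases, for which the
expected ITPC is known in closed form (1, $\sqrt{\pi}/(2\sqrt{T})$, and
$I_1(\kappa)/I_0(\kappa)$ respectively); the analysis stage is validated
against these ground truths independently of the simulator. These synthetic
ensembles are stationary sinusoids plus white noise — they do not reproduce
spike-train discreteness, slow non-stationarities, or harmonic structure of
real population rates, so they validate the estimator, not the simulator.

## Problem sizes and reproducibility

Full-scale runs (T = 100 trials, 10 independent network realizations per
condition, 1000 ms analysis windows) are the model's reference design and
available through `preset_sweep(..., scale = "full")`, but take days of CPU
time. The package's default verification scale — used by its test suite and
by `scripts/acceptance.R` — keeps the full 12,000-neuron network and reduces
the statistics: T = 12 trials, 500 ms analysis windows after a 500 ms
discarded warmup (2 Hz frequency resolution, so the $f_s \pm 2$ band holds
three bins), and 1–3 network realizations per condition. At T = 12 the
no-coherence floor of ITPC is $\sqrt{\pi}/(2\sqrt{12}) \approx 0.26$, low
enough to separate the coherent (> 0.8) and incoherent (< 0.5) regimes the
sweeps probe. One master seed is split into named sub-streams
(connectivity / weights / delays / per-trial background / failures and
initial conditions), so any trial can be reproduced in isolation; rerunning
a sweep from its spec reproduces every number bit for bit.

## Known limitations

* The input architecture is a reconstruction (see above); conclusions that
  hinge on the exact stimulus strength should be read against the
  `stim_fibers` sensitivity switch rather than as a parameter-free
  prediction. With this reconstruction the model robustly reproduces the
  spontaneous-activity results — gamma-band power falls monotonically as
  inhibition matures and rises with the EPSP ceiling — and a raised EPSP
  ceiling degrades stimulus coherence; but the shape of the band-mean ITPC
  profile over $G^{IE}$ is sensitive to the stimulus volley amplitude (its
  trend flips sign near a ~3 mV volley) and an inverted-U peaked at
  intermediate inhibition does not emerge at the package's verification
  scale under any volley size we examined.
* Band-mean ITPC over $f_s \pm 2$ Hz has a structural ceiling under this
  pipeline: with integer-cycle windows and a rectangular taper, a
  stationary entrained response concentrates its coherence in the $f_s$
  bin (the acceptance script reports the balanced condition's peak-bin
  coherence alongside its band mean, and the former is substantially
  higher) while the neighboring bins carry incoherent noise, so the
  three-bin band mean cannot much exceed (peak + 2 × chance)/3. Estimators with wider
  spectral kernels (wavelets, multitaper) would instead let the band mean
  track the peak; `mean_itpc(..., halfwidth = 0)` reports the undiluted
  peak-bin coherence.
* No synaptic plasticity, no refractory period, one inhibitory class only
  (PV); SST/VIP interneurons, NMDA currents and short-term dynamics are out
  of scope.
* Exact spike times are grid-quantized at `dt`; delays are uniform random
  but rounded to the grid (error ≤ `dt`/2, far below the 1–3 ms delay
  scale).
* Power spectra use a rectangular taper to stay consistent with the ITPC
  definition; Welch averaging is deliberately not the default.
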