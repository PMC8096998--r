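---
title: "A spiking working-memory circuit with STDP: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking working-memory circuit with STDP: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikewm)
```

## The scientific question

Working memory — holding an item in mind for a few seconds — has two
competing neural accounts. In the classical account, task-relevant neurons
keep firing at an elevated rate through the retention delay (*persistent
activity*). In the newer account, the item is written into the synaptic
state of the circuit and the neurons fall back to baseline firing
(*activity-silent memory*); the item is read out later by a non-specific
probe. `spikewm` implements a small prefrontal-style spiking circuit in
which both behaviors arise from a single mechanism: fast spike-timing-
dependent plasticity (STDP) acting on a temporally ordered stimulus code.

## The model

### Circuit

The circuit has 24 excitatory and 6 inhibitory Izhikevich neurons. The 15
first excitatory neurons are *coding neurons*: they receive the stimulus
and project to read-only *detector neurons* (one per stimulus) that serve
as the behavioral readout. Excitatory neurons are fully connected, each
ordered pair by `s_ee = 4` synapses whose conduction delays are
`R + 3k` ms, with `R` drawn once per pair from U[3, 12] and
`k = 0, 1, 2, 3` — a multi-delay design whose mean delay is 12 ms.
Excitatory-inhibitory links exist in each direction with probability 0.8
(delays U[1, 20] ms, fixed weights `w_ei = 0.4`, `w_ie = 1.0` applied
negatively). Inhibitory neurons are not interconnected. Only the
excitatory-excitatory synapses are plastic; their weights start uniform on
[0, 0.14] (mean 0.07).

### Neuron and synapse dynamics

Each neuron follows the two-variable Izhikevich model
`v' = 0.04 v^2 + 5 v + 140 - u + I`, `u' = a (b v - u)`, with reset
`v <- c`, `u <- u + d` when `v` crosses 30 mV. The excitatory preset is
the regular-spiking set (0.02, 0.2, -65, 8); inhibitory neurons use
(0.04, 0.24, -65, 2). Integration is explicit Euler at `dt = 0.5` ms; the
spike time is the start of the tick in which the threshold was crossed.

A spike arriving at a synapse evokes an alpha-shaped postsynaptic current
`(t/tau) e^(1 - t/tau)` with `tau = 4` ms, scaled by the synaptic weight
and by the short-term-plasticity efficacy `u x`, where the available
resources `x` (depression, recovery `tau_d = 50` ms) and utilization `u`
(facilitation, recovery `tau_f = 20` ms) follow the classical
depressing/facilitating synapse model. On each spike the facilitation
jump is applied first, the transmitted efficacy is recorded with the
post-facilitation `u` and pre-depression `x`, and the depression jump
follows. Kernels older than 40 ms are truncated (the kernel is below
1.3e-3 of its peak there; on a dense spike train this bounds the relative
input error at about 1e-3).

The baseline utilization `U` is not a published constant. We use
`U = 0.7`, placing the synapse firmly in the depressing regime: the
response to a rapid train declines from the first spike on, which is the
qualitative behavior the model's transmission stage is meant to show, and
a single isolated spike transmits at efficacy 0.91 rather than 0.36, so
one replayed volley carries usable signal. The cost is stronger
per-spike depletion, which usefully damps runaway population bursts.

### Background noise

Every excitatory and inhibitory neuron receives a Gaussian noise current
standing in for input from surrounding cortex: the mean is drawn once per
neuron from U[1.5, 2.0] and the variance is 1.8. The noise is *piecewise
constant with a 2 ms hold time* (`noise_spec(hold_ms = 2)`): each neuron
redraws its deviate every 2 ms, staggered across neurons. The hold time
matters: with a fresh independent draw every 0.5 ms tick, the integrated
membrane fluctuation is well under 1 mV and the excitatory population is
strictly silent at baseline, which contradicts the low-rate irregular
ground state the model is supposed to exhibit and leaves the
activity-silent regime with no fluctuations to ignite recall. A 2 ms
correlation time — the scale of fast synaptic currents — restores sparse
irregular ground-state firing (~0.2 Hz per excitatory neuron) while
keeping the stated mean and variance exactly. Setting `hold_ms = dt`
recovers fully independent per-tick draws.

### Stimulus code and detectors

A stimulus is a *rank-order pattern*: a permutation assigning each coding
neuron a slot, the neuron of rank `r` firing at `r * 4` ms within a 60 ms
cycle, so only one coding neuron fires in any 4 ms and 15 neurons can
represent 15! stimuli. The two built-in stimuli, red and green, are the
identity order and its reversal — every pairwise firing order differs
between them. During the 1 s cue the volley is injected cyclically
(~16 repetitions) by forcing the coding neurons over threshold, so all
downstream synapses see ordinary spikes.

Each detector neuron receives one afferent per coding neuron with delay
`max(t) - t_i + 1` ms: a volley in the target order arrives
*simultaneously* and drives the detector over threshold, any other order
spreads the arrivals and the leaky membrane never accumulates enough
charge. The afferent weight is solved numerically at build time: a
bisection on a simulated detector finds the smallest weight that fires on
`k_coincident = 10` simultaneous arrivals and the largest that stays
silent on 5 arrivals spread one slot apart, and the working weight is
placed between the two bounds on a log scale (`detector_margin = 0.55`,
slightly toward the sensitive end so that jittered replay volleys are
still caught).

### Plasticity

Excitatory-excitatory synapses follow asymmetric exponential STDP with
nearest-neighbor pairing: `A+ = 1`, `A- = -1`, `tau+ = 3` ms,
`tau- = 18` ms, learning rate `eta = 0.2`, and weights clipped to
`[0, w_max]`. The presynaptic time entering the pairing is the *arrival*
time at the synapse (emission plus conduction delay), which is what makes
the four delays of a connection learn differently: during the cue, the
one synapse of a pair whose delay matches the rank gap has its arrival
land just before the postsynaptic spike and is strongly potentiated,
while synapses arriving after the spike are depressed. The stored memory
is therefore a *delay-matched causal chain* along the stimulus order.
Each spike pairs at most once per direction (the paired partner is
consumed), and STDP runs in every trial period — forgetting during the
delay is nothing but noise-driven pairing traffic.

With `eta = 0.2` and ~16 cue repetitions, repeated causal pairing
saturates near `0.2 * 16 = 3.2`; we set `w_max = 3` so that learned chain
synapses (rather than the clip bound) determine how strongly a
predecessor can time its successor's spike. Replayed volleys then run at
roughly the encoded 4 ms/slot pace, which is what the fixed detector
delays require.

## The behavioral protocol

A delay-match-to-sample trial is 1 s preparation, 1 s cue, 3 s delay and
a 0.5 s response period; detector spikes are counted over the 0.5 s
readout and the stimulus of the strictly more active detector is the
recalled sample (ties, including double silence, are unresolved and
scored incorrect). The regime offset (+1.5 persistent, -0.3 silent) is
applied to the excitatory noise means for the whole trial; during the
response period a non-specific recall current is added on top. The recall
magnitude is not published; +1.5 turns out to be too weak to ignite
replay in the silent regime, and the package default is +2.25, solved for
by requiring that recall works while the wrong detector stays quiet.

In the persistent regime the delay-period excitatory rate (~8 Hz) sits
well above the preparation rate (~5.5 Hz) and the matching detector keeps
firing through the delay: the learned chain reverberates. In the silent
regime the delay activity returns to the ground state (~0.2 Hz); the
memory survives purely in the weights and is reproduced by the recall
current. One honest nuance: because the learned chains amplify rare noise
spikes, the silent delay rate sits at the *unstimulated* ground-state
level, which is slightly above the extra-quiet preparation rate under the
-0.3 offset (~0.05 Hz). The regime contrast we assert in the tests is
therefore "persistent delay elevated by several Hz; silent delay below
1 Hz and far below the persistent delay rate", not a literal
delay-below-preparation comparison.

Continuous sessions chain trials on one circuit, separated by an
unstimulated intertrial interval; this is where one memory interferes
with the next. `accuracy_sweep()` scores the second trial of two-trial
sessions over a delay-by-intertrial grid. The sweep keeps the model's own
1 s cue: compressing the cue to 125 ms (two volleys) pushes every cell to
floor accuracy and erases the delay/intertrial trends the sweep exists to
measure, so we read the published "reduced to one-eighth" as mapping the
source behavioral experiment onto the model's time scale rather than
shrinking the model's cue further. `cue_ms` remains a parameter.

## Analysis choices

Firing rates are spike counts in half-open 500 ms windows at 200 ms
stride, in Hz. Population decoding fits a linear-kernel SVM (`e1071`,
default cost, no rescaling) per time bin on the per-trial rate vectors of
the 24 excitatory neurons — detectors are excluded because they would
leak the label, inhibitory neurons carry no selective input — under
stratified 5-fold cross-validation. The decoding experiment uses 40
trials (20 per stimulus) on one circuit with fresh noise per trial;
keeping the circuit fixed matches the single-network design of the
underlying experiment and avoids decoding circuit identity instead of the
stimulus. Chance is 50%; the label-permutation control should stay within
three standard errors of it. Weight distributions are summarized over the
plastic synapses by the mean, the fraction above 0.2 (the learned tail)
and the fraction below 0.02 (the depressed bulk): after one cue the
distribution is strongly right-skewed, most weights near zero and a few
percent above 0.2.

## Numerical and engineering choices

The tick loop is compiled (Rcpp): per tick it delivers queued arrivals,
sums kernel responses within the truncation horizon, adds noise and
offset currents, advances all neurons by one Euler step, and lets spiking
neurons run their short-term-plasticity updates, delay-queue insertions
and STDP pairings. Conduction delays are rounded to ticks (minimum one).
A forced injection sets the membrane above threshold so the spike is
processed like any other. The engine consumes exactly one normal deviate
per neuron per noise-redraw tick in fixed order, so a run of length A
followed by one of length B reproduces a single run of length A+B
bit-for-bit; the test suite holds the engine to a pure-R full-rescan
reference simulator, spike for spike. Non-finite membrane values abort
with the neuron and time named.

Reproducibility is layered: a circuit seed feeds three derived streams
(topology, weights, noise baselines) so the anatomy can be rebuilt
independently of any noise realization; trial seeds control the noise;
analysis seeds control fold assignment and permutations.

### Problem sizes used in the tests

The shipped tests run the full reference circuit (32 neurons including
two detectors, 2462 synapses): 40 persistent trials for the decoding
analysis, 25 silent trials for recall, a 3x2x20 sweep for the
interference trends, and small fixtures (a 5-neuron circuit, 200 ms) for
the exact engine-versus-oracle comparisons. These sizes were chosen so
the whole suite documents the model's behavior in about a minute of
compute while keeping the stochastic checks' sampling error a few
percent.

## What the simulated conditions do and do not show

The generator *is* the study design: all conclusions are about this
30-neuron circuit with the stated parameters, two stimuli and forced
cue volleys. Passing tests show that the mechanism — rank-order coding,
delay-matched STDP chains, polychronous readout — works as described
under its own assumptions. They do not show anything about real cortical
tissue, about robustness to conductance-based synaptic dynamics, to
unslotted (continuous-latency) codes, or to larger stimulus sets; a
single small circuit is also fragile to noise in ways a redundant
population of circuits would not be, which is visible as trial-to-trial
volatility in the interference sweep.

## Known limitations

* Recall in the silent regime succeeds in roughly 85–90% of trials at the
  default settings, failing mostly by double-silence of the detectors,
  not by recalling the wrong item.
* Delay-period decodability declines over the 3 s delay as STDP traffic
  erodes the chain; decoding accuracy varies a few percent from one
  circuit topology draw to another.
* The readout requires the replayed volley to respect the 4 ms slot
  timing; substantially faster or slower replay (e.g. under very strong
  recall drive) defeats the fixed detector delays.
* Exact reproduction of the source figures is out of scope; the package
  targets the worked numeric examples and the qualitative regime
  phenomenology.
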