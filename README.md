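# spikewm

Spiking working-memory circuits with spike-timing-dependent plasticity.

`spikewm` simulates a small prefrontal-style circuit of Izhikevich neurons
that stores a stimulus for several seconds and recalls it under a
delay-match-to-sample (DMS) protocol. It is aimed at computational
neuroscientists studying how *persistent activity* and *activity-silent*
accounts of working memory can arise from one synaptic mechanism.

## The model in brief

* **Circuit** — 24 excitatory (15 coding) + 6 inhibitory Izhikevich
  neurons (`v' = 0.04v² + 5v + 140 − u + I`, `u' = a(bv − u)`, reset at
  30 mV). Excitatory neurons are all-to-all connected, 4 synapses per
  ordered pair with conduction delays `R + 3k` ms, `R ~ U[3,12]`,
  `k = 0..3` (mean 12 ms). Gaussian background noise (per-neuron mean
  `U[1.5, 2]`, variance 1.8, 2 ms correlation time).
* **Transmission** — alpha-kernel postsynaptic currents
  `(t/τ)e^{1−t/τ}` (τ = 4 ms) with short-term depression/facilitation
  (`x`, `u` dynamics; τ_D = 50 ms, τ_F = 20 ms, baseline utilization
  U = 0.7).
* **Stimulus code** — rank-order coding: each of the 15 coding neurons
  fires in its own 4 ms slot, so the firing *order* is the stimulus
  (`n` neurons encode `n!` items versus `n + 1` for a rate code).
* **Memory** — nearest-neighbor STDP
  (`ΔW = A± exp(±Δt/τ±)`, A± = ±1, τ₊ = 3 ms, τ₋ = 18 ms, η = 0.2),
  with the presynaptic *arrival* time entering the pairing, imprints a
  delay-matched causal chain along the stimulus order onto the
  multi-delay synapses.
* **Readout** — polychronization detectors: one neuron per stimulus whose
  afferent delays make a correctly ordered volley arrive simultaneously;
  the more active detector during the 0.5 s response readout is the
  recalled item.
* **Regimes** — a +1.5 excitatory noise-mean offset yields elevated,
  stimulus-specific delay activity (persistent regime); a −0.3 offset
  yields an activity-silent delay from which a non-specific recall
  current still retrieves the item (silent regime).

## A worked example

```r
library(spikewm)

circ <- build_circuit(circuit_config(seed = 101))
circ
#> working-memory circuit: 24 excitatory ( 15 coding ), 6 inhibitory, 2 detector(s) [ red, green ]
#>   synapses: 2468 total, 2208 plastic E-E; t = 0 ms

res <- run_trial(circ, trial_spec("green", regime = "silent", seed = 601))
res
#> trial_result: sample = green regime = silent
#>   detector counts: red=0 green=1
#>   recalled: green correct: TRUE
```

The circuit held the item through a 3 s delay in which the excitatory
population fired at its ground-state rate (no persistent activity); the
recall current in the response period replayed the stored order, and only
the green detector — whose delays line up with that order — fired.

The memory lives in the weights. After the cue the initially uniform
weight distribution (mean 0.0706) is strongly right-skewed:

```r
weight_histogram(res$weights$post_cue, threshold = 0.2)
#> weight_histogram: 2208 plastic weights, mean = 0.0952
#>   fraction above threshold: 0.0498 ; fraction below low mark: 0.443
```

i.e. 44% of the plastic weights have been depressed below 0.02 while a
5% tail — the synapses whose conduction delay matches the encoded
rank gap — has been driven above 0.2.

Higher-level drivers: `run_session()` chains trials on one circuit
(memory interference), `accuracy_sweep()` maps recall accuracy over
delay × intertrial grids, `decode_over_time()` fits a per-time-bin linear
SVM to binned excitatory firing rates, and `wm_cli()` /
`inst/cli/wmstdp` expose trials, sessions, sweeps, decoding and fixture
generation from the shell with text run archives.

See the vignette (`vignettes/working-memory-model.Rmd`) for the full
model description, parameter rationale and limitations.

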