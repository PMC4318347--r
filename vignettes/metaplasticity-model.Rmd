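---
title: "Synaptic-drive metaplasticity in spiking networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synaptic-drive metaplasticity in spiking networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polychron)
library(dplyr)
```

## The problem

Recurrent spiking networks trained with spike-timing-dependent plasticity
(STDP) on repeated spatio-temporal stimuli develop *polychronous neural
groups* (PNGs): sets of neurons that fire in reproducible, precisely timed
but non-synchronous sequences whenever the stimulus is presented. PNG
formation pushes excitatory weights to the extremes — most synapses are
pruned to zero and a minority saturate at the hard cap — and the resulting
bimodal weight distribution is what supports the time-locked chains.

Metaplasticity is the activity-dependent regulation of plasticity itself.
`polychron` implements a metaplasticity model whose control signal is not
the post-synaptic firing rate (as in classical BCM-style threshold models)
but the *synaptic drive*: the consistency of pre-before-post versus
post-before-pre spike timing at each synapse, approximated by the
per-synapse derivative that the simulation already accumulates between
weight updates. The package provides the model, the network simulation
apparatus around it, the PNG measurement pipeline (response fingerprints,
weight censuses, activation partitions), and small mechanistic circuits
that expose *why* the model changes network behaviour (spike latency,
input-space expansion).

## Neuron and network model

Neurons follow the two-variable Izhikevich dynamics

$$v' = 0.04v^2 + 5v + 140 - u + I, \qquad u' = a(bv - u),$$

with a spike cutoff at $v \ge 30$ mV and reset $v \leftarrow c$,
$u \leftarrow u + d$. Excitatory cells are regular-spiking
($a = 0.02, b = 0.2, c = -65, d = 8$), inhibitory cells fast-spiking
($a = 0.1, b = 0.2, c = -65, d = 2$). Integration uses two 0.5 ms
forward-Euler substeps for $v$ and one 1 ms step for $u$ per tick, the
scheme inherited from the reference network code this family of models
builds on; the cutoff is checked after each substep and the reset is
applied within the tick, so a stored $v$ never exceeds the cutoff.

Regular-spiking cells are *integrators*: driven just above threshold they
fire late (spike latency of tens of ms), and the latency shrinks as the
drive grows. Several package demonstrations rest on this property, so two
integration details matter and are fixed deliberately:

* **Resting state.** The exact resting fixed point of both presets is
  $v = -70$, $u = bv$ (the stable root of $0.04v^2 + (5-b)v + 140 = 0$);
  the conventional reset value $-65$ is *not* a fixed point and relaxes to
  $-70$ within a few ms. Isolated test frames (latency curves, input-space
  trials) therefore start neurons at the true resting point; the full
  network simulation keeps the conventional $-65$ initialization, where
  the distinction is immaterial under ongoing input.
* **Forced firing.** External events come in two kinds. `"current"`
  events add a one-tick current pulse (default 20 mV — super-threshold
  from rest, firing the cell a few ms later); they model the Poisson
  background. `"spike"` events force an exact spike emission at their
  tick; they implement patterned stimuli and toy-circuit drive schedules,
  where ms-exact timing against conduction delays is the point of the
  experiment. A 20 mV pulse cannot fire a cell on the tick it is
  delivered, so stimulus events that must land at defined offsets use
  forced spikes.

The standard network is 1000 neurons (800 excitatory, 200 inhibitory),
each with 100 distinct random targets (inhibitory cells target excitatory
cells only), excitatory delays uniform on 1–20 ms, inhibitory delays 1 ms,
initial weights +3.0 / −2.0 mV, and a 10 mV hard cap on excitatory
weights. Duplicate (pre, post) pairs and self-connections are excluded
during wiring by rejection sampling.

## STDP and the synaptic derivative

The STDP rule is temporally asymmetric and additive, with baseline
amplitudes $A_+ = 0.1$ and $A_- = 0.12$ and exponential traces
($\tau_+ = \tau_- = 20$ ms, trace reset on each event, i.e. nearest-event
interactions). The LTD trace is indexed by the pre-synaptic *arrival* time
(spike time plus conduction delay), so a 20 ms delay genuinely shifts the
pairing window. Pairings accumulate in a per-synapse derivative $d_i$
rather than modifying the weight immediately; once per second each plastic
weight is updated as

$$w_i \leftarrow \mathrm{clip}(w_i + 0.01 + d_i,\; 0,\; w_{\max}), \qquad
  d_i \leftarrow 0.9\, d_i .$$

The +0.01 drift, the 0.9 retention factor, the 1 s cadence and the trace
constants are adopted from the reference implementation this model family
extends; all are exposed in `stdp_params()` because the original platform
may have differed. The derivative, in mV per update interval with a
"normal range" of ±10, doubles as the synaptic-drive signal consumed by
the metaplasticity model — positive when pre-before-post pairings dominate
and negative in the opposite regime.

## The metaplasticity model

Each plastic synapse contributes a *resistance* value through the
weighting function

$$f(d_i, w_i) = r\,e^{p\,m(d_i)}\,(w_i - \mathrm{min}) -
  r\,e^{p\,(10 - m(d_i))}\,(\mathrm{max} - w_i),$$

where $m(x) = \mathrm{clip}(0.5(x + 10), 0, 10)$ maps the derivative range
±10 onto 0–10, $r$ (resistance) scales the amplitude, $p$ (precision)
controls the curvature, and min/max are *soft* weight limits distinct from
the hard cap. The surface is near zero over most of the $(d, w)$ plane and
rises exponentially only in the two opposing corners: strong positive
drive on an already-large weight (resisting further potentiation) and
strong negative drive on a small weight (resisting further depression).
Migration *away* from the limits meets almost no resistance. The placement
of $r$ as a global scale outside the exponentials is the reconstruction
consistent with its description as an amplitude parameter; the functional
form is isolated in `weight_resistance()` and easy to swap.

The per-neuron modification threshold integrates the resistances of the
neuron's plastic afferents:

$$\theta_M = \tanh\!\left(I \cdot \tfrac{1}{n}\sum_i f(d_i, w_i)\right),$$

with inertia $I$ controlling sensitivity; $\tanh$ bounds $\theta_M$ to
(−1, 1). The threshold then modulates both STDP amplitudes symmetrically:

$$A_{LTP}(t) = A_{LTP}(0)\,(1 - \theta_M), \qquad
  A_{LTD}(t) = A_{LTD}(0)\,(1 + \theta_M),$$

so each amplitude ranges over 0–2 times its baseline and their
baseline-relative sum is always 2. Because the threshold is an *average*,
individual synapses may still prune or saturate as long as the population
is balanced — and a single synapse that grows without bound increasingly
dominates the average, which drives $\theta_M \to 1$ and shuts LTP off: an
implicit brake that the test suite checks numerically.

Design choices where the model description is open:

* **Cadence.** $\theta_M$ and the amplitudes are recomputed at every
  weight-update interval (1 s), immediately before the weights are
  applied, and then hold for the next second. Nothing in the analysis
  depends on a finer cadence.
* **Scope.** The threshold is computed for excitatory neurons over their
  plastic (excitatory) afferents. Plastic synapses onto inhibitory
  neurons use the baseline amplitudes; inhibitory synapses are non-plastic
  throughout.
* **Soft limits.** Network runs use soft limits 0–10 mV, coinciding with
  the hard cap; the single-synapse demonstration scales the upper soft
  limit to its 15 mV cap.
* **Defaults.** Network experiments use $r = 0.1$, $p = 0.5$, $I = 0.2$;
  the single-synapse demonstration uses the flatter $p = 0.05$ surface.

## The experimental protocol

`run_experiment()` implements a paired comparison. Each network is
*matured* on 1 Hz per-neuron Poisson background with STDP (metaplasticity
off), developing the bimodal weight distribution. From the same matured
snapshot the network is then *trained* twice — once with and once without
metaplasticity, on identical input streams — on the ascending stimulus:
forty forced firing events, neuron $k$ at offset $k$ ms within each frame,
presented at 5 Hz over a 1 Hz background for 180 s. Finally each arm is
*probed* with the pattern at 4 Hz for 400 frames with all plasticity
frozen (the probe measures the response; it must not keep learning — an
assumption recorded here because the measurement protocol does not state
it).

Measurements per network and arm:

* **Response fingerprint / PNG size.** Per-neuron peri-stimulus histograms
  of the probe raster at 1 ms bins are scanned for contiguous peak regions
  (bins whose frame-hit fraction exceeds a 0.25 floor, regions separated
  by at most 1 low bin merged); a region becomes a fingerprint entry iff
  the fraction of frames with a spike inside it reaches the 0.75
  consistency threshold. PNG size is the fingerprint's distinct-neuron
  count. The floor and merge gap are package defaults — the full
  peak-detection recipe lives outside the model description — and the
  planted-signal tests are insensitive to them by construction.
* **Weight census.** Exact three-way counts of plastic weights: pruned
  ($w = 0$), saturated ($w = w_{\max}$), other. Exact comparison is valid
  because the update clips onto the bounds.
* **Activation partition.** A connection is *active* iff some pre-spike at
  $t_1$ and post-spike at $t_2$ in the probe raster satisfy
  $\mathrm{delay} \le t_2 - t_1 \le \mathrm{delay} + 2$ ms. Over a long,
  dense probe raster a delay-matched pair becomes likely by chance alone,
  so absolute active counts approach the connection total at desk scale;
  the informative quantity is the difference between arms, which the
  chance floor affects equally.
* **End-of-training excitatory rate** over the last 10 s of training.

### Problem sizes

The package's default experiment is a desk-scale version of the full
design: **5 networks, 20 min maturation, 180 s training per arm, 100 s
probing** (the full-scale design — 20 networks, 2 h maturation — is the
same code with different arguments and runs for several hours). At desk
scale the absolute counts differ from a fully matured network (less
pruning has accumulated), so the paired comparison is evaluated on
*directions*: with metaplasticity, PNG size increases, pruned synapses
decrease, saturated synapses increase, and the excitatory rate rises.
These directions hold for every network individually in the default
configuration, not just on the means.

## Mechanistic workbenches

**Single-synapse regulation** (`run_single_synapse_demo()`): two RS cells
joined by one plastic synapse (delay 1 ms, initial weight 6 mV, cap
15 mV), both driven directly with two bursts per second of six pulse
pairs, pre leading post by 5 ms. The stated burst schedule is ambiguous in
its spacing; the package uses a 12 ms intra-burst interval (~83 Hz, a
typical cortical burst rate) so that consecutive pairs also produce
post-before-pre pairings inside the 20 ms LTD window. Under that mixed
drive the metaplastic equilibrium sits well below the cap — the weight
rises, overshoots, and settles near 9–12 mV while $\theta_M$ stays
positive — whereas with metaplasticity off the same schedule saturates the
weight at 15 mV and keeps it there. With sparser pulses (≥ 15 ms) LTD
pairing is too weak and even the regulated weight touches the cap; the
spacing is a parameter, and this choice is recorded here.

**Spike-latency curve** (`spike_latency_curve()`): three inputs forced
simultaneously, one RS output. The combined weight is swept 17–30 mV and
the output's firing time recorded. The premise of the demonstration is
that 17 mV is *barely* super-threshold; under this integration scheme that
requires near-coincident arrivals, so the default delays are (10, 10, 11)
ms with the combined weight split (8 : 8 : 2) — a configuration in which
17 mV fires at 21 ms and 30 mV at 12 ms. With strongly staggered delays
such as (10, 10, 15) and an equal split, 17–27 mV is sub-threshold and the
demonstration is void; delays and split are arguments, including a seeded
random option.

**Synaptic-drive reversal** (`run_weight_reversal_demo()`): the fan-in
circuit with delays (10, 10, 15) and weights (8, 8, 6), inputs fired
together at 5 Hz. Initially the output fires ~19 ms after the inputs,
after the late arrival on connection C, so all three connections
potentiate. As A and B approach the cap the output's latency shrinks and
its firing time migrates backwards past C's arrival (~14 ms < 15 ms); the
drive on C reverses sign and its weight falls — an interior maximum in
C's weight series, driven purely by STDP plus spike latency.

**Input space** (`input_space_response()`): the firing times of the three
inputs are varied over 0–20 ms and each timing pattern is scored over 400
independent 250 ms frames (a cell is active at ≥ 100 firing frames).
Because a common shift of all three firing times leaves the pattern
unchanged, the 3-D timing cube is reported in difference coordinates
$(t_1 - t_2,\; t_2 - t_3)$; translation invariance is exact in noise-free
frames and is tested as such. Noise-free frames are deterministic repeats,
so the implementation evaluates one frame per cell and replicates it —
the equality with a full per-trial simulation is itself a test — and a
per-frame Poisson noise option restores genuine trial variability, under
which all trials are simulated. With all weights capped at 10 mV, any two
near-coincident arrivals fire the target, producing the three "arms" in
the difference plane.

**Latency optimization** (`optimize_latency()`): in the six-neuron chain
circuit, neuron 6 receives the chain connection from neuron 4 (delay 2–5
ms) and a lateral connection from neuron 5 (fired at a fixed 19 ms offset,
1 ms delay). Re-choosing the weight of the first input connection from ten
1 mV steps (1–10 mV) shifts neuron 4's firing time through its spike
latency; a cell of the input space is active in the optimized map iff any
step (or the default weight) gives consistent firing. The optimized active
set is a superset by construction; the demonstration's content is that it
is *strictly* larger at these chain delays — latency tuning expands the
input space a downstream PNG neuron can tolerate.

## Numerical and reproducibility notes

* All randomness is generated on the R side from explicit seeds (topology,
  per-phase Poisson streams); the compiled engine is deterministic, so a
  run is a pure function of its configuration. Identical configurations
  reproduce rasters and weights bit for bit, and metaplasticity with
  $r = 0$ is bit-identical to metaplasticity disabled.
* Simulation state (membrane variables, traces, thresholds, in-flight
  spikes) travels with the network object: consecutive runs compose
  exactly, and a snapshot written to disk resumes bit-exactly.
* Simultaneous synaptic arrivals sum linearly into the input current.
  A runaway-firing guard (mean excitatory rate above 100 Hz over any
  update interval) aborts network runs with diagnostics; it is disabled
  in the toy circuits, where extreme rates are intentional.
* $\tanh$ saturates to exactly 1.0 in double precision for arguments
  beyond ~19, so $\theta_M \in (-1, 1)$ holds on the open interval only up
  to floating-point saturation under extreme, out-of-model resistances.
* The compiled engine is validated against an independent plain-R
  event-queue implementation (bit-exact rasters, weights and membrane
  state on random small networks) and the STDP accumulation against a
  direct sum over all event pairs.

## What the synthetic conditions do and do not show

All inputs are generated: Poisson background, the ascending pattern, and
the toy-circuit drive schedules. Passing tests therefore demonstrate the
model's internal claims — regulation of single-synapse weights, the
direction of network-level effects under the stated protocol, the
latency mechanisms — under the stated noise model (independent Poisson
events, linear summation, 1 ms resolution). They do not speak to
biological variability absent from that model: heterogeneous neuron
parameters, conductance-based synapses, sub-millisecond timing, delay
plasticity, or stimulus statistics beyond a single repeated pattern.
Desk-scale runs also mature networks for 20 min rather than hours, so
absolute census and PNG-size values are smaller than fully matured
networks produce; the paired directions are the reproducible quantity.

## Session info

```{r}
sessionInfo()
```
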