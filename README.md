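# attractormask

Spiking cortical attractor-network simulation of metacontrast backward
masking.

## What this is

When a brief visual target (~20 ms) is followed within ~100 ms by a
spatially adjacent mask, observers often fail to perceive the target.
`attractormask` implements a biophysically detailed spiking model of the
early visual system — LGN relay cells, V1 and V2 with three-layer
(L2/3, L4, L5) hypercolumn/minicolumn microcircuits — in which visual
features are stored as *attractor memories*: sparse sets of minicolumns
coupled by long-range recurrent excitation.  A partially stimulated
memory can *complete* (ignite across its whole distributed
representation); completion in layer 2/3 of both V1 and V2 within a
presentation is the model's proxy for the possibility of conscious
perception.  Masking arises when lateral inhibition and competing
attractor activity from the mask quench the target's pattern before it
completes and propagates, and recurrent V2→V1 feedback (10 ms latency
each way) counteracts masking by reinforcing the target.

Two model instantiations are provided:

* **model 1** — 4×4 hypercolumns × 16 minicolumns, 18 random sparse
  memories of 10 minicolumns per area (39,424 neurons at full scale);
  target = 4 stimulated minicolumns of one memory, mask = 4 or 5
  minicolumns of *other* memories in the same hypercolumns (metacontrast
  noise).
* **model 2** — 9×9 hypercolumns × 8 minicolumns, 72 vertical-line
  feature detectors of 9 minicolumns (99,792 neurons); target = the
  middle line, mask = the two parallel lines 1–3 hypercolumns to each
  side, with lateral inhibition extending horizontally (probability 0.5
  one hypercolumn away, 0.25 two away).

Cells are conductance-based and multi-compartment (4 compartments for
pyramidal cells, 3 otherwise) with Hodgkin–Huxley spike currents,
calcium-dependent adaptation, AMPA/NMDA/GABA_A synapses and short-term
synaptic depression; the network engine (C++ under the hood) integrates
at 0.1 ms with exact delayed event delivery and bit-reproducible
two-level seeding (individual wiring seed, trial noise seed).

The masking function is measured with the standard protocol: target
alone, mask alone, then target+mask at SOAs of 20–120 ms, one
presentation per second, across independently wired "individuals" and
trials.  `classify_masking_type()` labels curves **type A** (masking
fades monotonically with SOA) or **type B** (U-shaped, worst at an
intermediate SOA).

## Worked example

A reduced model-1 experiment (desk scale 0.25, one individual, one
trial per feedback condition — a few minutes of CPU):

```r
library(attractormask)

cfg <- model_config("model1", scale = 0.25, mask_points = 5)
res <- run_experiment(cfg, n_individuals = 1, n_trials = 1,
                      feedback = c(TRUE, FALSE), seed = 42)
masking_curve(res)
```

```
Masking curves (completion % by SOA)
 feedback   condition soa scope n completed percent
    FALSE   mask_only  NA  both 1         0       0
    FALSE   mask_only  NA    V1 1         0       0
    FALSE   mask_only  NA    V2 1         0       0
    FALSE target_mask  20  both 1         1     100
    FALSE target_mask  40  both 1         1     100
    FALSE target_mask  60  both 1         1     100
    FALSE target_mask  80  both 1         1     100
    FALSE target_mask 100  both 1         0       0
    FALSE target_mask 120  both 1         1     100
    ...
     TRUE target_only  NA  both 1         1     100
     TRUE target_only  NA    V1 1         1     100
     TRUE target_only  NA    V2 1         1     100
```

Each row is the percentage of trials in which the target memory became
fully active (≥ 7 of its 10 minicolumns firing ≥ 10 layer-2/3 pyramidal
spikes) in V1, in V2, or in both simultaneously, at each stimulus onset
asynchrony.  `mask_only` rows are the false-completion control (the mask
must never complete the unstimulated target pattern); `target_only`
rows are the calibration ceiling.  With realistic trial counts
(`n_individuals = 5, n_trials = 5`) the curves acquire 4-point
resolution and can be classified:

```r
classify_masking_type(masking_curve(res), scope = "both", feedback = TRUE)
```

Lower-level entry points: `build_model()` (one wired individual),
`run_trial()` (one 8-presentation trial), `run_network()` (raw
integration with arbitrary forced-spike schedules and current
injections, returning a `spike_raster` with `print`/`summary`/`plot`
methods), `detect_completion()` (the completion criterion on any
raster), and `calibrate()` (the conductance-scale search that produced
the shipped per-model defaults).

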