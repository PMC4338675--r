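---
title: "A spiking attractor-network model of metacontrast backward masking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking attractor-network model of metacontrast backward masking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In visual backward masking, a brief target stimulus (around 20 ms) is
followed after a short stimulus onset asynchrony (SOA) by a mask.  When the
mask falls close to the target in space and within roughly 100 ms in time,
observers often fail to report the target.  Two families of explanation
have long competed: feedforward lateral inhibition (the mask's afferent
volley inhibits the target's cortical representation) and interruption of
feedback (re-entrant activity from higher areas never gets to confirm the
target).  `attractormask` implements a biophysical spiking model of LGN,
V1 and V2 in which both mechanisms coexist, and simulates the full
metacontrast protocol to ask how completion of the target's cortical
representation depends on SOA, mask geometry and the presence of
cortico-cortical feedback.

The central object is the *attractor memory*: a sparse set of minicolumns,
at most one per hypercolumn, wired together by long-range recurrent
excitation.  Partial stimulation of such a pattern can *complete* - ignite
the whole assembly - through recurrence; completion in layer 2/3 of both
V1 and V2 is the model's operational proxy for the possibility of
conscious perception.  Masking is then a race: the target's pattern must
complete before the mask's afferent inhibition and competing attractor
dynamics quench it.

## Model structure

Two instantiations are built by `model_config()`:

* **Model 1** - a 4 x 4 hypercolumn patch with 16 minicolumns per
  hypercolumn.  18 stored memories per area are drawn by randomly taking
  one minicolumn from 10 of the 16 hypercolumns, without ever re-using a
  minicolumn (sparse, orthogonal patterns).  The target is one memory,
  stimulated at 4 of its minicolumns via the LGN; the metacontrast noise
  mask stimulates 4 (or 5, for higher salience) minicolumns belonging to
  *other* memories inside the target's hypercolumns.
* **Model 2** - a 9 x 9 patch with 8 minicolumns per hypercolumn.  Every
  (grid column, minicolumn index) pair forms one vertically oriented line
  detector: 72 patterns of 9 minicolumns that partition the patch.  The
  target is the middle line; the mask is the two parallel lines 1-3
  hypercolumns to each side.  Lateral inhibition extends horizontally
  beyond the hypercolumn (connection probability 0.5 one hypercolumn away,
  0.25 two away, none further), implementing competition between parallel
  lines.

The LGN is a grid of locations (one per V1 minicolumn, 256 in model 1 and
648 in model 2), each holding a stack of 10 relay cells.  A location
projects to the layer 4 pyramidal cells of its minicolumn and to that
minicolumn's basket cells, which inhibit the surrounding minicolumns - the
feedforward leg of lateral inhibition.  V1 and V2 share the same
three-layer (L2/3, L4, L5) microcircuit: 20 pyramidal cells, 2 basket
cells and 2 RSNP interneurons per minicolumn per layer at full scale
(39,424 neurons in model 1; 99,792 in model 2).  Feedforward projections
run V1 L4 -> V2 L4 (strong) and V1 L2/3 -> V2 L2/3 (weaker); feedback runs
V2 L4 -> V1 L5 (strong) and V2 L4 -> V1 L2/3 at 10% of that strength, with
a di-synaptic inhibitory leg onto RSNP cells of competing minicolumns.
All inter-areal latencies are 10 ms.  Pattern projections are sparse cues:
four destination minicolumns per linked memory receive the axons.

## Neurons and synapses

Cells are conductance-based and multi-compartment: pyramidal cells have a
soma, an initial segment, a basal and an apical dendrite; basket, RSNP and
relay cells have three compartments.  Spike-generating Na/K currents of
standard Hodgkin-Huxley form sit on the initial segment; soma and
dendrites are passive.  A spike-triggered calcium pool drives a potassium
after-hyperpolarization current, giving strong adaptation in pyramidal
cells, weak adaptation in RSNP cells and none in basket or relay cells.
Synapses carry AMPA/kainate, voltage-dependent NMDA (1 mM magnesium
block), and GABA_A channels; every synaptic channel has single-release-
variable short-term depression (release fraction 0.2, recovery 350 ms).
Adaptation (300 ms calcium time constant) plus depression give attractors
their finite dwell time: an ignited pattern burns out after a few hundred
milliseconds, which is what makes a *temporal* masking function possible
at all.  The depression constants sit at the fast end of the plausible
0.3-1 s range deliberately: at the protocol's one-second presentation
spacing an attractor must be re-ignitable on the next presentation, and
slower recovery makes completion alternate with presentation history
instead of tracking the mask.

Because the original channel tables are not reproduced here, the spike
currents use the standard minimal cortical parameterization, and every
constant is exposed in `dynamics_config()`.  What the package treats as
load-bearing is the emergent behaviour - ignition in 25-50 ms, burn-out
within a second, completion thresholds - not any individual channel
constant.

Integration is a fixed-step (0.1 ms) linearly-implicit update per
compartment with exponential-Euler gating via lookup tables; synaptic
events travel through a circular delay-line buffer with delays quantized
to the step (the 10 ms inter-areal latency is exactly 100 steps).  The
engine is deterministic: one seed wires an individual, a second drives
the trial's noise and stimulus times, and the same pair replays
bit-identically.

## The masking protocol

A trial is 8 presentations at 1000 ms spacing: target alone, mask alone,
then target+mask at SOAs of 20-120 ms in 20 ms steps (ascending).  Targets
are 20 ms, masks 60 ms (model 1) or 50 ms (model 2); relay cells fire at
50 Hz, so each stimulated relay fires once for a target and three times
for a mask, at uniformly random times inside the stimulation window.
Model 2 consumes a fresh line pattern (a fresh minicolumn index) for every
presentation because attractors do not fully recover from adaptation
within the one-second spacing.  An experiment simulates 5 individuals
(independently wired networks) x 5 trials per condition set; the
feedback-off condition reuses the identical individual minus its V2->V1
synapses, so feedback comparisons are paired.

Completion is scored per presentation: a pattern is complete in an area
when at least ceiling(0.7 n) of its n minicolumns (7 of 10, or 7 of 9)
each fire at least 10 layer-2/3 pyramidal spikes between target onset and
the end of the presentation slot.  The `both` scope - completion in V1
and V2 simultaneously - is the proxy for perception.  `masking_curve()`
aggregates completion percentages per SOA and `classify_masking_type()`
labels the curve: type A if completion is nondecreasing in SOA within a
tolerance, type B if an interior SOA dips below both the first and last
SOA by more than the tolerance (the U-shaped visibility function).  The
default tolerance is one trial's worth of percentage.

## Desk scale and calibration

Full-scale networks (about 100,000 four-compartment neurons) are cluster
material.  The `scale` parameter divides per-minicolumn cell counts
(rounding half up, floor one pyramidal) and never touches geometry, so
patterns and the completion criterion are unchanged.  Two compensations
keep desk-scale dynamics comparable: presynaptic-count weight scaling
(total drive per cell is preserved), with the probability component
raised toward 1 first on sparse pathways (recurrent, interlaminar,
LGN->pyramidal) to avoid small-pool input-count variance that would make
ignition all-or-none; and mean-preserving lognormal weight jitter
(sd 0.35 of log-weight), which restores the heterogeneity that makes
per-minicolumn ignition graded rather than binary.  The package defaults
were produced by the `calibrate()` procedure at scale 0.25: target-only
presentations complete regionally in at least 90% of probe trials,
mask-only presentations never complete the target pattern, and no
runaway activity develops.  A few wiring constants are calibrated per
model.  Model 2 ships a higher excitatory scale (1.25) and a stronger,
faster feedforward cue into V2: its 9-minicolumn lines lean harder on
long-range completion across hypercolumn rows.  Model 2 also uses a
weaker relay-to-basket feedforward weight plus a 3 ms basket-to-pyramidal
delay: with line masks that never share a hypercolumn with the target,
masking is carried by competition between ignited attractors rather than
by the instantaneous afferent inhibition that dominates inside shared
hypercolumns in model 1.  Model 1, conversely, runs with a weaker
interlaminar (L4 to L2/3) coupling and a stronger relay drive and
feedback: the slow laminar hand-off opens the temporal window in which a
trailing mask's inhibition can abort the half-built target attractor
(the substance of its masking function), the strong relay drive keeps
re-ignition reliable across the eight presentations of a trial, and the
strong feedback makes the completion difference between the
feedback-on and feedback-off conditions large and consistent.

The shipped experiment sizes in `scripts/acceptance.R` and the acceptance
tests (scale 0.25; model 1: 2 individuals x 3 trials per feedback
condition plus a 3 x 4 target/mask-only set; model 2: 2 x 2 at mask
distance 1 and 2 x 1 at distance 3) are the package's chosen desk-scale
study conditions; they trade Monte-Carlo resolution for tractable
single-CPU runtimes and are stated here once so that every report derived
from them can be read with the right error bars in mind (one trial is
16.7 or 25 percentage points on a curve).

## What the generator does and does not emulate

The synthetic stimuli are abstract: four dots (or broken lines) of relay
volleys, not images; there are no oriented receptive fields, no off-center
cells, no color blobs, no binocular stripes, and no layer 6.  Passing
tests therefore show that the *attractor-completion account of masking*
behaves as described - they do not show that a retinotopic image pipeline
would reproduce psychophysical masking functions quantitatively.  Within
that scope the model reproduces the directional phenomena: completion
rises with SOA when the mask is strong and close (type A), dips at
intermediate SOA when competition is attractor-borne (type B), weakens
with mask distance, and is consistently helped by feedback.

## Numerical choices and degenerate inputs

Delays are rounded to the nearest step and floored at one step; the
optional 3 ms basket-to-pyramidal delay survives rounding exactly at
dt = 0.1 ms.  Membrane potentials outside (-500, 500) mV or non-finite
raise an error naming the compartment, cell and time.  Degenerate
configurations are contracts, not accidents: a zero-duration stimulus is
an empty schedule, an empty location set is an error, a mask-only
presentation scores the (unstimulated) target pattern, and requesting
more patterns than the minicolumn capacity fails with the violated
constraint named.  Whole-set redraws (bounded at 1000) make the random
pattern generator immune to stranded-capacity dead ends, which exhaustive
small-grid tests exercise.

## Known limitations

Layer 5 receives strong feedback but projects nowhere further (the model
has no subcortical or higher-area consumers), so the functional feedback
route is the direct L2/3 leg plus di-synaptic inhibition of competitors;
V2's interlaminar conductances are boosted (1.5) to stand in for the
missing areas above it, and desk-scale results are Monte-Carlo coarse.
Conduction-velocity gradients for horizontal axons are not modelled -
only the inter-areal 10 ms latency is.
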