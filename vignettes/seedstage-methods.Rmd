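---
title: "Detecting the kinetics of early seedling development: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the kinetics of early seedling development: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(seedstage)
```

## The problem

Seedling establishment is a sequence of ontological stages that occur in a
fixed order: the seedling emerges out of the soil (first appearance of the
cotyledon, **FA**), the cotyledons open (**OC**), and the first true leaf
appears (**FL**); before emergence a pot shows only **Soil**. Top-view tray
time-lapses — hundreds of pots per tray, one frame every 15 minutes during a
16 h photoperiod — make it possible to time these events on a seed-to-seed
basis, but only if every frame of every pot can be classified automatically.
`seedstage` implements the full chain: tray rectification and pot
extraction, background removal, four frame-classification strategies that
differ in how they use the ontological order as prior knowledge, temporal
post-processing, and per-pot event-timing with evaluation machinery.

Because raw imagery of this kind is rarely redistributable, the package
treats a **synthetic tray generator** as a first-class module: every
downstream stage is developed and tested against scenes whose per-pot
transition frames are known exactly.

## The synthetic generator

A scene (`scene_config()`) fixes the tray geometry (pot grid, default
10 x 20 pots of 89 px; five white landmark discs at the tray centre and the
four margin corners), the cadence (15 min frames, 16 h photoperiod, night
frames not rendered — frame indices are contiguous over kept frames while
timestamps carry the true overnight gaps) and a noise regime. Per-pot
transition frames are drawn by `sample_stage_schedule()`: germination with
probability 0.9 by default, then gamma-distributed delays (emergence around
20 % of the sequence, FA lasting ~12 %, OC ~25 %, sds of about a quarter of
each mean) — a standard right-skewed model for emergence timing, scaled to
the sequence length so short test scenes behave like shrunk full scenes.
Transitions beyond the last frame are censored to "never reached".

Stage renderings are parameterised ellipse lobes on textured brown soil
(hue ~20°): FA is a single small closed green blob (hue ~110°), OC two
separated cotyledon lobes, FL two larger lobes plus a central third lobe.
No quantitative description of real pot appearance is available to copy,
so the shapes are chosen to make the four classes separable by a small CNN
at the `"easy"` preset, with a difficulty knob for the harder regimes:

* **circadian movement**: lobes are displaced and partially *close* on a
  day/night-locked rhythm (closed around dawn, fully open by midday, with
  a small per-pot phase jitter), so at `"medium"`/`"hard"` the morning
  frames of an OC/FL pot approach the FA silhouette — ambiguous on a
  single frame, resolvable from temporal context (this emulates the
  circadian error source near stage boundaries in real data);
* **per-pot size variability**: each pot carries an overall plant-size
  factor, so the stage-wise sizes of different pots overlap between
  adjacent stages — the synthetic analogue of cotyledon-size differences
  between accessions, the other dominant boundary-confusion source; a
  memoryless classifier cannot calibrate to the individual, a recurrent
  one can;
* **overlap**: a lobe occasionally extends into a neighbouring pot;
* **degenerate renderings** and additive RGB pixel noise.

What the generator deliberately does *not* emulate: real soil texture and
moisture changes, species-specific cotyledon morphology, lighting drift,
condensation, or occlusion by neighbouring plants at late stages. Passing
tests on synthetic scenes therefore demonstrate the correctness of the
pipeline's machinery and the qualitative behaviour of the strategies, not
field-ready accuracy figures on any particular crop.

## Pre-processing

`detect_landmarks()` binarises the value channel at a fixed threshold
(200/255 by default — acquisition assumes controlled lighting), labels
connected components (EBImage), drops components below a minimum area and
keeps the five largest; roles are assigned by the quadrant of each
candidate's angle about the most central one (ties in centrality broken by
row-major scan order, deterministically).

`estimate_tray_orientation()` recovers the tray's in-plane rotation from
the modulus of the 2-D Fourier spectrum. The pot grid contributes two
orthogonal harmonic arms of nearly equal energy, which makes the spectrum
4-fold symmetric — ordinary second moments (PCA) of such a distribution are
degenerate, with the moment matrix close to isotropic at every rotation. The
estimator therefore computes the principal orientation from the
**fourth-order circular moment** (the quadrupled-angle resultant) of the
spectral mass, which is invariant under the 90° arm symmetry and unbiased
under isotropic noise. Numerical choices that matter: a Hann window (border
suppression), moments taken in normalised frequency units (cycles/pixel, so
non-square regions are not distorted), restriction to a mid-frequency
annulus (0.05–0.35 cycles/px) where the grid harmonics live, and an
adaptive threshold at 4x the annulus median modulus to remove the Rayleigh
noise floor. The resultant length doubles as an anisotropy score; below
0.05 the orientation is declared undefined. Angles are folded into
(−45°, 45°], matching the grid's symmetry; measured round-trip error is
under 0.6° across ±30°.

`rectify_tray()` rotates by the negative estimated angle about the central
landmark and then applies the projective map sending the four corner
landmarks to their geometric targets (half a margin outside the grid
corners), with bilinear interpolation; the output raster contains exactly
the pot grid, so `extract_pots()` can tile it row-major into disjoint
pot-sized crops that partition the grid. The order — rotation first, then
projection — was an open design point; doing the rotation first keeps the
homography close to a pure scale/translation and makes the estimated angle
independently testable.

`remove_background()` keeps pixels whose HSV hue lies in a green band
(default [70°, 160°], with S ≥ 0.2, V ≥ 0.15) and zeroes the rest. It is a
pure per-pixel mask, hence idempotent; optional small-object removal sits
behind a flag.

## Classification strategies

All four strategies share one feature extractor: four 3x3 convolution
layers (64, 128, 256, 256 filters), each followed by ReLU and 2x2
max-pooling, then a 512-unit fully connected layer with ReLU and dropout
(p = 0.5) and a softmax output — trained by minimising empirical
cross-entropy risk with Adam at learning rate 0.001.

* the **multi-class CNN** scores each frame independently (no temporal
  prior);
* the **chained 2-class CNNs** encode the ontology explicitly: M1
  (Soil/FA) scans the sequence until its first FA, then M2 (FA/OC) takes
  over, then M3 (OC/FL); after the first FL everything is FL. At a
  hand-over frame the incoming model re-scores that frame; already-emitted
  labels are never revised, so the output is non-decreasing by
  construction;
* the **CNN-LSTM** inserts a 128-unit peephole LSTM between the conv
  features and the classification head;
* the **ConvLSTM** replaces the LSTM's affine maps with same-padded 2-D
  convolutions over the final feature maps.

The recurrent cells are implemented from their gate equations with
elementwise (diagonal) peephole weights. One convention deserves note: the
output gate's peephole reads the **previous** cell state, exactly as the
gate equations are written here, although many implementations use the
freshly computed state; both are available
(`peephole_output = "previous"/"current"`) and both are gradient-checked.
At 1x1 spatial extent the ConvLSTM cell reduces exactly to the LSTM cell
with the same weights, which the tests exploit as a reduction oracle.

No deep-learning framework is involved: the package carries its own
engine — im2col convolutions as single BLAS GEMMs, hand-derived backprop
(the input gradient of a stride-1 same-padded convolution is another
im2col GEMM with spatially flipped kernels), 2x2 max-pool with winner
caching, inverted dropout, and bias-corrected Adam. Every gradient path is
verified against central finite differences in the test suite. Further
numerical choices: pixels are presented in [0, 1]; weights use uniform
fan-in initialisation U(±sqrt(6/fan_in)); the LSTM forget-gate bias starts
at 1; training is bit-reproducible given the seed (initialisation,
shuffling and dropout all hang off it).

Temporal models are trained by backpropagation through time on
fixed-length chunks (default 32 frames) with zero initial state — whether
full-sequence or chunked training was used originally is unstated, and
chunking keeps memory bounded; inference always consumes full sequences
with zero initial state. Two optimisation stabilisers are available and
matter at desk scale: global-norm gradient clipping (default ceiling 5),
and truncated-BPTT state carryover (`carry_state`), which visits one
sequence's chunks in order and carries the recurrent state across chunk
boundaries as a constant. Carryover aligns the state distribution seen in
training with the one seen at full-sequence inference; without it, a model
trained only on zero-state chunks systematically mis-handles late-sequence
states, which is visible as unstable accuracy on small sequence sets.

## Post-processing

Predicted label sequences are smoothed by an **ordinal median**: each
position is replaced by the floor((n+1)/2)-th smallest label in its window
of n consecutive labels (the lower median — never an average of ordinal
codes, so the output is always a valid stage), windows truncated at the
sequence boundaries. The window placement was an open design point; the
default is **centred**, the standard median-denoising placement, because
it leaves clean monotone transitions exactly where they are — which makes
post-processing idempotent and detection delay-free. A trailing variant
(window ending at the current frame, i.e. labels revised only from their
recent history) is available, at the cost of a systematic floor(n/2)-frame
detection delay per pass — a delay that also makes repeated application
keep shifting transitions, so trailing smoothing cannot be idempotent.
The shipped default window is 4 frames — one hour at the 15-minute
cadence — and `sweep_window_size()` reproduces the selection: under
isolated-flip noise the accuracy curve rises to a small optimum and falls
again as over-smoothing swallows short true stages.

A second rule enforces the ontology: the smoothed sequence is clamped to
its running maximum, so once a stage is reached the label never regresses
(the typical failure this fixes is the first leaf growing out of the crop
frame, leaving only cotyledons visible and tempting the classifier back to
OC). The running maximum is one reading of how a "keep the stage" rule can
be formalised; it is the least aggressive operator that guarantees
monotonicity while never lowering any label.

## Event timing and evaluation

After post-processing, the transition into each stage is the first frame
whose label equals (or exceeds) the stage — stages label *periods*, so the
period start is the event. Events on the first frame of a day are flagged
`gap_*`: the true transition may have happened overnight, when no frames
exist. Sequences that never reach a stage report "not reached".

Evaluation builds 4x4 confusion matrices (rows = true) and derives
one-vs-rest accuracy, error, sensitivity, specificity, precision, false
positive rate and F1 (computed as 2TP/(2TP+FP+FN); the harmonic-mean form
is asserted equal in the tests). Macro summaries report mean ± sd across
the four classes; the dispersion across pots/sequences can be obtained by
grouping the per-pot traces instead, and the output labels which one it is.

Train/validation/test splits are **by tray, never by pot**, to avoid
cross-sampling between splits; single-tray scenes fall back to
resubstitution with an explicit flag and warning.

## Problem sizes used in the checks

The shipped checks run at desk scale, chosen so the full suite completes
in minutes while still exercising every code path at the full-size reference baseline
input size where it matters:

* parameter recovery: one tray, 3 x 4 pots of 89 px, 64 frames, easy
  regime, full-size reference CNN-LSTM (lr 0.001, 2 epochs, 32-frame chunks);
  recovered event frames are compared with the generator schedule
  (median absolute error ≤ 2 frames);
* architecture ordering: 5 seeds of a two-tray, 3 x 4-pot, 80-frame
  (1.25 day) medium-difficulty scene with a reduced conv stack
  (8, 16, 16 filters; 32-unit LSTM; 10 epochs with state carryover),
  training on one tray and scoring raw frame accuracy on the other.
  Three conditions matter and are deliberate: the 1.25-day span puts the
  second morning's partially closed cotyledons onto OC/FL frames; the
  cross-tray split prevents a memoryless model from simply memorising
  each training pot's plant size; and state carryover removes the
  zero-state/full-sequence mismatch that otherwise dominates recurrent
  training error at this data size;
* window sweep and flip-noise robustness: simulated label sequences
  (200 x 60 frames, 5 % isolated flips), no training involved;
* difficulty monotonicity: mean absolute event error of a small CNN
  pipeline compared across the easy/medium/hard presets (2 x 3 pots,
  48 frames, 3 seeds per level);
* counting contracts (dataset sizing, 200 pots per tray, 5 landmarks) run
  at full tray geometry — sizing needs no rendering, so the 2 x 200 x 768
  accounting check expands the schedule only.

## Known limitations

* The generator's plants are schematic; absolute accuracies on synthetic
  scenes say nothing about any particular species or soil.
* The orientation estimator needs periodic grid structure; a tray without
  visible pot boundaries would fall back to "orientation undefined".
* The trailing median delays every detected transition by about half a
  window; downstream users comparing genotypes are unaffected (the bias is
  common to all pots) but absolute timings carry it.
* Night gaps are only flagged, not imputed; probabilistic gap-filling is
  out of scope.
* Training runs on CPU via BLAS; the engine is sized for desk-scale
  experiments, not for re-training on full 70-tray campaigns.
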