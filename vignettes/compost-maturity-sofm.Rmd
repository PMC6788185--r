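---
title: "Classifying compost maturity from image colour statistics with SOFM and LVQ1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying compost maturity from image colour statistics with SOFM and LVQ1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compostmap)
```

## The problem

Composted organic matter passes through visually distinguishable stages as it
matures: fresh material is light and straw-coloured, mature compost dark
brown. Practitioners traditionally judge maturity by eye (colour, granulation,
smell), which is subjective and hard to standardise. Because the optical
change is dominated by colour, simple per-image colour statistics carry enough
signal to classify maturity into discrete stages — here, five classes ordered
from fresh to fully mature.

compostmap implements that classifier as a pipeline: colour-statistic
feature extraction, an unsupervised 15×15 Kohonen self-organising feature map
(SOFM), majority-vote labelling of the map's nodes into the five classes, and
supervised fine-tuning of the labelled prototypes with the LVQ1 rule. A
synthetic image generator stands in for laboratory photographs so that every
stage is testable end to end.

## Colour descriptors

Each image is summarised by 30 numbers: for five derived channels —
HSV saturation $S = (\max - \min)/\max$ (0 for pure black), BT.601 luminance
$Y = 0.299R + 0.587G + 0.114B$, and the raw $R$, $G$, $B$ channels — the
mean, median and standard deviation are computed twice: over **all** pixels
("full" mode) and over **non-black** pixels only ("noblack" mode). A pixel is
black when $\max(R,G,B) \le$ `black_threshold`; the default threshold 0
counts only exact black, which is precisely what the synthetic generator
emits as background. For real photographs with near-black shadows the
threshold is a user-facing knob.

Conventions that are fixed (and pinned by tests) rather than universal:

* saturation stays on the $[0,1]$ scale; the min–max normalisation applied
  before training makes any per-feature scale immaterial, but serialised
  models depend on the choice;
* medians of even pixel counts average the two central values;
* standard deviations use the population convention (divide by $n$);
* the feature order is mode (full, noblack) slowest, channel
  (sat, lum, r, g, b), then statistic (mean, median, sd) fastest.

All descriptors are averages or order statistics of per-pixel values, so they
are invariant under pixel replication — image resolution does not matter in
expectation, which is why the generator can work at 64×64.

## The synthetic benchmark

The generator emulates the one property of compost photographs the
classifier actually uses: class-conditional colour. Its defaults are package
constants:

* five class means on a straight line in RGB space from light straw
  (200, 180, 120) to dark brown (60, 40, 25);
* per-channel pixel standard deviations (8, 8, 5), chosen so each channel's
  between-class mean gap is at least four within-class standard deviations
  (the tightest margin is blue: gap 23.75 against 4 × 5);
* 5% exact-black background pixels per image (`black_fraction = 0.05`),
  the count forced to exactly `round(black_fraction · h · w)`;
* spatial smoothing `pixel_corr = 0.3`: each channel is blended with a 3×3
  box blur, `(1 − c)·z + c·blur(z)`. The smoothing is cosmetic — the
  descriptors are per-image statistics — and is kept mild so per-image
  feature variance stays small;
* 3048 images of 64×64 pixels, benchmark seed 20190907.

What the generator does **not** emulate: compost texture and granulation,
illumination variation, lens vignetting, JPEG compression artefacts, class
imbalance, or intermediate/ambiguous maturity states. Passing the benchmark
therefore demonstrates that the pipeline is implemented correctly and can
separate classes whose colour distributions are well separated; it does not
certify performance on real photographs, where class overlap is the hard
part.

Every image's seed is derived from the benchmark seed by a counter scheme
(`derive_seed`), so the full image set is a pure function of the
specification, and the in-memory route (`generate_feature_table()`) is
byte-equivalent to rendering PNGs and re-reading them (8-bit PNG is
lossless).

## Split and normalisation

`split_211()` assigns cases to training/validation/test at exactly 2:1:1
(remainder cases go to train, then valid, then test). The assignment is
stratified by class: each class is allocated near-proportionally by largest
remainder, then single cases are moved deterministically until the exact
global totals are met. The published procedure says only that cases were
"conventionally divided" at this ratio; stratification is this package's
choice, made to keep all five classes represented in the two small folds.

Features are min–max scaled to $[0,1]$ using minima and maxima from the
**training partition only** (no leakage); validation and test values outside
the training range are clipped, and features constant on the training
partition map to 0.5. The $[0,1]$ range matches the uniform initialisation
of the map's prototypes.

## The self-organising map

The map is a 15×15 grid (225 nodes) of prototype vectors in the
30-dimensional feature space, coordinates 0-based and row-major, grid
distance Euclidean on integer coordinates. Training is the online Kohonen
algorithm: present one case at a time (shuffled each epoch), find the
best-matching unit (BMU) — the node minimising Euclidean distance, ties to
the smallest row-major index — and move every node towards the case:

$$w_k \leftarrow w_k + \alpha(t)\, h(k, \mathrm{bmu}, r(t))\,(x - w_k),$$

with a Gaussian neighbourhood $h = \exp(-d^2 / 2r^2)$ by default (a bubble
kernel is available). Training has two phases, a coarse ordering phase and a
fine-tuning phase; the published description states the two phases exist but
gives no numbers for them, so the defaults are declared package constants:

| parameter | default | meaning |
|---|---|---|
| `phase1_epochs` | 1000 | ordering phase length |
| `phase2_epochs` | 2000 | convergence phase length |
| `lr_start → lr_mid → lr_end` | 0.9 → 0.1 → 0.01 | linear decay within each phase |
| `radius_start → 1`, then `radius_end` | 7.5 → 1, then 0.5 | phase-1 shrink; phase-2 fixed |
| `neighbourhood` | gaussian | kernel |

Linear decay was chosen as the simplest schedule consistent with a stated
"0.9–0.01" style range; the radius starts at half the grid so early updates
organise the whole map. Because every update is a convex combination of a
prototype and a case, prototypes of data in $[0,1]^{30}$ remain in
$[0,1]^{30}$.

Numerical choices: neighbourhood weights below $10^{-12}$ are skipped during
updates (with the phase-2 radius of 0.5 almost all of the 225 nodes fall
below this; the cumulative skipped effect is bounded by roughly $3\times
10^{-7}$ per coordinate). The per-epoch quantization error logged in
`meta$qe` is the *online* one — each case's distance to its BMU at
presentation time — which costs nothing extra; `quantization_error()`
recomputes the exact post-hoc value.

## Labelling and LVQ1

`label_map()` gives each node the majority class among the training cases it
wins, ties to the smallest class id. Nodes that win no case inherit the label
of the nearest directly-labelled node by grid distance (ties to the smallest
row-major index), so the classifier is total. `class_regions()` reports how
many 4-connected components each class occupies — a coherent map has one
territory per class.

LVQ1 then fine-tunes the labelled prototypes supervised: only the BMU moves,
towards a same-class case and away from a different-class case,

$$w \leftarrow w \pm \alpha(t)(x - w),$$

for 3000 epochs with the rate decaying linearly 0.9 → 0.01 and shuffled
("mixed") case order — the published training parameters. Validation quality
is computed after every epoch and the prototypes from the best validation
epoch are returned (ties keep the earliest); whether the original experiment
selected or merely logged the best epoch is not stated, and selection is this
package's declared behaviour. The published configuration also lists
`epsilon = 0.35` and `beta = 0.25`; the textbook LVQ1 rule has no such
parameters (they govern window-based LVQ2/3 variants), so they are carried in
the schedule and model metadata for provenance but not interpreted —
inventing a semantics for them would be guesswork. Early stopping is off by
default (the published run used fixed 3000 epochs); a patience flag exists
for desk-scale experiments.

## Evaluation

Classification *quality* is the fraction of concordant classifications.
*RMSE* follows the sum-of-squares / count / root definition over the
network's 5-component output; with the crisp winner-take-all one-hot encoding
used here, a misclassified case contributes exactly two unit errors among
five components, giving the identity

$$\mathrm{RMSE} = \sqrt{2\,(1 - \mathrm{quality})/5},$$

which the tests assert, making the two metrics mutually checking. The
original software evidently used a soft internal output encoding (its
published quality/RMSE pairs do not satisfy the crisp identity), but that
encoding is not recoverable, so the crisp form — the simplest total
specification — is used and documented. Every confusion matrix is 5×5
(rows = true class), and per-partition quality equals the trace over the
total by construction.

## Reproducibility and problem sizes

A single master seed drives a whole `run_benchmark()` call: generator,
split, map initialisation, SOFM shuffling and LVQ1 shuffling seeds are all
derived from it by a counter scheme, and the shuffles themselves use a
Mersenne-Twister stream with an explicit Fisher–Yates implementation, so
runs are bit-reproducible. Model files are JSON with 17-significant-digit
numbers, enough to round-trip IEEE doubles exactly.

The test suite exercises the full-scale benchmark (3048 images, the complete
1000 + 2000 SOFM and 3000 LVQ1 epochs) over three master seeds; unit and
property tests use reduced instances — tens to a hundred images of 8–16
pixels square, maps of 4×4 to 5×5 nodes, tens of epochs — which are the
sizes at which the tested properties (determinism, oracle equivalence,
metric identities, monotone separability) are already binding.

## Limitations

* The default benchmark is deliberately well separated; headline accuracy on
  it is near-perfect and says nothing about photographs of real compost.
* The classifier has no rejection option: every input receives one of the
  five classes, however far it sits from all prototypes.
* Features are global per-image statistics; images containing mixed
  materials or large non-compost objects (beyond exact-black background)
  violate the model's assumptions.
* JPEG input is supported for completeness (via EBImage) but the synthetic
  benchmark is PNG-only; compression noise is not modelled.
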