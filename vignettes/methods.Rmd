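---
title: "Methods: enhancer window classification and Grad-CAM boundary condensation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer window classification and Grad-CAM boundary condensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Enhancers are distal cis-regulatory elements of roughly 50–1500 bp.
Classical predictors label whole genomic windows (typically kilobases) as
"enhancer" or "not", which buries a short functional core inside a much
larger annotation and dilutes downstream analyses such as variant
enrichment.  This package treats enhancer discovery as a *weakly
supervised object-detection* problem in one dimension:

1. A convolutional binary classifier decides whether a 4 kb window of five
   co-registered epigenetic signals contains an enhancer.  Training labels
   come from STARR-seq activity peaks corroborated by chromatin
   accessibility and active histone marks — region-level ("fuzzy") labels
   only.
2. For windows called positive, Grad-CAM (gradient-weighted class
   activation mapping) converts the classifier's own gradients into a
   per-10 bp-bin importance score, and bins scoring above a global cutoff
   are merged into *refined* core-enhancer intervals that were never
   explicitly labeled during training.

## Input representation

Each window is a 5 × 400 matrix: five assays (rows) by 400 bins of 10 bp
(columns), each entry the mean base-resolution signal in that bin.
Missing coverage counts as zero, so binning conserves signal mass.  The
assay panel is ordered with chromatin accessibility in the middle row
(H3K4me3, H3K9ac, accessibility, H3K27ac, H3K4me1 by default) so that a
5-row convolution kernel always sees accessibility flanked by histone
marks, maximising cross-assay interactions inside a kernel.  Signal values
are used as given; no cross-assay normalisation is applied.

All interval semantics are BED: 0-based, half-open.  Windows that would
extend past a chromosome end are dropped during scanning (the 5 × 400
shape is invariant) but shifted inward during training-set construction
(positives are too precious to drop).

## Classifier architecture

Seven convolutional layers with squeeze-and-excitation (SE) channel gates
between consecutive layers, two max-pooling layers, and two dense layers
ending in a sigmoid:

| stage | layer | kernel | padding | output |
|-------|-------|--------|---------|--------|
| 2D | conv1 + SE | 5 × 10 | same | k × 5 × 400 |
| | max-pool | 1 × 4 | — | k × 5 × 100 |
| 2D→1D | conv2 + SE | 5 × 10 | valid height, same width | k × 100 |
| 1D | conv3–conv7 (+ SE after 3–6) | 1 × 4 | same | k × 100 |
| | max-pool | 1 × 4 | — | k × 25 |
| head | dense(64) + ReLU + dropout(0.3), dense(1) + sigmoid | | | P(enhancer) |

Design notes, where the design was genuinely open:

* **conv1 keeps the assay axis.**  Its activation maps are 5 × 400, so the
  feature-wise Grad-CAM map is natively assay × bin with no height
  interpolation.  conv2 then removes the height padding and collapses the
  five rows, making every later layer 1D along the genome.
* **Pooling placement.**  The first 1 × 4 max-pool sits between the two 2D
  convolutions rather than after the full 2D stage.  This widens conv2's
  receptive field (each of its 10 width taps spans 40 bp) and keeps the
  collapse convolution — by far the widest kernel, 5 × 10 over k channels —
  running at 100 positions instead of 400, which is what makes single-CPU
  training practical.  The classifier's capacity is unaffected; the
  position-wise Grad-CAM grid is 100 cells (40 bp each) either way, and
  scores are interpolated back to the 10 bp bin grid.
* **SE blocks** use the classic squeeze-excitation form: global average
  pool per channel, a bottleneck (reduction 4) with ReLU, a sigmoid gate,
  and channel-wise rescaling of the layer output.  They sit after conv1
  through conv6 ("between every convolution layer"); conv7's output is the
  position-wise Grad-CAM layer.
* **Defaults**: 32 filters per layer, 64 dense units, dropout 0.3,
  binary cross-entropy loss (implied by the sigmoid head).  All are
  exposed in `model_config()`.

## Training configuration

`train_config()` defaults: Adam at learning rate 5e-5, up to 100 epochs,
early stopping on validation loss with patience 10 (best weights
restored), an 80–20 train/validation split stratified by label, batch
size 64, and inverse-frequency class weights `w_c = N / (2 N_c)` that
equalise the total weight of the two classes under the 1:10
positive:negative imbalance.  The validation loss monitored for early
stopping uses the same class weights as training.

Training runs in single precision (the convention for this model family);
inference and Grad-CAM gradients run in double precision.  All random
elements — initialisation, the split, per-epoch shuffling, dropout —
derive from explicit integer seeds, and a fixed seed reproduces training
bit-for-bit on a single thread.

## Grad-CAM

For the positive class, the weight of filter $k$ at conv layer $l$ is the
global average of the gradient of the class score over all spatial
positions of that filter's activation map,
$a_k = \tfrac1Z \sum_i \sum_j \partial y / \partial A^{k,l}_{ij}$,
and the map is $\mathrm{ReLU}(\sum_k a_k A^{k,l})$.  Choices:

* Gradients are taken of the **pre-sigmoid logit** (standard Grad-CAM
  practice; a flag switches to the post-sigmoid probability).
* The **position-wise** score comes from conv7 (the last 1D layer) and is
  linearly interpolated from the 100-cell pooled grid to the 400 bins;
  pooled cell $p$ covers bins $4p..4p{+}3$, so its value is anchored at
  bin coordinate $4p + 1.5$ and the ends are extended constantly.
* The **feature-wise** score comes from conv1 and is already 5 × 400.
* Gradient correctness is enforced in the test suite against a central
  finite-difference oracle on a loop-based reference implementation of
  the forward pass (relative error below $10^{-3}$ at $\varepsilon =
  10^{-4}$).  Finite differences are only valid away from max-pool ties,
  so the toy models used there lift the biases of the pooled layers until
  their activations are strictly positive.

## Genome scanning and condensation

The genome is tiled with 4 kb windows at 500 bp steps; a window is
positive when its probability strictly exceeds 0.5.  Merged positive
windows (overlapping or book-ended) form the *original* annotation.  The
refinement cutoff is the arithmetic mean position-wise score over every
bin of every positive window — unweighted by window, computed only after
the whole scan.  Within each positive window, bins strictly above the
cutoff are kept; where overlapping windows disagree, a genomic bin is kept
if *any* covering window selects it (union rule), which is equivalent to
merging all per-window refined intervals.  The refined set is therefore
always inside the original footprint, and raising the cutoff can only
shrink it.

## The synthetic genome generator

`simulate_tracks()` emulates the canonical epigenetic footprint used to
select real training regions: a unimodal accessibility peak over the
enhancer core and a peak–trough–peak shape in the four histone marks.

* Enhancer cores: lengths uniform in 50–1500 bp, placed in evenly spaced
  slots with jitter (so cores never overlap and are well separated),
  across two chromosomes (~25 kb of genome per enhancer).
* Accessibility: Gaussian bump centered on the core, sd = length/4,
  amplitude 10 over background, truncated at 4 sd.
* Histone marks: two Gaussian flank bumps (sd 150 bp, amplitude 6)
  centered 300 bp outside the core edges, and background suppressed by
  80% over the core.
* Background: exponentiated Gaussian noise smoothed with a 50 bp moving
  average — non-negative, autocorrelated, coverage-like; `noise_scale`
  (sd of the log background, default 0.5) controls difficulty, 0 gives a
  flat background of 1.
* Tracks are generated at 10 bp granularity, the same resolution at which
  windows are binned.

Positive windows are centered on each core with a uniform offset (default
±500 bp; the shifted-enhancer analyses use ±1200 bp); negatives are drawn
uniformly from the genome excluding cores and positive windows, at 10 per
positive.

What the simulator does *not* emulate: read-count sampling noise,
fragment-length effects, copy-number and mappability artifacts, assay
cross-contamination, promoter-like signal shapes, overlapping or nested
enhancers, and cell-type mixtures.  Passing tests on this generator
demonstrates that the implementation is correct and that the architecture
can exploit the canonical shape signature; it does not certify
performance on real ENCODE-scale data.

## Problem sizes used in the checks

The test suite trains small models (8–16 filters) on genomes with 20–40
planted enhancers, and one full-scale run with 1000 enhancers (11,000
windows) and the default 32-filter model capped at 30 epochs — enough for
a clearly separable synthetic problem while keeping the whole suite to
minutes.  Boundary recovery is evaluated on a low-noise genome
(`noise_scale = 0.1`) with deliberately off-center windows
(`offset_range = 1200`), summarised by the median per-enhancer Jaccard
index between refined intervals and true cores.

## Known limitations

* The per-layer filter counts, pooling sizes, SE reduction, dropout rate
  and early-stopping patience are defaults chosen here; they are exposed
  in the configuration objects rather than hard-coded.
* The refinement stage assumes position-wise scores are comparable across
  windows (a single global cutoff); no per-window normalisation is
  applied.
* `bin_signal()` treats signal values as given — fold-change versus raw
  coverage tracks will behave differently and should not be mixed within
  a panel.
* Cross-cell-type transfer treats the accessibility row as interchangeable
  between ATAC-seq and DNase-seq panels.
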