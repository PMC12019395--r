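---
title: "Methods: artery and plaque segmentation for ORO-stained slides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: artery and plaque segmentation for ORO-stained slides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models, the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic data generator does and does not emulate, and the design
choices made where the design was genuinely open.

## Problem setting

Murine atherosclerosis is conventionally quantified on cross-sections of
the aortic root stained with Oil Red O, which colors lipid-laden plaque
deep red inside the pale arterial wall. The measurement chain is: find the
artery in the slide, delineate it, delineate the plaque inside it, and
reduce plaque areas to per-mouse statistics. The package automates all
four steps. Artery delineation is a supervised problem (labs hold large
hand-labelled mask collections); plaque delineation is treated as
unsupervised, because pixel-accurate plaque labels are rarely available at
scale.

## Stage 1: ROI proposal

The detector is a pluggable contract: any function mapping a slide to
scored boxes. The built-in desk-scale implementation is a color-saliency
proposer — pixels far (Euclidean RGB distance, default threshold 40 of
255) from the slide's median color are marked salient, the largest
8-connected component wins, and its tight box is returned. For production
use an external one-class object detector can be substituted without
touching the rest of the pipeline.

Two hard rules make the stage total. First, no detection means the full
frame is used. Second, if the padded crop is smaller than the segmentation
input size in either dimension, the full frame is used too: cropping below
the network's input resolution would discard information rather than
preserve detail. Box padding defaults to 5% per side — a detector's tight
box routinely clips the adventitia, and small padding costs almost nothing
in resolution.

## Stage 2: supervised artery segmentation

### The loss

Training minimises the sum (equal weights by default) of three terms: soft
Jaccard loss, soft Tversky loss with $\alpha = 0.3$, $\beta = 0.7$, and
mean binary cross-entropy. The region terms use real-valued sums with an
$\varepsilon$-stabilised denominator ($\varepsilon = 10^{-7}$), so the
loss is exactly zero only for a perfect prediction. The Tversky weighting
penalises false negatives more than false positives — losing arterial wall
hurts downstream plaque quantification more than including a margin of
background, which the ensemble voting can later remove. Algebraically the
Tversky term contains Dice ($\alpha=\beta=0.5$) and Jaccard
($\alpha=\beta=1$) as special cases; the test suite asserts both
identities numerically.

### The network family

Four encoder–decoder shapes are provided (U-Net, U-Net++, FPN, PAN) at
depth 2 with a configurable base width and single 3×3-conv blocks. They
are implemented on a small reverse-mode autograd core written for this
package (compiled convolution/pooling/upsampling kernels, R tape), with
every architecture's gradients verified against central finite differences
in the tests. The shapes define the topology of their full-scale
counterparts at a capacity that trains in seconds on a CPU; larger
backbones are deliberately out of scope — the package's contribution is
the pipeline and the combination strategies, and the segmenter behind the
module surface can be swapped.

Networks operate at a fixed 4:3 input size (default 640×480 for
production-sized slides; the tests and the acceptance study use 64×48, a
deliberate desk-scale choice) and return *logit* maps, resized back to the
source resolution by bilinear interpolation of the logits. Returning
pre-activation values is load-bearing: ensemble averaging is defined as
the mean of member logits *before* the output function, which is only
implementable if members expose logits.

### Snapshot ensembles

A snapshot ensemble harvests several converged weight states from one
training run by cycling the learning rate. The package follows the
standard recipe: SGD with momentum 0.9, triangular schedule rising from
`base_lr` (1e-4 default) to `max_lr` (1e-1, a factor of 10³) over
`step_size` steps (default five epochs' worth of batches) and back, one
snapshot per cycle. Design choices worth stating:

* **Capture point.** Snapshots are taken at the end of each descending
  phase, where the learning rate is at its minimum and the weights sit in
  a local optimum. Capturing mid-cycle would store deliberately displaced
  weights.
* **No early stopping** during ensemble training: cycles must complete or
  the snapshot count is undefined. (Standard training uses early stopping
  on validation mIoU with patience 10; mIoU is the monitored quantity
  because it is the study's headline metric.)
* **Gradient clipping** (global norm 1) stabilises the high-learning-rate
  phase at desk scale, where a single hot step can kill the small
  network's activations irrecoverably.
* The desk-scale ensemble study uses `base_lr` 1e-3, a 5e-2 peak and two
  8-epoch cycles: with tens (not thousands) of optimiser steps per cycle,
  the production base rate would leave the first cycle underfitted, and
  the production peak overheats the small networks even with clipping.

### Combination strategies

`combine_overlap()` implements α-of-n voting by summing the stacked
member masks and thresholding at α — a pixel is artery iff at least α
members agree. α = 1 is the union, α = n the intersection, and the
monotonicity in α (area and false positives non-increasing, false
negatives non-decreasing) is asserted as a property test. Ties in
`combine_average()` (mean logit exactly 0) resolve to foreground; the
choice is arbitrary but fixed and documented. The combined ROI ensemble
concatenates half the members of a full-frame ensemble with half of an
ROI-trained ensemble (selected by validation score by default; last-k and
explicit indices are available) and applies the chosen strategy against
n = 2k, so members that never saw the bounding box can overrule box
failures.

## Stage 3: unsupervised plaque segmentation

### W-Net

The W-Net couples two U-Nets: the encoder ends in a per-pixel softmax
over K classes (default K = 4 — plaque, wall, lumen-like and
background-like tissue is the granularity this task needs), the decoder
reconstructs the input from the soft assignment. Each batch applies two
updates: an encoder-only step on the soft normalized-cut loss

$$\mathcal{L}_{cut} = K - \sum_k
\frac{\sum_u p_k(u) \sum_v w(u,v)\, p_k(v)}
     {\sum_u p_k(u) \sum_t w(u,t)},$$

with affinities
$w(u,v) = e^{-\|F(u)-F(v)\|^2/\sigma_I^2}\, e^{-\|X(u)-X(v)\|^2/\sigma_X^2}$
for spatial distances below the radius $r$ (a 0/0 ratio counts as 0), and
a joint encoder+decoder step on mean-squared reconstruction error. The
affinity feature $F$ is pixel brightness on the 8-bit scale by default
($\sigma_I = 10$, $\sigma_X = 4$ px, $r = 5$ px, following common W-Net
practice); a 3-channel color mode is available by flag. The gradient of
the cut term is computed in closed form and checked against finite
differences and a brute-force double-loop oracle.

Numerical choices that proved load-bearing at desk scale:

* **Restarts with objective-based selection.** Unsupervised training is
  initialisation-sensitive: a run can collapse most of the softmax mass
  onto one class and never recover. The trainer runs three independent
  seeded attempts and keeps the one with the lowest final reconstruction
  loss — the same label-free model selection that k-means performs with
  multiple starts. The criterion is honest (a collapsed class structure
  cannot reconstruct the stain contrasts, so its reconstruction loss is
  visibly worse) and uses no ground truth.
* **Instance normalisation** in every conv block of both W-Net halves.
  Without it the class softmax saturates on one class within a few steps
  and gradients to the unused classes die; normalisation keeps the logits
  in range and the partition mobile. The supervised artery networks do not
  need it and run un-normalised.
* **Step balance.** The two steps run under separate adaptive (Adam)
  optimisers, which are invariant to loss rescaling, so the
  `loss_balance` knob is applied as a factor on the encoder step's
  learning rate instead of on the loss value.
* **Native-resolution inference.** The encoder is fully convolutional, so
  class maps are inferred at the artery crop's own resolution (padded to a
  multiple of 4) rather than resized through the training patch size;
  resizing soft maps blurs class boundaries into exactly the
  partial-volume mixtures the downstream color vote struggles with.
* Training patches are artery-box crops with non-artery pixels set to the
  background mean color, so the network never spends classes on
  surrounding tissue structure.

### Color transfer

Dataset-level statistical color transfer runs in the decorrelated lαβ
space (RGB → LMS → log₁₀ → lαβ): each image's per-channel mean and
standard deviation are mapped onto statistics pooled over the whole
dataset (up to 50 000 pixels per image, seeded subsample). Pooled-pixel
statistics — not a mean of per-image means — define "the dataset's color
space", so large slides weigh proportionally. A standard-deviation floor
(`guard_eps`) turns the scaling into a pure shift for constant-color
channels. The transfer is exactly moment-matching before the final
clipping to valid RGB; the tests assert the pre-clip moments to 1e-6 and
an identity-transfer round trip within ±2 of 255.

### From class map to plaque mask

Nothing in an unsupervised class map says which class is plaque, and the
reference post-processing for this stain is under-specified; the package's
reading is a two-stage color assignment. First, a *class-level* vote: each
class's mean RGB is classified plaque / non-plaque by a
k-nearest-neighbour vote (k = 3) against a labelled palette of reference
tones, and the union of plaque-voted classes forms the candidate. Second,
a *pixel-level* refinement: the same k-nn vote is applied to every
candidate pixel's own color, and pixels voting non-plaque are dropped. The
two stages play complementary roles: an unsupervised class is rarely pure,
so the class vote must tolerate partial-volume dilution (the palette's
plaque seeds extend from saturated ORO red well into diluted reds), while
the pixel pass restores precision by removing the wall pixels an impure
class drags along. The strongest dilutions sit close to wall tone and
therefore participate in the class vote only (`pixel_vote = FALSE` in the
palette): at pixel scale, dilution means boundary mixing, and only
confident tones may keep a pixel — this is what keeps plaque-free slides
plaque-free even when a wall-tone class squeaks past the class vote.

Class means and pixel colors are taken on the original, untransferred
slide — the palette seeds are stain colors, and transfer deliberately
moves everything toward the dataset mean. The palette is a configuration
object, not a constant; labs with different stain protocols should
replace it.

The candidate mask then passes a fixed sequence: intersection with the
artery, morphological opening (disk radius 2 px) and closing (1 px),
8-connected component filtering (components under `min_cluster_px` = 10
removed; components exactly at the threshold kept), and the empty-slide
rule: a plaque fraction below 0.5% of the artery area declares the slide
plaque-free and empties the mask. The connected-component labelling is
implemented in compiled code because the available image library labels
4-connected components only, and diagonal plaque fragments must connect.
An adaptive cluster threshold (halved when total candidate plaque is
small) exists behind a flag, off by default.

## Analysis

`seg_metrics()` counts TP/FP/FN/TN pixelwise and derives
mIoU = TP/(TP+FP+FN), precision and recall. Conventions: an empty
prediction of an empty truth scores mIoU 1 (plaque-free slides must be
able to score perfectly); precision with no predicted positives is 0 with
a warning. Quality bins follow the ≤ 0.5 / (0.5, 0.7] / > 0.7 convention
with both boundaries in the lower bin. Summaries report mean ± sample
standard deviation (the column is labelled `_sd` explicitly). Group
comparisons use the equal-variance two-sample t-test on per-mouse medians
(midpoint convention for even slide counts), with Welch's correction
behind a flag and raw pairwise p-values (no multiplicity correction, which
matches how such panels are conventionally reported).

## The synthetic data generator

The generator emulates the features of real slides that the pipeline's
logic depends on: a closed annular vessel wall with smooth low-frequency
radial perturbation around a pale lumen; saturated red plaque blobs
strictly inside the wall with an exact ground-truth mask and a
controllable area fraction (candidate blobs are generated in a fixed
random order and the shortest prefix reaching the target is kept, which
makes the achieved fraction monotone in the target for a fixed seed);
per-subdataset additive color drift; textured background; pixel noise;
4:3 aspect at configurable resolution (default 960×720, the smallest
production size; tests generate smaller). The plaque fraction is capped
below 0.8, matching the upper range of real burdens.

It does **not** emulate valve leaflets, sectioning artifacts, focus
gradients, or the irregular texture of real plaque. Consequently, passing
desk-scale tests demonstrates that the pipeline's machinery — losses,
voting, color transfer, unsupervised partitioning, post-processing,
statistics — is correct and trainable, not that the shipped tiny networks
reach production accuracy on real histology. Production use requires
full-size networks and real labelled data behind the same module
surfaces.

## Problem sizes used by the tests and the acceptance study

Chosen once as the package's desk-scale study conditions: artery stage —
60 slides at 320×240, U-Net++ shape with 8 base channels at 64×48 input,
5 epochs (Adam) and a two-snapshot cyclic ensemble (16 epochs, two
8-epoch cycles); plaque stage — 24 slides at 160×120 with generated
fractions 0 / 0.1 / 0.3, K = 4, 64×64 patches, 10 epochs. Unit and
property tests run on grids between 1×8 and 32×32 against brute-force
oracles.

## Known limitations

* The supervised stage's capacity is deliberately small; mIoU on real
  WSIs with the shipped networks is untested and expected to be modest.
* The class-level color vote assigns whole W-Net classes to plaque; a
  class that merges plaque with wall at low purity produces an
  all-or-nothing error on that slide. More classes or a purer encoder
  reduce the risk, at training cost.
* The empty-slide threshold (0.5%) and the cluster threshold (10 px) are
  resolution-dependent defaults; at other magnifications they should be
  rescaled (a relative-threshold mode exists).
* Color transfer assumes the lαβ decorrelation is adequate for ORO
  staining; other transfer spaces are not implemented.
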