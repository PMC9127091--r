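---
title: "Methods: multi-scale fruit detection with a GIoU position loss"
author: "fruityield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale fruit detection with a GIoU position loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruityield)
```

## The problem

Estimating fruit yield in a plant factory with artificial lighting (PFAL)
requires counting both red (mature) and green (immature) tomatoes in RGB
images of the canopy. Classical color thresholding fails on green fruit,
which is nearly the color of the foliage; a convolutional detector that
fuses color, shape and texture is the standard answer. `fruityield`
implements a desk-scale version of a three-scale grid detector in the
YOLOv3 family, with the positional part of its training objective replaced
by a loss built on the generalized intersection-over-union (GIoU), and
evaluates it with mean average precision (mAP) and a count-ratio yield
accuracy.

## Box overlap: IoU and GIoU

Boxes are axis-aligned rectangles in center form $(c_x, c_y, w, h)$,
treated as continuous regions (no pixel discretization). For two boxes
with intersection area $J$, union $U = w_1 h_1 + w_2 h_2 - J$, and
smallest enclosing box of area $A$,

$$\mathrm{IoU} = \frac{J}{U}, \qquad
  \mathrm{GIoU} = \frac{J}{U} - \frac{A-U}{A}.$$

GIoU equals IoU whenever the enclosure is tight ($A=U$), attains its
maximum 1 exactly at coincidence, and decreases toward $-1$ as the boxes
separate — so unlike IoU it carries gradient information even for disjoint
boxes. Both measures are invariant to joint rescaling and translation of
the pair.

The per-pair position loss used for training is $1-\mathrm{GIoU}$, summed
over the responsible (cell, prior) slots. The classical alternative, also
implemented for comparison, is the Euclidean form
$(x-\hat x)^2 + (y-\hat y)^2 + (\sqrt w - \sqrt{\hat w})^2 +
(\sqrt h - \sqrt{\hat h})^2$, which is *not* scale invariant: shrinking
fruit (distant plants) shrink their loss contribution, which is the
motivation for the GIoU replacement. Both properties are asserted in the
test suite.

```{r giou-demo}
a <- from_corners(c(0, 0, 2, 2))
b <- from_corners(c(1, 1, 3, 3))
box_giou(a, b)            # J = 1, U = 7, A = 9
giou_position_loss(a, b)  # 1 - (1/7 - 2/9)
```

The analytic subgradient of GIoU in the predicted box's center
parameterization (`giou_gradient()`) drives training; the tests verify it
against central differences, and verify GIoU itself against a
lattice-rasterization oracle.

## Priors by 1−IoU K-means

Nine prior (anchor) sizes are estimated from the training labels by
K-means in which the distance between a box size and a centroid is
$1-\mathrm{IoU}$ of the two rectangles co-centered at the origin, so that
the clustering is scale-aware rather than Euclidean. Centroids are updated
as per-cluster mean width and height; initialization is k-means++-style
seeding on the same distance, with restarts (default 10) keeping the best
total within-cluster distance. Because the mean update is a heuristic for
the IoU objective, an update that fails to decrease the total distance
terminates the loop with the previous centroids, making the recorded
per-iteration trace non-increasing by construction.

The nine sizes are assigned to the three grids by area: the three
largest-area priors to the coarsest grid (13×13 at a 416-pixel input),
the three smallest to the finest (52×52). Area is the package's single
ordering key; printed reference allocations that deviate from a pure area
ordering in one adjacent pair are not reproduced exactly.

## Grid encoding and decoding

At input size $N$ the detector predicts at strides 32/16/8, giving grids
$S = N/32, N/16, N/8$, each cell holding $B = 3$ priors with
$4 + 1 + C$ channels (box, objectness, $C = 2$ class scores) — a total of
$\sum_s S_s^2 B$ candidates, 10,647 at $N = 416$. Each labeled object is
assigned to the cell containing its center at the scale of its
best-matching prior (co-centered IoU, ties to the smaller prior); that
slot receives objectness 1 and the class one-hot. If two objects claim
one slot the larger wins and the collision is counted. Raw outputs decode
with the standard parameterization: center $(\mathrm{cell} + \sigma(t))/S$,
size $\mathrm{anchor}\cdot e^{t}$, confidence
$\sigma(t_o)\cdot\max_c \sigma(t_c)$. The paper family never restates
this transform; it is adopted from the cited architecture. Non-best
priors whose co-centered IoU with an object exceeds 0.5 are excluded from
the no-object confidence loss.

## The detector and its training

The backbone mirrors the reference topology at reduced width: five
stride-2 stages, feature maps at 1/8, 1/16, 1/32, upsample-and-concatenate
fusion from coarse to fine, and a 1×1 head per scale. Channel widths are
`(16, 32, 64, 128, 256, 512) * width_multiplier`; the base profile is half
the full reference backbone, and the desk-scale setting is 0.25. Every
backbone convolution is followed by per-image channel normalization with a
learned scale and shift (the batch-free analogue of the normalization the
reference architecture applies after each convolution) and a leaky ReLU
(slope 0.1); heads are plain linear convolutions whose objectness bias is
initialized to −4 and whose box-channel weights are damped at
initialization, so an untrained network predicts background nearly
everywhere.

Training is plain SGD with momentum per the reference recipe: defaults of
700 cycles, batch 8, momentum 0.9, learning rate 0.001 multiplied by 0.1
after 400 cycles; validation mAP is evaluated every 10 cycles and the best
checkpoint kept (the source protocol likewise scores the test set every
10 cycles and keeps the best model). Each training draw is randomly
augmented by quarter turns and flips with consistently transformed
labels, the geometric part of the image-enhancement protocol; it can be
disabled with `augment = FALSE`. Numerical safeguards found necessary on
this desk-scale
setup: the size logits are clamped to $|t| \le 3$ inside the loss (beyond
that the GIoU surface flattens into a vanishing-gradient plateau while
$e^t$ runs away) and to $|t| \le 8$ at decode as a pure overflow guard;
gradients are clipped at global norm 25.

`toy_train_config()` is the CPU-scale recipe used by the package's smoke
runs: 128-pixel inputs, width 0.25, 300 cycles, learning rate 0.008
dropped 10× at cycle 240, checkpoint selection on the full validation
split. The higher rate was chosen by convergence probes on the training
loss — the desk-scale normalized network tolerates and needs a larger
step than the full-scale default — and the late drop settles the
end-of-run oscillation before the best checkpoint is taken.

## Post-processing and evaluation

Candidates are filtered at confidence ≥ 0.5 (inclusive) and reduced by
greedy non-maximum suppression per class at IoU > 0.3 (strict), the
defaults of the reference recipe. NMS is per class because red and green
are separate count targets; cross-class suppression would corrupt counts.
Ties on confidence go to the larger box, then input order, fixing
determinism.

mAP uses greedy confidence-ordered matching at IoU ≥ 0.5, one match per
truth, and all-point interpolated average precision, averaged over the
classes present — the common VOC-style choice; the source recipe names
mAP without defining it. Yield accuracy is the detector's count divided by
the reference count as a percentage, per class and total, overall and per
viewing regime. The raw ratio is reported (overcounts exceed 100%)
together with the symmetric error $|100 - \mathrm{ratio}|$.

## Synthetic scenes

No public imagery accompanies the source recipe, so the package generates
its own study conditions: textured green foliage backgrounds with leaf
clutter, red fruit as shaded red-hued ellipses, green fruit as
darker-green shaded ellipses deliberately close to the foliage hue (the
confusion observed on real green fruit), in three regimes — `sparse`
(pairwise box IoU exactly 0), `dense` (clustered, IoU allowed up to 0.4),
and `occluded` (each fruit at least 40% covered by a foreground leaf
drawn after the label is recorded; labels are amodal, as human annotators
label partially hidden fruit). Default fruit semi-axes are 5–10% of the
image side and per-class counts 2–6 per scene; scenes are byte-reproducible
under their seed. Augmentations (quarter-turn rotation, horizontal and
vertical flips, Gaussian blur) transform labels consistently.

What passing tests on these scenes do **not** show: robustness to real
illumination, camera noise, perspective, specular highlights, or true
leaf geometry. The generator exists to exercise the algorithmic pipeline
under controlled difficulty, not to certify field performance.

## Problem sizes used by the checks

The smoke run trains the 0.25-width detector on 200 sparse 128-pixel
scenes for 300 cycles and evaluates on 50 held-out scenes (mAP and count
accuracy against an untrained baseline); geometry oracles use 1,000
random box pairs on a 512-point-per-side lattice; NMS is checked against
a brute-force reference on 200 random candidate sets; round-trips use 100
random label sets. These sizes keep the whole suite comfortably on one
CPU while leaving each check statistically meaningful.

## Known limitations

- The detector is a faithful small-scale analogue, not the 53-layer
  original; absolute accuracy on real imagery is out of scope.
- Degenerate zero-area boxes are rejected at construction; the GIoU
  decomposition is undefined there and the source recipe is silent.
- `Iteration ordinal number 700` in the reference recipe is ambiguous
  between epochs and steps; the package reads it as training cycles with
  evaluation every 10, matching the every-10-cycles model output it
  describes.
- The Euclidean position loss squares its height term; the printed form
  omits the square on that term only, which the package treats as a
  typesetting slip (by symmetry with the width term and the stated
  Euclidean-distance reading). The unsquared variant is not implemented.
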