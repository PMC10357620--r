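---
title: "Attentional feature fusion for polyp detection: models, parameters, and verification"
author: "polypatt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attentional feature fusion for polyp detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polypatt)
```

## The problem

Gastroscopic polyp detection is hard for two reasons that are structural, not
incidental: the luminance contrast between a polyp and the surrounding mucosa
is weak, and many polyps are small, flat and sometimes densely clustered among
visually similar distractors (mucosal folds, specular reflections from the wet
surface). A detector that treats every location and every channel of its
feature maps equally wastes capacity on background that looks almost like
foreground.

`polypatt` implements a serial position-and-channel attention block for
convolutional detection necks, a multi-scale fusion neck that applies this
block before every prediction layer, a minimal single-class anchor-based
reference detector so the neck can be exercised end to end on a desk, VOC-style
detection metrics, and a seeded synthetic scene generator that reproduces the
qualitative challenges above with exact ground truth. Everything is plain R on
top of a small reverse-mode automatic differentiation core, which keeps every
computation deterministic and directly checkable against scalar oracles.

## The attention block

A feature map is an array $X \in \mathbb{R}^{C\times H\times W}$. The block is
the composition of two gates, applied serially (position first, then channel —
the ordering that performed best in ablation; both orders are available).

### Position attention

1. **Local soft enhancement.** Every element is replaced by the
   softmax-weighted average of its $2\times 2$ neighbourhood: with window
   values $x_1,\dots,x_4$,
   $w_i = e^{x_i}/\sum_k e^{x_k}$ and the output is $\sum_i w_i x_i$. This is
   a parameter-free, data-dependent smoothing that leans towards locally
   strong activations. We use stride 1 with replicate padding of the last row
   and column, so the output keeps the input's shape; a downsampling reading
   would make the later per-row/per-column weights incompatible with the
   original indexing. Outputs are confined to the window's min–max range and
   constant maps are fixed points — both properties are asserted in the tests.
2. **Directional average pooling.** The enhanced map is averaged over columns
   to a height descriptor $X^h \in \mathbb{R}^{C\times H}$ and over rows to a
   width descriptor $X^w \in \mathbb{R}^{C\times W}$, preserving position
   along one axis while summarising the other.
3. **Joint transform and split.** The two descriptors are concatenated along
   the spatial axis, reduced to $C/r$ channels by a pointwise transform, split
   back into height and width parts, and each part is restored to $C$
   channels by its own pointwise transform. We split *before* the restoring
   transforms (the alternative reading — restore first, then split — would
   force the two directions to share one restoring map); this is a declared
   interpretation.
4. **Gating.** Both parts pass through hard-Swish,
   $h(x) = x\cdot\mathrm{clamp}(x{+}3, 0, 6)/6$, giving weights
   $w^h \in \mathbb{R}^{C\times H}$ and $w^w \in \mathbb{R}^{C\times W}$, and
   the *original* (pre-enhancement) map is gated separably:
   $U_c(i,j) = X_c(i,j)\, w^h_c(i)\, w^w_c(j)$. Gating the original rather
   than the enhanced map follows the method as specified; no alternative is
   exposed.

Hard-Swish is unbounded above, so position weights may amplify as well as
suppress; a sigmoid position gate is available as a configuration switch for
sensitivity checks.

### Channel attention

Two parallel global poolings reduce each channel to a scalar: the ordinary
average $s_1(c)$ and the **soft pool**
$s_2(c) = \sum_{ij}\mathrm{softmax}(U_c)_{ij}\, U_c(i,j)$, an
exponential-weight activation pooling in which every position contributes but
strong activations dominate. Soft pooling always lies between the channel mean
and maximum (strictly above the mean unless the channel is constant) and is
translation covariant; both properties are tested. As printed, the soft-pool
normaliser would carry an extra factor of the activation inside the sum, which
would make the pooled value identically one; we implement the standard softmax
normaliser $\sum_{ij} e^{U_c(i,j)}$, the only reading consistent with
"normalised weights" and the mean–max bound.

Each descriptor passes through a bottleneck $C \to C/r \to C$ (ReLU in the
middle, shared between the two branches by default; a non-shared variant is
configurable), the two outputs are fused by addition, and a sigmoid produces
the per-channel gate $g \in (0,1)^C$; the map is scaled channel-wise. The
strict $(0,1)$ bound is asserted in the tests.

## The fusion neck

Given backbone maps $F_2, F_3, F_4$ at strides 8/16/32, the neck first fuses
all three levels at once: $F_3$ and $F_4$ are upsampled to $F_2$'s grid by
nearest-neighbour interpolation (index map $\lfloor i/k \rfloor$),
concatenated with $F_2$ along channels ($c_2{+}c_3{+}c_4$ wide), and passed
through an alternating $1\times1$/$3\times3$ convolution block (five layers by
default, leaky-ReLU activations) down to a common width. Fusing the full
triple before any prediction, rather than only adjacent levels, is the point:
each output level then derives from all semantic depths. A bottom-up path
rebuilds the pyramid — $N_2$ from the fused base, then
$N_{k+1} = \mathrm{conv}(\mathrm{cat}(\mathrm{down}(N_k),
\mathrm{lat}(F_{k+1})))$ with a learned stride-2 $3\times3$ downsampling and
$1\times1$ lateral projections — and one attention block with its *own*
parameters is applied to each level before its prediction head.

Contracts asserted in the tests: exact stride-8/16/32 shapes (a $416^2$
geometry yields $52^2/26^2/13^2$), gradient connectivity from every $F_k$ to
every attended output, and a closed-form parameter count
(`neck_param_count()`) that guards against silent architecture drift.

## The reference detector

The detector is deliberately minimal — it exists to exercise the neck, not to
compete with production frameworks. A five-layer stride-2 backbone produces
the pyramid; one $1\times1$ head per attended level emits, per cell and per
anchor, box offsets $(t_x, t_y, t_w, t_h)$ and an objectness logit. Decoding
is the standard anchor parameterisation
($\sigma(t_x)$ offsets within the cell, $e^{t_w}$ anchor scaling), followed by
confidence thresholding and greedy NMS. The single class makes a separate
classification term degenerate, so objectness doubles as the score.

Training uses the two-phase schedule: during the freeze phase the backbone
parameters receive no updates (asserted bitwise in the tests), then all
parameters thaw. The loss is a YOLO-style composite: binary cross-entropy on
objectness plus squared error on the box terms at assigned anchors. Each
ground-truth box is assigned to the anchor of best shape overlap across all
levels; competing anchors with shape overlap above 0.5 are ignored rather than
punished. Both objectness terms are normalised by the number of positives:
with a handful of objects against thousands of background cells, averaging the
background term over the background count starves suppression and leaves
confident false positives (we observed exactly this), while positive-count
normalisation balances the two pressures. Default weights are 5/1/0.5 for
box/object/no-object, Adam at `lr0 = 0.001` (the stated base setting; the
scaled-down overfit runs below use 0.002), global gradient-norm clipping at 10.

Mosaic augmentation composes four annotated images into one canvas around a
split point sampled uniformly in the central 50% of each axis; each source is
resized into its quadrant by nearest neighbour and its boxes are mapped by the
same affine transform, clipped, and dropped below a 2 px side. With the split
fixed at the centre and sources matching their quadrants, the mapping reduces
to pure translation — the exactness case the tests pin down. Per-quadrant
scale jitter is deliberately absent so that the operation stays exactly
verifiable.

### Initialisation of the position gate

One numerical choice matters enough to single out: at a naive zero-bias
initialisation the position gate evaluates hard-Swish near zero, which is
itself near zero — the block then almost annihilates its input, and the
detector trains an order of magnitude slower. We therefore initialise the
restoring-transform biases at the hard-Swish unit fixed point
$x^\ast = (-3+\sqrt{33})/2 \approx 1.372$ (where $h(x^\ast) = 1$), so the
block starts near pass-through and learns to deviate. Zero initialisation
remains available and is what the exact zero-gate unit tests use.

## The synthetic scene generator

`generate_scene()` renders, in order: a smooth dark reddish base (bilinear
interpolation of a coarse random luminance grid, red-dominant colour model);
sinusoidal fold ridges of random orientation, frequency and phase; elliptical
polyps; and small saturated specular discs kept off the polyps. Polyps differ
from their surroundings chiefly in luminance — `contrast_delta` is added to
all three channels inside the ellipse — so the weak-contrast regime is
controlled by a single parameter and is verified against the rendered pixels.
Ellipses are anti-aliased by 4-fold supersampling, and the returned boxes are
the tight bounds of the supersampled mask, so ground truth is exact to a
quarter pixel.

Defaults are chosen once to emulate the described data: box sides log-uniform
on (6, 64) px at the 416 px reference size (small polyps dominate — the tests
check the size law against an analytic oracle for the box side of a random
rotated ellipse), axis ratios on (0.6, 1), `contrast_delta = 0.10` with 0.05
as the tested low-contrast regime, six folds and eight speculars per scene,
and an optional clustered placement mode. Every scene is a pure function of
its seed; datasets record per-image seeds in their manifest so any image can
be regenerated in isolation.

What the generator does *not* emulate: hue variation between polyp and mucosa,
perspective and lens distortion, motion blur, bubbles, and the intensity
statistics of any real endoscope. Passing tests on these scenes demonstrates
that the operators, the training loop and the metrics are correct and that the
pipeline can overfit and localise under weak contrast — they say nothing about
clinical performance on real gastroscopy.

## Evaluation

`evaluate_detections()` reports precision, recall and F1
($F_1 = 2PR/(P{+}R)$, with zero denominators mapped to 0) at a confidence
threshold (default 0.5), and AP at IoU 0.5 from the full score-ranked PR
sweep with greedy per-image matching — each detection matches the unmatched
ground truth of highest IoU at or above the threshold, ties broken by index.
AP uses all-point interpolation (the precision envelope integrated over
recall) by default, with classic 11-point interpolation as an option; with a
single class, mean AP equals AP. The implementation is tested against
explicit enumeration oracles and against hand-swept PR curves.

## Problem sizes and determinism

The test-suite and acceptance-script runs are sized for a single CPU: oracle
comparisons use tensors up to $8\times9\times9$; the end-to-end run trains on
16 scenes of $256^2$ px with backbone widths (8, 12, 16, 24, 32), a 32-channel
neck, reduction ratio 8, and 10 freeze + 90 thaw epochs — about five minutes —
and is expected to overfit: final loss under 10% of initial and AP@0.5 of at
least 0.90 on its own training scenes. All randomness flows from explicit
seeds; repeated runs are bitwise identical, which the tests assert for the
generator, mosaic and training history.

## Known limitations

* The reference detector is desk-scale by design: no batching, no batch
  normalisation, no augmentation beyond mosaic, a tiny backbone. Absolute
  accuracy numbers from it are not comparable to GPU-trained detectors.
* The attention operators are exact but not micro-optimised; maps much larger
  than $10^5$ elements per level will be slow in pure R.
* Image IO is PNG-only.
* Reported metrics are single-class; the multi-class generalisation is out of
  scope.
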