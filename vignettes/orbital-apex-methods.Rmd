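---
title: "Segmenting the orbital apex: model family, phantom design and evaluation calculus"
author: "apexseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting the orbital apex: model family, phantom design and evaluation calculus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(apexseg)
```

## The problem

Axial CT slices through the orbital apex show three paired structures whose
delineation matters for diagnosing optic-canal fractures and for planning
endoscopic optic-canal decompression: the optic canal (OC), a thin bony
ring; the internal carotid artery (ICA), a bright contrast-enhanced disc
adjacent to the sphenoid sinus lateral wall; and the sphenoid sinus (SS),
an air-filled dark cavity. `apexseg` provides, at desk scale and with no
clinical data:

* a seeded synthetic phantom generator for such slices, with per-pixel
  ground truth and four-category fracture bounding boxes,
* a U-Net model family whose skip connections can carry texture-enhancing
  selective-kernel convolution (SK) modules or semantic-perception
  transformer encoder blocks (TEB),
* a deterministic CPU training loop,
* the complete segmentation and detection evaluation calculus
  (IoU/Dice/mIoU/mDice; precision/recall/F1, PR curves, AP/mAP\@0.5, ROC
  AUC, paired comparisons), and
* an ablation harness comparing the four variants (base, +SK, +TEB,
  improved) under shared seeds.

## The model family

The base network is a five-level U-Net: each encoder level applies two 3x3
same-padded convolutions with ReLU and a 2x2 max-pool; channels start at
`baseChannels` (default 8) and double per level; the decoder mirrors this
with 2x2 transposed convolutions that halve channels, concatenation with
the skip path, and two 3x3 convolutions; a final 1x1 convolution yields
per-class scores. Counting the bottleneck path as the fifth module site,
the model carries five per-level skip modules, and the four named variants
are

| variant    | levels 1-3 | levels 4-5 |
|------------|------------|------------|
| `base`     | plain      | plain      |
| `sk`       | SK conv    | plain      |
| `teb`      | plain      | TEB        |
| `improved` | SK conv    | TEB        |

**SK module** (split/fuse/select). Split: one same-padded convolution per
kernel size, default 1x1, 3x3, 5x5 and 7x7, each mapping C channels to C
channels. Fuse: the branch outputs are summed, globally average-pooled to
one C-vector per sample, passed through a bottleneck (width
`max(C/reductionRatio, minBottleneck)`, defaults 8 and 16, with ReLU) and
through one score head per branch. Select: a softmax across branches per
channel yields nonnegative weights summing to one, which blend the branch
outputs. The module therefore preserves shape and adaptively chooses its
receptive field per channel — the property that should help when classes
differ by texture scale rather than mean intensity.

**TEB module.** Feature maps at the two coarsest levels are tokenized
(patch size 1 there, so a token per position; the token width is
`channels * patchSize^2`), learned position terms are added, and
`depth = 2` pre-norm encoder blocks are applied: multi-head self-attention
(4 heads) with residual, then a feed-forward sublayer (`mlpRatio = 4`,
GELU) with residual. Attention rows are probability vectors; tokens are
reassembled to the spatial layout, so the module is a drop-in replacement
for a plain skip.

Because the attention sublayer's key bias shifts all keys equally, it
cannot change the attention pattern; its gradient is identically zero.
This is expected and harmless.

**Initialization and determinism.** All parameters are drawn under a
derived seed (He-scaled normals for convolutions and feed-forward layers,
small normals for position terms); layers common to every variant are
drawn first under the master seed and each skip module under its own
level-derived seed, so the four variants built from one seed share
bit-identical common-layer initializations. This is what makes the
ablation a controlled comparison. TEB position terms are sized when the
model is built (`buildModel(spec, seed, imageSize)`); a forward pass on an
incompatible side fails with an explicit error, as does any input whose
side is not divisible by `2^(depth-1)`.

## The phantom generator

`generateSlice(config, seed)` is a pure function of its arguments. Per
side it draws, in order, a sphenoid-sinus ellipse (dark, mean 0.08), an
ICA disc (bright, 0.90) touching the sinus lateral border, and an
optic-canal ring (bone, 0.65) superior-lateral to the sinus, on a
soft-tissue background (0.35); geometry is jittered per seed and scales
with image size. With the per-side fracture probability (default 0.5 per
side; the clinical datasets report only totals, so prevalence is a free
parameter here) a fracture is rendered as a gap of at least ~2 px cut into
the ring plus a displaced bone fragment — the direct CT signs
(discontinuity, displacement, fragmentation). The box of each side is the
bounding box of that side's canal pixels plus a 2 px margin; its category
is `Fracture(R/L)` or `Non-fracture(R/L)` accordingly. Classes also carry
texture gratings (amplitude `textureContrast`, default 0.15) and additive
Gaussian noise (`noiseSd`, default 0.02).

Two preset families fix the benchmark conditions:

* `easyPhantomConfig()` — classes separated by mean intensity; low noise
  (0.01), visible texture (0.2). This is the "easy" learning benchmark.
* `textureConfusablePhantomConfig()` — all three structures share one mean
  (0.55) and differ only in the period of a diagonal grating: 3 px (OC),
  6 px (ICA), 12 px (SS), amplitude 0.35. Discriminating periods 3 and 6
  requires integrating over windows larger than 3x3, which is precisely
  the receptive-field axis the SK module controls; this family is chosen
  to make the SK contribution observable, not to imitate clinical
  difficulty.

What the phantom deliberately does not emulate: Hounsfield calibration,
partial-volume blur, scanner noise spectra, anatomical shape variation
beyond jitter, indirect fracture signs (sinus fluid/air), and 3-D
continuity. Passing benchmarks on phantoms therefore shows that the
architecture, training loop and metrics behave as specified — not that
clinical performance is reproduced. The original study's absolute
benchmark values come from private clinical data at GPU scale and are out
of reach (and out of scope) at desk scale.

## Training

`trainModel` runs seeded mini-batch Adam (default batch 8). The loss is
selectable: plain softmax cross-entropy (default), soft Dice, or their sum
(`"combined"`). The canal ring is a thin, heavily imbalanced target —
about 2% of pixels — and with plain cross-entropy the early epochs are
spent on the background class; the Dice term rewards foreground overlap
directly, which is why both shipped benchmarks use `"combined"` with
learning rate 3e-3. Validation (the held-out 8:2 split) is evaluated every
epoch as mIoU over the three foreground structures; `stopMiou` stops
training once a target is reached. With a fixed seed the whole loop —
shuffling, augmentation, initialization — is bit-reproducible.

## Evaluation calculus

Segmentation: per class, TP/FP/FN/TN are exact pixel counts;
IoU = TP/(TP+FP+FN), Dice = 2TP/(2TP+FP+FN), so Dice = 2 IoU/(1+IoU) per
mask pair. A class absent from both masks scores 1 by convention (the
prediction made no mistake); this choice is config-free but recorded in
every report. Means default to the three foreground classes (k = 3);
`includeBackground` gives the 4-class mean. Over a test set the default is
macro-averaging over images; global count pooling is available.

Detection: matching is greedy per category in descending confidence with
one-to-one assignment at IoU >= 0.5 (the threshold is named by the
evaluation convention; the matcher is the standard one). AP integrates the
precision envelope over recall (all-point interpolation; an 11-point mode
exists), mAP averages categories. TN is undefined for open-set detection,
so TN-based quantities are only computed for the per-side binary diagnosis
task (`diagnosisFromDetections`: the highest-confidence detection per side
decides). ROC AUC is the normalized Mann-Whitney statistic computed from
midranks (ties count one half), hence invariant under monotone transforms
of the scores. The paired before/after comparison is a two-sided paired t
test on n-1 degrees of freedom; identical vectors are flagged degenerate
rather than tested.

## Benchmarks and problem sizes

`easyBenchmark()` — 200 easy-family slices at 64 x 64 (8:2 split), the
improved variant, up to 30 epochs per seed, three seeds, target mIoU 0.90.
`textureBenchmark()` — 80 texture-confusable slices at 48 x 48, base vs
+SK under three shared seeds, a fixed 20-epoch budget each; the budget is
long enough for the slower-starting SK variant to express its advantage
(both variants spend several epochs in an all-background phase before the
foreground Dice signal takes hold). These sizes keep a full
run on one CPU core in the minutes range while leaving the learning
signals well clear of noise; both are deliberately small stochastic
checks of direction and attainment, not estimates of clinical accuracy.

```{r}
bench <- easyBenchmark(seeds = 1:3)
bench$bestMiou          # per-seed best validation mIoU
tex <- textureBenchmark()
tex$gain                # mean mIoU(+SK) - mIoU(base)
```

## Numerical choices and edge cases

* Coordinates are 0-based, row-major, origin top-left; boxes are stored as
  half-open pixel extents and exported in normalized center form with the
  category table fixed as 0 = Fracture(R), 1 = Fracture(L),
  2 = Non-fracture(R), 3 = Non-fracture(L).
* Predicted masks break per-pixel score ties toward the lower class index.
* Polygon rasterization uses even-odd pixel-center inclusion; centers
  exactly on an edge are included.
* Convolutions use zero same-padding at every kernel size so skip modules
  preserve shape; softmax rows are computed with max-shifting; layer norm
  uses eps = 1e-5.
* Empty-vs-empty overlap returns 1; zero-denominator precision and recall
  return 0; PR curves require at least one ground-truth box.
* Mask PNGs store the class code as the 8-bit gray value (round trips are
  bit-identical); image PNGs quantize by round-half-up to 1/255 steps.

## Known limitations

The engine is a minimal CPU implementation (im2col convolutions over
BLAS): adequate for the desk-scale benchmarks, not for clinical image
sizes. The detector itself is out of scope — the package evaluates
detections from any source and ships only phantom ground truth plus a toy
jitter detector for pipeline tests. Reported phantom metrics say nothing
quantitative about clinical CT; only the directional ablation claims are
designed to transfer.
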