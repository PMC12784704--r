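---
title: "Lightweight behaviour-detector blocks: models, cost accounting, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lightweight behaviour-detector blocks: models, cost accounting, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdbyolo)
```

## What this package models

`sdbyolo` implements, as a self-contained operator library in R, the building
blocks of SDB-YOLO — a lightweight single-stage detector for recognising four
livestock postures (stand, lie, eat, drink) in fixed-camera pen footage.  The
detector is a nano-scale anchor-free architecture (backbone / neck / head)
whose stock blocks are modified in four places:

* **FPSC** (feature pyramid shared convolution) replaces the fast
  spatial-pyramid pooling block at the end of the backbone.  One 3×3 kernel is
  *shared* across dilation rates d ∈ {1, 3, 5}: `F_d = W *_d X'` after a 1×1
  channel reduction.  Branch features are fused with softmax gates
  `beta_d = exp(g_d) / sum_k exp(g_k)` and concatenated with the reduced input
  (a 4-way concatenation, the same fusion width as the pooling block it
  replaces), then projected 1×1.  Because the kernel is shared, the branch
  weight count equals that of a single 3×3 convolution no matter how many
  rates are used.
* **C3_GDConv** replaces the stock cross-stage (CSP) blocks.  The split /
  transform / merge shell is retained; the inner bottlenecks become ghost
  modules (a 1×1 primary convolution produces half the channels, a cheap 5×5
  depthwise convolution derives the other half) and, in the deeper variant,
  the stack GhostModule → GhostModule → DynamicConv.  The dynamic convolution
  aggregates K expert kernels with input-conditioned attention
  `w = sum_i alpha_i(x) w_i`, `sum_i alpha_i = 1`; optional element-wise
  masks `y = sum_i alpha_i (M_i ⊙ w_i) * x` reduce to the plain aggregation
  when `M_i ≡ 1`.
* **CBAM** — sequential channel-then-spatial multiplicative attention — is
  inserted after the P4 neck block.
* **EfficientHead** replaces the stock decoupled head: a per-scale 3×3
  *group* convolution stem, then two 1×1 branches for classification and
  box regression.  Each box side is predicted as a discrete distribution
  `P = (p_0 … p_K)`, `sum p_i = 1`, decoded by its expectation
  `d_hat = sum i p_i` and mapped to corner coordinates by `dist2bbox`.

Everything runs on plain R arrays: convolution is shifted-slice im2col over
BLAS, and a small reverse-mode autograd tape makes every block trainable, so
the whole architecture can be exercised — assembled, profiled, trained at
desk scale, evaluated — without any deep-learning runtime.

## Cost accounting

The profiler is analytic.  For a convolution, `Params = K²·C_in·C_out / g`
and `FLOPs = Params · H · W` multiply-accumulates at the output resolution;
headline GFLOPs are `2 × MACs / 1e9` (multiply and add counted separately),
the reporting convention of this detector family.  Two conventions matter
and are applied deliberately:

* **Deployed (batch-norm-folded) parameters are the headline.**  The
  published totals for this architecture family correspond to the deployed
  network: each conv+BN pair counts its weights plus one fused bias.  We
  verified this against the baseline anchor: the stock nano model at 4
  classes has 2,590,620 train-time parameters and exactly **2,582,932**
  after folding — the published figure, digit for digit (and the same
  accounting at 80 classes yields 2,624,080, the family's known figure).
  Both totals are reported; group-norm and true biases count identically in
  both.
* **Each parameter tensor is counted at one effective application.**  The
  FPSC kernel is swept at three dilations but is one tensor; the dynamic
  convolution applies one attention-aggregated kernel (its K expert tensors
  all count toward parameters, plus the gate MLP's cost).  This is the only
  reading consistent with the published GFLOP figures, which do not grow
  when the shared-kernel pyramid replaces the (FLOP-free) pooling pyramid.
  Pooling, activations, upsampling and attention matrix products are
  excluded, as in the published accounting.

```{r profile}
model <- assemble(preset_config("sdb-yolo"), seed = 1)
profile_model(model, 640)
```

## Calibration of the under-specified widths

The architecture description fixes the block topology but not every internal
width.  Those internals were resolved against the published per-variant
parameter totals (the ablation grid), which pin them essentially uniquely:

* **FPSC**: hidden width = half the input (the convention of the block it
  replaces); the shared 3×3 kernel carries no bias and no norm; the gates are
  **parameter-free** — the logit of a branch is its global mean response, so
  fusion adapts to content.  The published delta for this substitution is
  +147,456 = exactly 9·128², leaving zero room for gate parameters; static
  learnable logits would have added three.  A fixed-logit mode
  (`gate_logits`) exists for testing the softmax fusion in isolation.
* **C3_GDConv**: ghost modules use a 1×1 primary and 5×5 depthwise cheap
  convolution; the dynamic convolution uses 1×1 experts with **K = 2** and a
  bias-free gate `GAP → fc(c → c/2) → ReLU → fc(→ K) → softmax`.  Over a
  search of ~10⁴ structural combinations (ghost kernels, norms, shells,
  K = 1…8, gate shapes, biases) this is the *only* configuration that
  reproduces the published substitution total exactly.
* **EfficientHead**: stem groups of **32 channels** with **GroupNorm** (16
  groups) — group-normalised heads are a standard choice for training
  stability at small batch sizes, which is also the property claimed for this
  head; 16 distribution bins per side (so 64 regression channels); biased
  1×1 output convolutions.  Again the unique exact solution found, and it
  reproduces the published GFLOP drop (6.3 → 5.1) as well.
* **CBAM**: dual-pool shared MLP without biases and a bias-free 7×7 spatial
  convolution over edge-replicated padding.  The published full-model budget
  implies a channel-gate hidden width of **269** at the 128-channel P4 site;
  no power-of-two reduction ratio reproduces that figure (we enumerated
  reductions 1–32, bias variants, pooling variants, kernel sizes 3/5/7 and
  up to three insertion sites), so the preset records the calibrated width
  explicitly and `cbam_config()` exposes it as a first-class parameter.

One published figure cannot be reconciled: the ablation grid's combination
rows each sit exactly +1,392 parameters above the sum of their solo-row
deltas, although the substitutions touch disjoint layers and therefore add
per layer in any single consistent implementation.  (The grid also contains
an off-by-one in one pairwise row.)  We match the baseline and all three
solo rows, and consequently the full model, exactly; the three-module
combination computes to 2,105,428 against a printed 2,106,820, and the
package reports its computed value rather than forcing the printed one.

## The detection head and decoding

Raw head outputs are per-scale maps of 4·16 regression logits and 4 class
logits per cell.  Decoding applies the logistic to class logits, a softmax
over the 16 bins of each side followed by the expectation, and the
distance-to-corner mapping at the cell centre, scaled by the stride;
class-wise greedy non-maximum suppression (confidence order, ties broken by
input order; defaults conf 0.25 / IoU 0.45) yields the final detections.

## Metrics

Matching is greedy in confidence order: each prediction takes the unmatched
ground truth of highest IoU above the threshold; unmatched predictions are
false positives, unmatched truths false negatives.  Average precision uses
all-point interpolation (area under the precision envelope), switchable to
the 101-point variant; mAP50-95 averages thresholds 0.50:0.05:0.95.  The
matching protocol and interpolation are not fixed by the source description;
these defaults are the common modern choice, and the test-suite cross-checks
the whole engine against independent brute-force implementations.

## Synthetic scenes and what they do (and do not) show

The generator emulates fixed-camera pen footage at desk scale: textured
ground, 1–6 animals per scene with posture-coded geometry — upright body
with legs (stand), low wide body (lie), head down at a trough (eat), head
down at a water basin (drink) — optional partial occlusion by fence posts,
illumination ramps and motion blur.  Class frequencies default to the
published label distribution (2369 : 812 : 1600 : 281, i.e. 46.8 / 16.0 /
31.6 / 5.6 %).  Randomness is a master seed plus per-scene substreams, so
datasets are reproducible piecewise.

Synthetic scenes validate the machinery — label geometry, losses, decoding,
metrics — not field performance: real footage has pose and coat variation,
perspective, clutter and inter-animal contact that the generator does not
model, so passing tests here says nothing about accuracy on real animals
(the published accuracy figures require the original, non-public dataset and
GPU-scale training, and are out of scope).

## The toy training loop

`train_toy()` runs plain SGD with momentum (defaults lr 0.01, momentum 0.9,
batch 8 — the batch size of the original training setup).  Label assignment
is deliberately minimal: each truth box goes to the cell containing its
centre at the scale whose stride best matches the box size; the loss is
binary cross-entropy on class logits over all cells, an IoU loss on decoded
boxes, and the distribution-focal cross-entropy with soft two-bin targets
(weights 0.5 / 7.5 / 1.5).  This is a gradient-flow harness, not a
reproduction of full-scale training: no mosaic batching, no dynamic
assignment, no schedule.

Problem sizes are chosen so the whole pipeline is exercised quickly on one
CPU: the `sdb-yolo-pico` preset (same block vocabulary, reduced widths) at
64×64 input overfits 8 synthetic scenes by a factor ≈10 in 200 iterations
(~1 minute), and a 600-iteration run already yields non-zero training-set
mAP through the full synth → train → decode → evaluate path.

## Numerical choices and edge cases

* Batch-norm uses batch statistics in both modes (there is no running-stats
  inference path; all tests and the toy loop are batch-mode).
* Weight init is Kaiming-uniform from R's RNG under a local seed, so
  `assemble(cfg, seed)` is bit-reproducible and never disturbs the caller's
  RNG stream.
* Softmax is computed with max-subtraction; the DFL expectation validates
  normalisation to 1e-6; degenerate zero-area boxes are flagged rather than
  silently kept.
* Motion blur uses a wrap-around border, which preserves mean intensity
  exactly for any streak angle (an edge-reflection border biases the mean by
  ~1e-4 at oblique angles).
* Mosaic compositing drops a box when less than 1 % of its area remains
  visible after clipping (threshold exposed as `min_visible_frac`), avoiding
  degenerate slivers.
* The scene generator retries placement a bounded number of times, then
  re-draws the scene from a fresh substream.

## Known limitations

* Pure-R execution: a full 640×640 forward pass of the assembled model takes
  a few seconds; the profiler, which is analytic, is instant.  Training
  beyond the toy scale is out of scope.
* Only the kernel-number attention dimension of the omni-dimensional dynamic
  convolution formulation is modelled; the spatial/input/output attention
  flags are reserved and rejected if enabled.
* Images are PNG on disk (no JPEG reader in the dependency set).
* The baseline C2PSA attention stage is implemented for assembly and
  profiling parity; its attention matrix products are excluded from the FLOP
  ledger, consistent with the published accounting.
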