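---
title: "Model and methods behind ghostwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind ghostwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Early Parkinson's disease (PD) alters the substantia nigra (SN), a small
midbrain nucleus, in ways that are subtle on T2-weighted MRI: mild intensity
changes from iron accumulation and altered local texture. `ghostwave`
implements a lightweight U-shaped convolutional network that classifies a
single preprocessed 192x192 T2 slice as PD vs. healthy control, using an
auxiliary SN segmentation branch purely to localize the disease-relevant
anatomy: the predicted SN probability map multiplicatively gates the
classification features, so the classifier attends to the nucleus rather
than the whole slice.

Everything — convolutions, batch normalization, attention, the wavelet
transform, backpropagation and Adam — is implemented natively in R on
BLAS-backed matrix algebra. Feature maps are arrays laid out
`(height, width, channels, batch)`.

## Architecture

The network is a four-level encoder/decoder with a bottleneck:

* **Encoder stage** *i*: one hybrid ghost block (channel-preserving)
  followed by one wavelet downsampling block that halves resolution and
  expands channels to the ladder value. The ladder is 16, 24, 40, 80 with a
  160-channel bottleneck; a 192x192x1 input therefore passes shapes
  (16, 96, 96), (24, 48, 48), (40, 24, 24), (80, 12, 12), (160, 12, 12).
* **Decoder level** *d*: bilinear 2x upsampling with a 1x1 projection,
  concatenation with the same-level encoder skip (and, for the two
  highest-resolution levels, a mid-skip from the encoder two levels deeper,
  4x-upsampled and 1x1-projected), a 1x1 fusion, a hybrid ghost block, and
  coordinate attention.
* **Heads**: a 1x1 convolution produces the SN logit map (sigmoid gives
  `sn_prob`); the final decoder feature map is multiplied by `sn_prob`,
  globally average-pooled and passed through two fully connected layers
  (width 64, dropout 0.2) to the two class logits.

### Hybrid ghost block

Each block is ghost expansion -> learned group 3x3 convolution -> ghost
projection with a residual shortcut. A ghost module produces `out/s`
intrinsic maps with a standard (here 1x1) convolution and the remaining
maps with cheap 3x3 depthwise convolutions of the intrinsic maps; batch
norm follows every convolution, ReLU only on expansion stages (the usual
GhostNet convention). Encoder expansion modules are self-gated by
decomposed fully connected (DFC) attention: a 1x1 mix plus 1x5 and 5x1
depthwise aggregations on a 2x-pooled copy, sigmoid-squashed and
nearest-upsampled, capturing long-range row/column context at low cost.

The mid-block operator is a *learned* group convolution: each input channel
carries saliency logits over the `G = 2` groups; routing is the balanced
capacity-constrained argmax of the logits, and each routed channel is
scaled by its softmax probability so gradients reach the logits through the
scaling (a straight-through scheme — the discrete routing itself receives
no gradient). The scaling is applied identically during training and
inference; an earlier variant that dropped the scale at inference produced
a large train/test activation mismatch, visible as evaluation-mode
collapse on short runs.

The expansion width equals the output width (`exp_factor = 1`,
configurable). Wider expansions make the mid-block grouped convolution more
expensive than the plain double-conv block the hybrid block replaces, which
would invert the intended cost ordering of the ablation family; the lean
setting keeps every hybrid stage strictly cheaper than its plain
counterpart.

### Wavelet downsampling

Downsampling is a level-1 discrete wavelet transform with the Daubechies-2
(4-tap) orthonormal filter, applied per channel with periodic boundary
extension, implemented as explicit orthonormal filter matrices. Periodic
("wrap") extension is chosen because it keeps the transform exactly
orthogonal on even sizes: perfect reconstruction and energy conservation
hold to machine precision and are asserted at 1e-6 in the tests. The LL
band carries the signal forward; the LH/HL/HH detail bands are concatenated
and fused by a 1x1 convolution, then `[LL, fused]` is concatenated and
1x1-projected to the stage's target channel count (an additive combination
is available via `combine_mode = "add"`; concatenation is the default
because it preserves both streams losslessly before learned mixing). The
transform itself has no learnable weights — all learning in the block lives
in the 1x1 convolutions. Channel expansion happens in this final
projection rather than in the following block.

### Coordinate attention

Decoder features are reweighted by per-axis gates: means over width give a
per-row descriptor, means over height a per-column descriptor; both pass a
shared channel-reduction bottleneck (default ratio 8, ReLU) and per-axis
maps, and sigmoids yield `alpha_h` and `alpha_w` strictly inside (0, 1).
The bottleneck is applied per position: a position-mixing fully connected
layer would break the row/column permutation equivariance that the tests
assert, so `use_fc` only selects the dense-matrix implementation of the
same per-position linear map.

### Gating and ablations

The predicted SN probability gates the final decoder feature map (the
highest-resolution, best-localized representation); gating the bottleneck
is available via `gate_location`. Four switches reduce the model to its
ablation family: without hybrid ghost blocks, plain double 3x3
conv-BN-ReLU blocks; without wavelet downsampling, strided 3x3
convolutions (a learned-pooling baseline — against a parameter-free
max-pool the wavelet step could only add parameters, contradicting the
intended cost direction); without attention, DFC and coordinate attention
become identities; without mid-skips, the classic same-level U-Net
topology. Enabling hybrid ghost blocks and wavelet downsampling each
strictly reduces parameters and FLOPs relative to the all-off baseline;
attention necessarily adds a small number of weights back.

### Cost accounting

`count_costs()` counts trainable parameters exactly from the weight arrays
and multiply-accumulate operations (MACs) of one forward pass, covering
convolutions, fully connected layers, attention aggregations, the wavelet
filtering (4 MACs per coefficient per axis) and resampling interpolation.
The headline `flops_g` follows the efficient-CNN convention 1 MAC = 1 FLOP;
`flops_2x_g` reports the multiply-plus-add convention alongside. The
default model has ~0.28 M parameters and ~0.39 G MACs at 192x192x1, inside
the 2.03 M / 4.36 G budget of the architecture family it implements; block
internals are deliberately lean because the ablation cost ordering above
constrains the expansion width.

## Synthetic phantoms

Real cohorts of preprocessed T2 slices cannot ship with a package, so
`generate_phantom()` renders deterministic 2-D phantoms: an elliptical
head, a ventricle, a darker midbrain and two bright bilateral SN ellipses,
plus band-limited high-frequency texture (difference of Gaussian blurs of
white noise) and additive Gaussian noise, standardized to zero mean / unit
variance within the thresholded brain region. PD status attenuates the SN
intensity contrast by `contrast_delta` (exactly, on the noiseless
template) and boosts SN texture power, so both the intensity pathway and
the wavelet detail bands carry class signal. The default cohort emulates
the study composition: 450 PD, 103 + 347 controls in two control groups.

What the phantoms do *not* emulate: anatomical variability, scanner and
site effects, registration error, partial-volume effects, 3-D context and
realistic noise correlation. Passing tests on phantoms demonstrates that
the architecture, losses, optimization and metrics are implemented
correctly and can recover a known signal — not that the printed diagnostic
performance transfers to PPMI/IXI data, which would require the external
downloads and GPU-scale training.

Upstream preprocessing (skull stripping, bias-field correction, MNI
registration, slice selection) is out of scope; `load_slice()` consumes
its NIfTI output, selects a slice, resizes bilinearly and standardizes.
DICOM is not read directly (no R reader is available); convert to NIfTI
upstream.

## Training protocol

`train_config()` defaults follow the study protocol: Adam (betas 0.9/0.999,
the usual default since none is stated), initial learning rate 1e-3, L2
weight decay 1e-4 added to the gradients, batch size 16, cosine annealing
over 150 epochs to `lr_min = 1e-6` (a conventional floor), early stopping
with patience 20 on the *combined* validation loss (the protocol names only
a validation loss; the combined objective is the natural reading), fixed
seed 42. The loss is `lambda_seg * Dice + lambda_cls * cross-entropy` with
unit weights: the protocol names Dice for training while the primary task
is classification, so a classification term must exist; unit weighting is
the minimal interpretation and both weights are exposed.

Two evaluation protocols coexist, as in the study's description: a
per-group 64/16/20 split and stratified 5-fold cross-validation. The
published split table is internally inconsistent under any single rounding
rule; the rule `n_train = round(0.64 n)`, `n_test = floor(0.20 n)`,
remainder to validation reproduces every published cell (450 -> 288/72/90,
103 -> 66/17/20, 347 -> 222/56/69, totals 576/145/179) and is what
`make_split()` implements.

Two details matter for short CPU-scale runs. First, the segmentation head
bias is initialized to -2 so the network starts predicting mostly
background; with a sparse foreground (the SN covers ~1-2% of pixels) this
speeds Dice convergence substantially. Second, after training (and after
restoring the best-validation weights) the batch-norm running statistics
are re-estimated over the training set with the final weights
(`refresh_bn_stats()`, the usual cumulative re-estimation); after only a
few hundred optimizer steps the exponential running estimates otherwise lag
the weights badly enough to destroy evaluation-mode predictions.

## Metrics

Accuracy, precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and F1 (their
harmonic mean) at threshold 0.5, with zero-denominator ratios reported as 0
plus an `undefined` flag rather than NaN. Segmentation quality is per-class
IoU over SN and background and their mean (mIoU), thresholding `sn_prob` at
0.5. Metrics are computed per slice; the study's aggregation level is not
stated, and slice-level is the natural unit here.

## Numerical and testing choices

* Problem sizes: unit tests exercise blocks at 5-32 pixel tiles and the
  full 192 ladder where shape contracts demand it; the end-to-end
  recovery test trains a reduced model (64x64 input, channels 8/12/16/24,
  bottleneck 32, batch 4, learning rate 1e-2, 10 epochs, seed 42) on 80
  easy phantoms (high contrast 0.7, noise 0.02, SN semi-axes scaled up to
  keep ~90 mask pixels at 64x64) and requires held-out F1 >= 0.9 and SN
  IoU >= 0.6; it reaches F1 = 1.0 and SN IoU ~ 0.73 in about two minutes
  on one CPU.
* Degenerate inputs: odd spatial sizes are rejected by the wavelet
  transform rather than silently padded; empty groups and oversized group
  counts are rejected; constant images standardize to all zeros through a
  variance floor; zero-denominator metrics are flagged, not NaN.
* Ties in the balanced group assignment resolve by channel confidence
  order (decreasing max logit), then by group preference order —
  deterministic for fixed logits.
* All randomness (weight init, shuffling, dropout, phantom noise,
  augmentation) flows from explicit seeds; two builds or two training runs
  with equal seeds are bitwise identical.

## Known limitations

* Pure-R execution is orders of magnitude slower than an accelerated
  framework; the package targets correctness, auditability and desk-scale
  verification, not production training.
* Only the Db2 wavelet and level-1 decomposition are implemented.
* Phantoms are 2-D and geometric; see the synthetic-data section for what
  that does and does not validate.
* The exact internals of the published 2.03 M-parameter configuration are
  not decomposable from its description; this implementation satisfies the
  budget as an upper bound with a leaner model, and exposes every relevant
  knob in `model_config()`.
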