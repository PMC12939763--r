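# ghostwave

Lightweight ghost-wavelet attention network for MRI-based Parkinson's
disease screening, implemented natively in R.

Early Parkinson's disease (PD) leaves subtle traces in the substantia
nigra (SN) on T2-weighted MRI — mild intensity shifts and altered local
texture in a nucleus that covers a tiny fraction of a slice. `ghostwave`
is for methods researchers and imaging scientists who want an auditable,
dependency-light implementation of a modern lightweight diagnostic
architecture: every layer, including backpropagation, is plain R on
BLAS-backed matrix algebra, so each computational step can be inspected
and tested against independent oracles.

## The model

A four-level U-shaped network for slice-level binary classification
(PD vs. healthy control) with an auxiliary SN segmentation branch:

* **Hybrid ghost blocks** — ghost modules (a fraction of feature maps from
  a standard convolution, the rest from cheap depthwise ops) around a
  *learned group convolution* whose channel-to-group routing is trained
  via per-channel saliency logits; encoder blocks add decomposed
  fully connected (DFC) attention for long-range row/column context.
* **Wavelet downsampling** — pooling is replaced by an orthonormal Db2
  level-1 DWT per channel: the LL band carries the signal to the next
  stage and the LH/HL/HH detail bands are fused back through 1×1
  convolutions, so high-frequency texture survives each resolution drop.
* **Coordinate attention** in the decoder: per-row and per-column pooled
  descriptors produce axis-wise sigmoid gates α_h, α_w, and the feature
  map is reweighted as X · α_h · α_w.
* **Mid-skip connections**: besides same-level skips, decoder level d
  receives the encoder skip from level d + 2, upsampled and projected.
* **Mask-gated classification**: the predicted SN probability map
  multiplies the final decoder features element-wise; the gated map is
  pooled and passed through two fully connected layers, so the classifier
  sees the disease-relevant anatomy.

Training follows the protocol of the architecture family: Adam
(lr 10⁻³, weight decay 10⁻⁴), Dice + cross-entropy loss, cosine annealing
over 150 epochs, early stopping (patience 20), per-group 64/16/20 splits
or stratified 5-fold cross-validation, seed 42. Standard metrics
(accuracy, precision, recall, F1, per-class IoU / mIoU) and exact
parameter/MAC cost accounting are included, as is a deterministic
synthetic phantom generator that emulates the cohort structure (450 PD,
103 + 347 controls) with pixel-accurate SN masks.

## Worked example

```r
library(ghostwave)

cfg <- model_config()      # 192x192x1 input, channels 16/24/40/80 -> 160
net <- build_model(cfg)
count_costs(net)
#> parameters: 278,575 (0.279 M)
#> MACs:       386,113,920 (0.386 G; 2x = 0.772 G)
#>   component params      macs
#>  enc_blocks  20568  87121152
#>       downs  18240  25574400
#>  bottleneck 150240  21404160
#>  ...
```

The cost report counts trainable parameters exactly and one forward
pass's multiply-accumulate operations (1 MAC = 1 FLOP convention; the
2× figure is the multiply-plus-add convention). The skip topology is
inspectable:

```r
mid_skip_wiring(cfg)
#>   decoder_level encoder_level type scale channels
#>               1             3  mid     4       16
#>               1             1 same    1        16
#>               2             4  mid     4       16
#>               2             2 same    1        16
#>               3             3 same    1        24
#>               4             4 same    1        40
```

A complete scaled-down experiment — generate an easy phantom cohort,
train a reduced model for 10 epochs on CPU, evaluate held-out slices:

```r
pp <- phantom_params(size = 64, sn_radius = c(14, 9),
                     contrast_delta = 0.7, noise_sd = 0.02,
                     texture_scale = 0.05)
cohort <- generate_cohort(cohort_spec(n_pd = 40, n_control_a = 20,
                                      n_control_b = 20, params = pp,
                                      seed = 42))
labels <- sapply(cohort$samples, `[[`, "label")
set.seed(42)
held <- c(sample(which(labels == "PD"), 8), sample(which(labels == "HC"), 8))

cfg <- model_config(input_size = c(64, 64),
                    encoder_channels = c(8, 12, 16, 24),
                    bottleneck_channels = 32, ca = list(reduction = 4))
tc <- train_config(batch_size = 4, lr_init = 1e-2, epochs = 10,
                   early_stop_patience = 10, seed = 42)
fit <- train_model(build_model(cfg), cohort$samples[-held], tc = tc)
evaluate_run(fit$net, cohort$samples[held])$metrics[c("f1", "iou_sn")]
#> $f1
#> [1] 1
#> $iou_sn
#> [1] 0.7331306
```

Held-out classification is perfect and the auxiliary SN masks overlap the
ground truth at IoU ≈ 0.73 after ~2 minutes of CPU training — the phantom
cohort plants a known class signal in exactly the structures (SN
intensity and high-frequency texture) the architecture is built to read.

The split arithmetic of the emulated cohort:

```r
make_split(c(pd = 450, control_a = 103, control_b = 347))$sizes
#>           train val test
#> pd          288  72   90
#> control_a    66  17   20
#> control_b   222  56   69
```

A shell interface wraps the same functions
(`inst/cli/ghostwave.R generate|train|evaluate|report` with a YAML config);
every run writes a JSON manifest sufficient to reproduce it.

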