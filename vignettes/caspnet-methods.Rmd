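---
title: "CASPNet: model, training recipe and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CASPNet: model, training recipe and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Pap-smear screening produces crops of single cervical cells that
cytopathologists sort into normal (Superficial-Intermediate, Parabasal) and
abnormal (Koilocytotic, Metaplastic, Dyskeratotic) classes. The diagnostic
cues are morphological: nucleus-to-cytoplasm (N:C) area ratio,
hyperchromasia, nuclear-membrane irregularity. CASPNet is a hybrid
classifier built for this task that combines three ingredients:

1. **A ViT-Base token encoder.** A strided convolution cuts the
   $224 \times 224 \times 3$ input into $16 \times 16$ patches and projects
   each to a 768-dimensional token ($196$ tokens), followed by a non-affine
   LayerNorm over the embedding axis. A learnable class token is prepended
   and a learnable positional table ($197 \times 768$) added; twelve
   pre-norm transformer blocks follow, each
   $x \leftarrow x + \mathrm{MHSA}(\mathrm{LN}(x))$,
   $x \leftarrow x + \mathrm{MLP}(\mathrm{LN}(x))$ with 12 heads
   (head dimension 64, attention scale $1/\sqrt{64} = 0.125$), a GELU MLP
   expanding $768 \to 3072 \to 768$, and dropout 0.1 on activations and
   attention weights. A final affine LayerNorm closes the encoder.

2. **A parameter-free bridge.** The class token is discarded and the 196
   patch tokens are laid row-major back onto their $14 \times 14$ grid,
   giving a $768$-channel feature map. The operation is a pure reshape —
   exactly invertible, zero trainable parameters.

3. **YOLO-style convolutional fusion.** A CSP (cross-stage-partial) block
   splits the map into two $1{\times}1$-conv branches of width 384; branch 2
   is flattened to 196 tokens and passed through one transformer block
   (6 heads, keeping head dimension 64) before both branches are
   concatenated and merged back to 768 channels. An SPPF block
   (spatial-pyramid-pooling-fast) then reduces to 384 channels and applies
   three cascaded $5 \times 5$ stride-1 max pools — equivalent to
   $9\times9$ and $13\times13$ receptive fields — concatenating all four
   maps (1536 channels) and merging to 768. Global average pooling and a
   $\mathrm{LN}(768) \to 512 \to 256 \to K$ GELU/dropout head produce the
   logits.

Conv units are Conv → SiLU; a `conv_batchnorm` flag inserts BatchNorm
between them (off by default — the published parameter budget of 90.76 M
is met without it, and also with it after rounding).

Under the default configuration the model has exactly 90,757,893 trainable
parameters: 85,798,656 in the encoder (patch conv 590,592; class token 768;
positional table 151,296; $12 \times 7{,}087{,}872$ blocks; final norm
1,536), 2,955,648 in the CSP block, 1,475,712 in SPPF and 527,877 in the
head. The patch-embedding LayerNorm is deliberately non-affine: that is the
only reading under which the encoder's component arithmetic and the
published 90.76 M total agree simultaneously.

## Training recipe

Training minimizes the mean categorical cross-entropy
$-\log p_{i,y_i}$ (max-subtraction stabilized) with **AdamW**:
$m \leftarrow \beta_1 m + (1-\beta_1) g$,
$v \leftarrow \beta_2 v + (1-\beta_2) g^2$, bias-corrected
$\hat m, \hat v$, and the decoupled update
$\theta \leftarrow \theta - \eta\, \hat m / (\sqrt{\hat v} + \epsilon)
 - \eta \lambda \theta.$
The decay term ($\lambda = 0.05$) applies only to conv/linear kernels;
biases, normalization parameters and the class/positional embeddings are
excluded, following common transformer practice (configurable). The
additive penalty $\lambda \lVert W \rVert^2$ is computed only as a
reporting quantity (`weight_decay_penalty()`) so the decay is never applied
twice. $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$ are the
standard defaults; the source recipe names the symbols without fixing
values.

The **one-cycle schedule** is stepped per optimizer step (not per epoch;
a deliberate choice — "the first 10% of training" is read over total
steps): cosine interpolation from $10^{-4}$ up to $10^{-3}$ across the
first 10% of steps, then cosine annealing down to $10^{-5}$, continuous at
the boundary. Batch size 128, 450 epochs and seed 1337 are the published
defaults in `training_config()`; the best-validation-accuracy checkpoint is
retained, ties resolved toward the later epoch (the published account names
a best epoch but no selection rule).

## Data handling

`load_dataset()` reads the class-per-directory layout with alphabetical
class indices, skipping undecodable files with a logged warning.
`stratified_split()` makes the 80:10:10 holdout deterministic: per class,
a generator seeded from (seed, class index) shuffles the items and
round-half-up quotas assign the first $\mathrm{round}(0.1\,n_c)$ to test,
the next $\mathrm{round}(0.1\,n_c)$ to validation, the remainder to train.
The assignment rule is this package's own (the source fixes only ratios
and seed); under it the benchmark's per-class counts give test quotas
(81, 79, 83, 79, 81), total 403. The benchmark's published table is
internally inconsistent here: its rows sum to 4031 while its printed total
is 4049 (the public dataset actually contains 831 rather than 813
superficial-intermediate cells); the fixture profile mirrors the printed
per-class rows.

Augmentation (`augment()`) applies, on the fly and to the training split
only: random-resized crop to 224 (area scale 0.6–1.0, aspect 3/4–4/3 —
unstated in the source; chosen so the cell stays mostly in frame),
horizontal/vertical flips at $p = 0.5$, rotation uniform in $\pm 20^\circ$
(fill: median border colour) and colour jitter with
brightness/contrast/saturation/hue factors 0.1. Evaluation uses a
deterministic resize plus per-channel standardization with the widely used
natural-image statistics (overridable; dataset statistics can be supplied
instead).

## Synthetic fixtures: what they emulate and what they do not

`generate_fixtures()` renders class-conditional single-cell images:
background noise, a cytoplasm ellipse, a nucleus ellipse whose area is a
class-specific fraction of the cytoplasm (the N:C ratio), chromatin-like
speckles, and optionally a koilocyte-like perinuclear halo. Class
separability is therefore carried by exactly the cue the explainability
analysis targets — nucleus geometry — and every image ships with its
ground-truth nucleus mask. Generation is byte-reproducible: each image
derives its own RNG stream from (seed, class, index).

The fixtures emulate the *structure* of the classification problem
(five-class layout, per-class counts, localizable nuclear cues), not real
Pap-smear optics: no staining variability, focus blur, overlapping cells,
inflammatory background or scanner artifacts. Passing the fixture-based
tests demonstrates that the architecture, optimizer, metrics and Grad-CAM
plumbing are correct and that the model can learn a nucleus-size rule
end-to-end; it says nothing about accuracy on real cytology, which
requires the real benchmark and a full training run.

## Explainability

`grad_cam()` hooks the SPPF output (the final convolutional stage; a flag
targets the CSP merge instead), backpropagates a single target-class logit,
spatially averages the gradient into channel weights $\alpha_k$ and forms
$\mathrm{ReLU}(\sum_k \alpha_k A_k)$, min-max normalized per image
(all-zero maps stay zero; the source's red/blue rendering implies relative
per-image scaling) and bilinearly upsampled. `localization_check()` scores
the fraction of heatmap mass inside the ground-truth nucleus mask and
inside a disc-dilated mask, against the area fraction a uniform heatmap
would score.

## Numerical choices and degenerate inputs

* LayerNorm $\epsilon = 10^{-6}$; attention softmax is max-subtracted;
  GELU is the exact ($\Phi$-based) form; dropout is inverted (scale
  $1/(1-p)$ at train time).
* Max-pool backward routes gradients first-wins on ties.
* Token-to-grid order is row-major (token $k \mapsto$ row
  $\lfloor (k-1)/14 \rfloor$, column $(k-1) \bmod 14$), fixed so the
  round-trip is well defined. Spatial maps use the R-natural channel-last
  layout `(H, W, C, B)`; the logical contract (197 tokens of 768, a
  $768 \times 14 \times 14$ map, and so on) is unchanged.
* Weight init is truncated normal ($\sigma = 0.02$, clipped at $2\sigma$);
  biases zero; LayerNorm gain one.
* Degenerate geometry (image size not divisible by the patch, token counts
  that are not perfect squares, channel mismatches, out-of-range labels)
  fails fast with named diagnostics; 0/0 metric ratios are reported as 0
  with a warning; an all-zero Grad-CAM map is returned as such with a
  notice.
* FLOPs are counted analytically: one multiply-accumulate = one FLOP over
  conv, linear and attention matrix products only ($QK^\top$ and
  $PV$ included; norms, activations, pooling excluded). Under this
  convention the full model costs 18.46 G at 224 px, within 5% of the
  published 17.731 G whose convention is unstated; the figure is logged,
  not asserted.

## Ablation variants

`build_variant()` shares one configuration across the roster: `full`
(everything), `vit_only` (encoder, class token into the head),
`vit_csp` (no SPPF), and `csp_sppf_only` (the patch-embedding conv reused
as a strided stem, no class/positional path — the source gives this
variant no architecture, so the stem choice is this package's own,
keeping it comparable). Parameter accounting is additive:
full − vit_csp = 1,475,712, the SPPF hand-sum. The published ablation
table's ViT-only row (0.046 M parameters) cannot describe the twelve-block
backbone its own hyperparameter tables specify (≈85.8 M); the package
reports the true count and does not chase that row.

## Problem sizes used by the test suite

The suite exercises full-geometry (224 px, 90.76 M-parameter) forward
passes for batch sizes 1, 2 and 7, and trains depth-reduced configurations
(16–56 px, embed 16–32, depth 1–2) elsewhere: 200 optimizer steps on the
64-image two-class fixture suffice to reach 100% training accuracy and a
Grad-CAM nucleus-localization score well above the uniform baseline. These
sizes are the package's own choices for a deterministic, CPU-only test
bed; scaling the same code to the published 450-epoch, batch-128 run
requires only the default configurations.

## Known limitations

* Pure-R execution: a full-scale training run at the published settings is
  far slower than the GPU run it mirrors; the package is built for
  correctness, inspection and desk-scale experiments.
* The CSP reconstruction (two parallel 768→384 transitions, one 384-wide
  transformer on branch 2, concat + merge conv) fills gaps the source's
  block table leaves open; it reproduces the published parameter budget,
  which is the strongest available consistency check.
* BatchNorm running statistics are updated only by the training loop;
  evaluating a BN-enabled model that was never trained uses the
  initialization statistics.
* `vit_only` supports no Grad-CAM (no convolutional stage), by
  construction.
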