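# caspnet

Hybrid vision-transformer + CSP/SPPF classifier for Pap-smear cervical
cell images, in pure R.

Automated screening of Pap smears asks a classifier to sort single-cell
crops into normal (Superficial-Intermediate, Parabasal) and abnormal
(Koilocytotic, Metaplastic, Dyskeratotic) classes — the five-class layout
of the standard SIPAKMED benchmark. The discriminative cues are
morphological: the nucleus-to-cytoplasm (N:C) area ratio, hyperchromasia
and nuclear irregularity. This package implements **CASPNet**, a hybrid
architecture that bridges a ViT-Base token encoder into YOLO-style
convolutional blocks:

```
image (224x224x3)
  -> patch embedding (16x16 conv, 196 tokens x 768) + CLS + positional
  -> 12 pre-norm transformer blocks (12 heads, head_dim 64, MLP 768->3072)
  -> drop CLS, reshape 196 tokens -> 768 x 14 x 14   (parameter-free)
  -> CSP block   (two 1x1-conv branches @384, one with a transformer,
                  concat + merge conv)
  -> SPPF block  (1x1 conv @384, three cascaded 5x5 stride-1 max pools
                  ~ 9x9 and 13x13 receptive fields, concat 1536 -> 768)
  -> global average pool -> LN(768) -> 512 -> 256 -> 5 logits
```

The full model has exactly **90,757,893 trainable parameters (90.76 M)**
and ~18.5 GFLOPs per image under a one-MAC-=-one-FLOP convention over
matrix products. Training follows the published recipe: cross-entropy,
AdamW with decoupled weight decay
(`theta <- theta - eta * mhat/(sqrt(vhat)+eps) - eta * lambda * theta`,
lambda = 0.05), and a per-step one-cycle cosine schedule
1e-4 → 1e-3 (first 10% of steps) → 1e-5, batch 128, 450 epochs, seed 1337.

Everything — forward passes, backpropagation, the optimizer, the schedule —
is written on base R matrix algebra; no deep-learning runtime is needed.
The package also provides deterministic stratified splitting, on-the-fly
augmentation, confusion-matrix/ROC evaluation, ablation accounting over
the four architecture variants, Grad-CAM at the SPPF output, and a
synthetic cell-image generator so the entire pipeline is testable with no
dataset download.

## Worked example

Train a depth-reduced CASPNet on a generated two-class fixture whose
classes differ only in nucleus size, then inspect what the model looks at:

```r
library(caspnet)

set <- generate_fixtures(fixture_profile("two_class"), tempfile("cells"))
print(set)
#> image_set: 64 images in 2 classes
#>   high_nc                       32
#>   low_nc                        32

splits <- stratified_split(set, split_spec(seed = 1337))   # 52/6/6

cfg <- arch_config(image_size = 56, patch_size = 8, embed_dim = 32,
                   depth = 2, num_heads = 2, csp_mid = 16, sppf_mid = 16,
                   head_hidden = c(32, 16), num_classes = 2)
fit <- caspnet_train(caspnet(config = cfg, seed = 42), splits$train,
                     val = splits$val,
                     config = training_config(max_lr = 3e-3,
                                              batch_size = 16,
                                              epochs = 50, seed = 7))
print(fit)
#> caspnet_fit: 50 epoch(s), 200 optimizer step(s)
#>   final train loss 0.0000, accuracy 1.000
#>   best validation accuracy 1.000

pred <- predict(fit, splits$test)
cm <- confusion_matrix(splits$test$items$class_idx, pred, n_classes = 2,
                       labels = set$class_names)
print(compute_metrics(cm))
#> overall accuracy: 100.00%
#>    class precision recall f1 accuracy support
#>  high_nc         1      1  1        1       3
#>   low_nc         1      1  1        1       3

img <- read_image(splits$test$items$path[1])
hm <- grad_cam(fit$best_model, img,
               target_class = splits$test$items$class_idx[1])
print(hm)
#> Grad-CAM heatmap (7x7 grid at the sppf output, class 1, p = 1.000)
```

The 200-step run overfits the fixture completely, and the Grad-CAM mass
concentrates on the nucleus: scored against the fixture's ground-truth
mask, `localization_check()` reports 0.83 of the heatmap mass inside the
nucleus (0.18 area fraction) and essentially all of it inside the dilated
mask — the model is using the cue the classes were built from.

Architecture accounting at full scale:

```r
summary(caspnet("full"))          # per-module parameter counts
#>   total       90,757,893  (90.76 M)
#>   FLOPs at 224 px: 18.460 G (MAC convention)
ablation_report()                 # the four variants, accounting only
```

A shell entry point wraps the same workflows
(`fixtures`, `train`, `evaluate`, `ablate`, `summary`, `gradcam`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","caspnet.R",package="caspnet"))')" \
    summary --variant full
```

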