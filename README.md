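# fpnseg

Binary semantic segmentation of brain tumors in 2D MRI slices, built
around a fully convolutional network that fuses a **U-Net contracting
path** with a **feature pyramid network (FPN) decoder**. The package is
aimed at medical-image-analysis practitioners who want the whole
pipeline — preprocessing, paired image/mask augmentation, training with
a smoothed Dice loss, overlap metrics — as testable R functions that run
end to end on CPU, with a synthetic phantom generator standing in for
the (external) lower-grade-glioma MRI slice collection.

## The method

The encoder is a U-Net contracting path: per scale two 3×3
convolutions (batch norm + ReLU) followed by 2× max-pooling, four
downsamplings in total. The four post-downsampling scales form a
feature pyramid at 1/2 … 1/16 of the input resolution. The decoder is
FPN-style:

* lateral 1×1 convolutions bring every level to a fixed width
  (128 channels at full scale);
* the top-down pathway upsamples each coarser merged map
  (nearest-neighbour) and adds it element-wise to the lateral map
  below;
* two 3×3 convolutions smooth each merged level;
* all levels are upsampled to the finest pyramid resolution and
  concatenated — 4 × 128 = **512 fused channels** — then a 3×3
  convolution with batch norm and ReLU and a 1×1 convolution produce
  logits, bilinearly upsampled to input resolution, with a sigmoid
  head.

Training minimizes the smoothed Dice loss

    L = 1 − (2·|A∩B| + ξ) / (|A| + |B| + ξ),   ξ = 100,

with Adam (lr 1e-4, batch 8) and early stopping on the validation Dice
loss. Evaluation reports the Dice similarity coefficient
DSC = 2|A∩B|/(|A|+|B|), the Jaccard/IoU index |A∩B|/|A∪B| and pixel
accuracy (TP+TN)/(TP+TN+FP+FN). A classical U-Net baseline with the
same encoder is included for side-by-side comparison.

No deep-learning framework is used: layers and gradients come from the
package's own reverse-mode autodiff tape over Rcpp/Armadillo
convolution kernels, validated against finite differences in the test
suite.

## Worked example

Train the improved-FPN model on 200 synthetic 64×64 phantoms
(tumor-bearing slices with exact masks), split 70/20/10, with the
nine-operation augmentation table:

```r
library(fpnseg)

pc <- phantom_config(image_size = c(64, 64), tumor_probability = 1,
                     seed = 100)
records <- preprocess_records(generate_phantom_records(200, pc))
split <- split_dataset(records, c(0.7, 0.2, 0.1), seed = 1)

cfg <- model_config(input_size = c(64, 64, 3),
                    encoder_widths = c(8, 16, 32, 64, 128),
                    lateral_channels = 48, seed = 1)
fit <- train(build_model(cfg, "improved_fpn"), split,
             training_config(max_epochs = 12, seed = 1),
             augmentation_config(), verbose = TRUE)
#> epoch  11  train 0.2841  val 0.2711  val DSC 0.8263
#> epoch  12  train 0.2466  val 0.2418  val DSC 0.8449

evaluate(fit, split$test)
#> evaluation (improved_fpn, 20 images): DSC 0.826, Jaccard 0.716, accuracy 0.9730
```

The printed numbers are the mean per-image DSC and Jaccard over the 20
held-out phantoms and the global pixel accuracy: the model recovers
~83% Dice overlap with the exact masks after 12 epochs on one CPU.
`autoplot(fit$history)` shows the loss/DSC trajectories;
`tidy(fit$model)` lists the per-layer architecture;
`score_masks()` scores exported mask files standalone.

A thin CLI (`inst/scripts/fpnseg`) exposes `make-synthetic`,
`preprocess`, `train`, `evaluate`, `predict`, `compare` and `score`
subcommands over the same functions, configured by a YAML file whose
augmentation block mirrors the nine operation names verbatim.

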