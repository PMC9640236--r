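# mmanet

Dual-branch multiresolution encoder–decoder networks for 2D short-axis
cardiac MR segmentation, implemented as a self-contained R package. It is
aimed at researchers who want a fully inspectable, CPU-runnable
implementation of a mutual-assistance segmentation architecture — every
layer, gradient and training step is in this package, with no external
deep-learning framework — together with a phantom generator that makes the
whole pipeline trainable and testable without any clinical data.

## The model

Cardiac MR slices are hard to segment because of intensity inhomogeneity
and blurred boundaries between adjacent tissues. The network addresses this
with three components:

- **Multibranch input.** The slice is fed to two parameter-independent
  VGG19-style encoders at full (224×224) and half (112×112) resolution.
  The high-resolution branch extracts local detail `M_E,i` (i = 1..5), the
  low-resolution branch global context `N_E,j` (j = 2..6); equal index
  means equal spatial side.
- **Mutual-assistance decoder.** An *attention gate* (AG) uses the deepest
  global feature `N_E,6` to suppress background in the deepest local
  feature `M_E,5`. *Feature fusion* (F) concatenates equal-width features
  and projects back with two 3×3 convolutions. *Attention feature
  selection* (A) lets each scale's shared complementary feature gate the
  same-scale encoder feature before fusing with it. The decoder computes a
  bottleneck `B = F(Up(N_E,6), AG(Up(N_E,6), M_E,5))` once, derives
  `M_D,4 = A(Up(B), M_E,4)` and `N_D,4 = A(Up(B), N_E,4)`, and then walks
  up the pyramid with `C_i = Up(F(M_D,i+1, N_D,i+1))`,
  `M_D,i = A(C_i, M_E,i)`, `N_D,i = A(C_i, N_E,i)` down to the
  full-resolution `M_D,1`, whose head is the final prediction.
- **Multilabel deep supervision (MLDS).** All seven decoder features get a
  1×1-convolution sigmoid head; each head is supervised *at its own scale*
  by a nearest-neighbour-downsampled one-hot label, with loss
  `L = L_BCE + L_DICE` summed over heads. The classical deep-supervision
  variant (upsample every head to full resolution first) is available as an
  ablation mode.

Evaluation uses Dice `2|A∩B|/(|A|+|B|)`, specificity `TN/(TN+FP)`,
sensitivity `TP/(TP+FN)` and F1 `2TP/(2TP+FP+FN)`, pooled per case and
averaged over cases and cross-validation folds.

## Worked example

A slim configuration (64-px phantoms, 1/8-width network) trains in well
under a minute on one CPU core:

```r
library(mmanet)

spec <- phantom_spec(side = 64)                      # slim 64-px phantoms
ds <- generate_dataset(spec, n_cases = 4, slices_per_case = 4, seed = 1)
ds <- preprocess_samples(ds, target_side = 64)       # crop + per-case 0-1

cfg <- net_config(input_side = 64, num_classes = 3, width_multiplier = 1/8)
tc  <- train_config(learning_rate = 2e-3, batch_size = 8,
                    max_epochs = 40, early_stop_patience = 10, seed = 1)

cases <- vapply(ds, `[[`, "", "case_id")
fit <- mma_train(cfg, ds[cases != "case004"], ds[cases == "case004"], tc)

held <- ds[cases == "case004"]
pred <- mma_predict(fit, held)
gt <- array(0L, dim(pred$masks))
for (i in seq_along(held)) gt[, , i] <- held[[i]]$mask
report <- evaluate_cases(list(case004 = pred$masks), list(case004 = gt),
                         class_ids = 1:3, class_names = c("RV", "Myo", "LV"))
print(report)
```

```
Segmentation metrics (1 cases)
  class   dice specificity sensitivity     f1
1    RV 0.9173      0.9897      0.9557 0.9173
2   Myo 0.9143      0.9963      0.8839 0.9143
3    LV 0.9061      0.9890      0.9626 0.9061
```

The held-out case is segmented with Dice ≈ 0.91 for all three structures
(right ventricle, myocardium, left ventricle) after 40 short epochs; note
dice = F1 exactly, as both reduce to the same expression on hard masks.

## Command line

`exec/mma` wraps the exported functions:

```sh
mma simulate --side 64 --cases 10 --slices 4 --seed 1 --out data/
mma train    --config config.yml --data data/ --out run/
mma cv       --config config.yml --data data/ --out run/
mma ablate   --config config.yml --data data/ --out run/   # Num/DS table
mma predict  --config config.yml --checkpoint run/checkpoint.rds \
             --input data/ --case case001 --out pred/
mma evaluate --pred pred/case001_pred.nii.gz --gt gt.nii.gz --out eval/
```

One YAML file drives everything; see `inst/extdata/example-config.yml`.

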