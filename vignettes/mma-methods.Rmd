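---
title: "Multiresolution mutual-assistance segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiresolution mutual-assistance segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
open design points were resolved the way they were.

## The segmentation model

The network is an encoder–decoder for 2D short-axis cardiac MR slices. Two
VGG19-style encoders — five stages of (2, 2, 4, 4, 4) 3×3 convolutions with
batch normalization, ReLU, and 2× max-pooling between stages — process the
same slice at full and half resolution. The branches share no parameters:
the full-resolution branch specialises in local detail, the half-resolution
branch in global context, and neither has to compromise its receptive-field
budget for the other. With input side $s$ (divisible by 32), branch 1
produces features $M_{E,i}$, $i = 1..5$, at sides $s/2^{i-1}$; branch 2
produces $N_{E,j}$, $j = 2..6$, at sides $s/2^{j-1}$, so equal index means
equal spatial side.

The decoder couples the branches through three operators:

* **Attention gate (AG)** — additive attention in the Attention-U-Net
  style: both inputs are projected to an intermediate width with 1×1
  convolutions, summed, passed through ReLU and a 1×1 convolution to one
  channel, and squashed by a sigmoid. The resulting per-pixel coefficient
  $\alpha \in [0,1]$ multiplies the local feature across channels.
* **Feature fusion (F)** — channel concatenation of equal-width features
  followed by two 3×3 convolution + BN + ReLU blocks projecting back to a
  single input's width.
* **Attention feature selection (A)** — the decoder-side "complementary"
  feature yields a one-channel coefficient map (1×1 convolution + sigmoid)
  that gates the same-scale encoder feature; complementary and gated
  encoder features are then concatenated and projected by the same
  two-convolution fusion block to the stage's channel count.

The wiring: the bottleneck $B = F(\mathrm{Up}(N_{E,6}),
\mathrm{AG}(\mathrm{Up}(N_{E,6}), M_{E,5}))$ is computed **once** and
shared, giving $M_{D,4} = A(\mathrm{Up}(B), M_{E,4})$ and $N_{D,4} =
A(\mathrm{Up}(B), N_{E,4})$. Below, each scale builds one shared
complementary feature $C_i = \mathrm{Up}(F(M_{D,i+1}, N_{D,i+1}))$ and sets
$M_{D,i} = A(C_i, M_{E,i})$, $N_{D,i} = A(C_i, N_{E,i})$, ending at the
full-resolution $M_{D,1}$. All seven decoder features receive a 1×1
sigmoid prediction head; inference uses the $M_{D,1}$ head only.

### Channel bookkeeping

The published description leaves the decoder channel plan open: branch 2's
encoder features carry the *previous* stage's width (e.g. $N_{E,4}$ has the
stage-3 width), so a literal cross-branch fusion of $M_{D,i+1}$ with
$N_{D,i+1}$ would concatenate unequal widths, violating the fusion
operator's own equal-width contract. This package resolves it by making
decoder stages *same-index-same-width*: $M_{D,i}$ and $N_{D,i}$ both carry
the stage-$i$ encoder width, with the attention-feature-selection fusion
convolutions performing the projection. Every standalone fusion call then
sees equal-width inputs, and the contract holds everywhere. Similarly, the
internal structure of the attention operators is not recoverable from the
text; the additive-attention reading for AG and the
"gate-then-concatenate-then-fuse" reading for A follow the operators'
stated roles and their cited lineage, and both sit behind narrow interfaces
(`attention_gate()`, `attention_feature_selection()`) so alternatives are
pluggable.

## Objective

Each head $k$ contributes $L_k = L_{\mathrm{BCE}} + L_{\mathrm{DICE}}$ and
the total loss is the unweighted sum over heads. Per channel (one-vs-rest
over $C$ foreground classes, which matches per-tissue reporting; $C = 1$
gives the pure binary task):

$$L_{\mathrm{BCE}} = -\frac{1}{n}\sum_{x,y} \big[G_{x,y}\log Q_{x,y} +
(1-G_{x,y})\log(1-Q_{x,y})\big], \qquad
L_{\mathrm{DICE}} = 1 - \frac{2\sum G Q + \epsilon_s}
{\sum G + \sum Q + \epsilon_s}.$$

Conventions worth stating because sums, signs and denominators are easy to
get wrong: cross-entropy is the standard *negated* form (a loss to be
minimised must be non-negative); BCE is averaged over pixels, channels and
batch so its scale is batch-size independent, while Dice is computed per
(channel, sample) and averaged; probabilities are clamped to
$[\epsilon_p, 1-\epsilon_p]$ with $\epsilon_p = 10^{-7}$; and
$\epsilon_s = 1$ makes an empty prediction of an empty target lossless.
In the evaluation metric the Dice denominator is $|A| + |B|$, the form
consistent with dice ≡ F1 on hard masks (asserted property-style in the
tests).

**Multilabel deep supervision.** In MLDS mode head $k$ is compared with the
one-hot mask *downsampled by nearest neighbour to the head's own side* —
targets stay crisp binary at every scale, and the full-resolution member
equals the one-hot mask bit-exactly. The DS ablation mode upsamples every
head bilinearly to full resolution and compares against the full-resolution
label only, reproducing the classical deep-supervision setup whose
upsampling-induced target inconsistency MLDS is designed to avoid.

## Training protocol

`train_config()` defaults encode the full-scale protocol: Adam with
$\beta_1 = 0.9$ (the conventional reading of "momentum" for Adam, which has
no classical momentum parameter; $\beta_2 = 0.999$), learning rate
$5\times10^{-4}$, batch size 32, weight decay $10^{-4}$ as an L2 term on
convolution weights, at most 1000 epochs, early stopping with patience 20
on the validation mean foreground Dice (the monitored quantity is not named
in the protocol; mean foreground Dice is the natural choice for a
segmentation monitor), no learning-rate schedule, and no pretrained
weights (pretraining is not part of the stated protocol, and grayscale MR
input uses a 1-channel first convolution anyway). The best-epoch parameters
are snapshotted and restored, so early stopping never returns a non-best
epoch.

**Desk scale.** The package's tests and the acceptance script run a *slim*
configuration: 64-px phantoms, width multiplier 1/8 (stage widths
8, 16, 32, 64, 64), batches of 4–8 slices, and a learning rate of
$2\times10^{-3}$ — a narrow network at small batch tolerates and needs a
larger Adam step than the full-scale setting, and converges in minutes on
one CPU core. Problem sizes used: memorization on 8 slices (2 cases) for at
most 200 steps; generalization with 20 training cases (80 slices) against 5
unseen cases (20 slices) for 30 epochs; the branch-count × supervision
ablation on 10 cases with 2-fold case-level cross-validation and 25 epochs
per fold. These sizes were chosen so each experiment completes in minutes
while leaving clear headroom over the test thresholds.

## Preprocessing and cross-validation

The pipeline order is fixed: center crop to the target side (inputs smaller
than the target are symmetrically zero-padded first; labels pad with
background), max-min normalization to $[0,1]$ computed over the *whole
case* (never per slice; a constant case maps to zeros), optional affine
augmentation (training only; image bilinear, mask nearest-neighbour, same
transform for both), and derivation of the half-resolution input from the
final full-resolution image by 2×2 bilinear averaging — so both branches
always see consistent content. Augmentation defaults (≤10 px translation,
scale 0.9–1.1, rotation ±15°) quantify "slight" perturbation and are
config-exposed. Cross-validation folds are assigned at *case* level by
seeded shuffling and round-robin dealing (fold sizes differ by at most 1);
all slices of a case share its fold, and the trainer additionally refuses
any train/validation case overlap. Within each fold a seeded 20% of the
training cases serves as the early-stopping set, distinct from the held-out
test fold.

## The phantom generator

`generate_phantom()` emulates the geometry and the two stated difficulties
of short-axis cardiac MR — intensity inhomogeneity and unclear boundaries —
without claiming anatomical realism. In `acdc_like` mode the mask is a
bright blood-pool disk (LV, class 3), a darker myocardial annulus strictly
surrounding it (Myo, class 2), and an RV crescent (class 1) abutting the
annulus as an angular sector of the next ring outward; `asc_like` mode is a
single tilted ellipse (LA, class 1). The image renders per-tissue base
intensities (LV 0.85, RV 0.55, Myo 0.30, background 0.15), multiplies a
smooth bias field (three broad Gaussians rescaled to $1 \pm$ amplitude,
mimicking coil inhomogeneity), applies a normalized Gaussian blur to soften
tissue boundaries, adds Gaussian noise (a Rician approximation is
unnecessary at this fidelity), and clips to $[0,1]$. The mask is generated
*before* blurring and is never smoothed — ground truth stays crisp. Slices
within a case share one geometry draw up to a small jitter (centers within
1.5 px, sizes within 4% + 0.5 px), which is what makes case-level
cross-validation meaningful. Default geometry scales with the image side
(LV radius 11–17% of side, myocardium 4.5–7%, RV thickness 6–10%, crescent
extent $\pi$), chosen to resemble mid-ventricular slice proportions.

What passing tests on phantoms do and do not show: they validate the
architecture, gradients, losses, training loop, fold handling and metrics
end to end, and they show the network can learn this class of shapes under
bias fields and noise. They do not establish clinical performance — real
short-axis data has through-plane anatomy changes, pathology, partial
volume effects and scanner-specific artifacts the generator does not
emulate, and the headline full-scale numbers require the registered
challenge datasets and full-width GPU training.

## Numerical implementation

No deep-learning framework for R is assumed: the package carries its own
layer-level reverse-mode engine. Forward ops record backward closures on a
tape; convolutions run as im2col + single-precision GEMM (the im2col matrix
is cached from the forward pass and reused in backward), while batch
normalization, pooling, upsampling and all losses run in double precision
with analytic gradients. The fp32 convolution path matches a
double-precision sliding-window reference to ~$10^{-5}$ and every kernel
passes finite-difference checks in the test suite. Accumulation order is
fixed, so training is bit-reproducible for a given seed on a given BLAS.
Further numerical choices: He fan-in initialization under a build seed;
batch-norm batch statistics in training with momentum-0.1 running averages
for inference; bilinear 2× upsampling with half-pixel centers (constants
are preserved exactly); max-pool ties resolved to the first element in
scan order; argmax ties at inference resolved to the lowest class index;
pixels are background unless some foreground probability reaches 0.5.

## Known limitations

Single-node CPU training only; 2D slices (no 3D context); the
unidirectional/two-way fusion-mode variants and 3- and 4-branch
configurations are out of scope (no implementable published description);
surface-distance metrics (Hausdorff, ASSD) are not provided; checkpoints
are R-serialized and not interchangeable with other frameworks.
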