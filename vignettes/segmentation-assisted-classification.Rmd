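---
title: "Segmentation-assisted staging of proliferative diabetic retinopathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation-assisted staging of proliferative diabetic retinopathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The method

Proliferative diabetic retinopathy (PDR) is defined by neovascularization
(NV): thin, web-like vessels that are small, low-contrast, and easily
confused with intraretinal microvascular abnormalities (IRMA) or drowned out
by far more salient lesions such as panretinal photocoagulation scars.
Whole-image convolutional classifiers therefore tend to latch onto the
salient but non-defining features.

`segassist` implements *segmentation-assisted classification*:

1. A fully convolutional network (FCN) is trained on the **green channel**
   of fundus photographs (NV vessels are red, so the green channel carries
   their strongest contrast) against binary NV masks, producing a per-pixel
   NV probability map. The head of the network is a single transposed
   convolution that upsamples the backbone's coarsest feature map back to
   the input resolution; at full scale (512 × 512 input) it uses stride 32
   and kernel size 64 and emits a 512 × 512 × 2 score map with a per-pixel
   two-class softmax.
2. The probability map is **fused** onto the original image as a fourth
   channel (RGB rescaled to [0, 1], probability already in [0, 1]), so no
   information from the photograph is lost. Fusion runs **once** per
   dataset; every classification trial consumes byte-identical fused files,
   enforced by a provenance digest of the segmentation checkpoint.
3. A four-category classifier (0 = NPDR without NV, 1 = past NV/laser
   scars, 2 = ambiguous lesions, 3 = active NV) is trained either on the
   3-channel RGB images (baseline arm) or on the 4-channel fused records
   (assisted arm), with identical architecture apart from the first layer's
   input channel count.
4. Repeated trials per arm are summarised by mean/SD accuracy, per-category
   one-vs-rest ROC/AUC, confusion matrices, and a Welch two-sample t-test
   on the per-trial accuracies.

## Why a simulator

The retinal photographs the method was developed for cannot be
redistributed, and their pixel-level NV annotations were never deposited.
The package therefore ships a seeded synthetic fundus generator as a
first-class module: a circular field with radial shading, an optic disc,
and a branching vessel tree, plus five lesion kinds:

* `nv_web` — clusters of thin random-walk strands, elevated red and
  depressed green; the **only** mask-positive kind. Webs are seeded within
  1.5 disc radii of the optic disc with probability 0.7, echoing the
  clinical tendency of NV to cluster at the disc.
* `laser_scar` — regular grids of pale dots; highly salient but
  mask-negative (they mark *past*, treated NV).
* `ambiguous_irma` — short, tortuous, thicker vessel segments with the
  same colour signature as NV: only shape and texture distinguish the two,
  so the distinction must be learned, not thresholded. Mask-negative.
* `hemorrhage`, `exudate` — confounders allowed in every category, with a
  higher rate in category 3 (severe eyes carry more non-NV lesions).

Category composition rules are structural invariants: category 0 has no NV
webs, category 1 has scars and no webs, category 2 has IRMA-like lesions
and no webs, category 3 has at least one web — so a mask is nonzero exactly
for category-3 images. Across many category-3 scenes the mask-positive
fraction of the field stays below 5%: the "few small areas of NV" regime
that makes whole-image classification hard and segmentation assistance
valuable.

What the simulator does **not** model: camera optics and 30° field
geometry, inter-device colour variation, image-quality artefacts, fibrous
tissue, and the full morphological variety of real NV. Passing tests on
synthetic data demonstrate that the pipeline's machinery behaves as
specified — not that the specific accuracy numbers transfer to real fundus
photographs.

## Networks and training

No deep-learning framework is required: the package implements its own
small convolutional engine (compiled kernels for convolution, transposed
convolution and max pooling; the layer graph, SGD-with-momentum loop and
softmax heads in R). Finite-difference gradient checks pin the engine down
in the test suite.

Design choices where the method description leaves room:

* **Loss**: per-pixel two-class cross-entropy for segmentation, with an
  optional positive-class weight (`pos_weight`) for the ~1–2% positive
  pixel fraction; four-class cross-entropy for classification, unweighted
  by default (matching the observed tendency of a baseline classifier to
  collapse onto the majority categories).
* **Optimizer**: SGD with momentum 0.9. "Decay" is a per-epoch
  multiplicative learning-rate factor: `lr_k = lr · decay^k`.
* **Dropout** is applied before the network head.
* **Minibatches**: gradients are averaged over minibatches (default 5) for
  the classifier; classifier inputs are centred by subtracting 0.35, the
  approximate mean intensity of the simulated field.
* **Backbone**: a miniature inception-style stack (parallel 1×1/3×3
  branches) whose total downsampling equals the transposed-convolution
  stride. The full-scale head contract (stride 32, kernel 64, 512 × 512 × 2
  output) is honoured and tested at size 512; desk-scale training uses a
  stride-2 or stride-4 head at 64 × 64 to keep CPU runs in seconds to
  minutes.
* **Model selection**: the checkpoint with the best validation accuracy is
  used for testing (`select = "final"` is available).
* **Empty-mask convention**: Dice and IOU are 1 when both masks are empty
  and 0 when exactly one is; probability maps are binarized at 0.5 by
  default (threshold config-exposed).
* **Augmentation** (classification training only): rotation ≤ 15°, both
  flips, translation ≤ 10%, brightness multiplier in [0.8, 1.2]. Geometric
  transforms act identically on all channels; brightness acts on colour
  channels only — a probability channel is a calibrated quantity, not a
  photometric one. This protection is also the mechanistic reason the
  assisted arm is robust where the baseline must cope with photometric
  jitter on its only NV cue.
* **Rotation resampling** is nearest-neighbour about the image centre, so
  the identical geometric map applies to every channel without inventing
  interpolated probability values.

## The split arithmetic

Stratified splitting uses largest-remainder rounding per category, which
sums exactly to each category total and is reproducible under a seed. A
printed partition of a real cohort need not equal exact fractions of the
total (e.g. 75/8/17% of 1163 gives 872/93/198, while the reference cohort
partition is 867/98/198); `assign_splits()` therefore also accepts an
explicit per-category count override that reproduces any printed partition
exactly. The segmentation subset is drawn from classifier-*training* rows
only, so no segmentation-time pixel ever leaks into classifier validation
or testing.

## The desk-scale study conditions

`exp_config()` fixes the benchmark the tests and the acceptance script
run: 200 images at 64 × 64 in proportions 52/12/4/32% (104/24/8/64),
split 75/8/17%, an FCN trained once for 50 epochs on 45 training-row
images (about half of them category 3, 5 held out for validation;
learning rate 0.05, decay 0.98, dropout 0.1, positive-class weight 12,
stride-2/kernel-4 head), and three classifier trials per arm (24 epochs,
learning rate 0.02, decay 0.99, dropout 0.1, width 12, minibatch 5) with
distinct seeds per trial. Segmentation quality (mean Dice/IOU, image-level
presence accuracy at the any-pixel-above-0.5 rule) is reported on the
classification test rows, which the FCN never saw. These sizes were chosen
once as the smallest conditions under which all pipeline stages train
meaningfully on a single CPU in minutes.

Statistical conventions: reported SD is the sample (n−1) standard
deviation of per-trial accuracies; the arm comparison is a Welch
two-sample t-test computed in closed form (two identical constant arms
give t = 0, p = 1, where a textbook implementation is undefined); ROC
curves are one-vs-rest on each category's softmax probability, AUC by
trapezoidal integration (equal to pairwise concordance with ties counted
one half); argmax ties resolve to the lowest category index.

## Known limitations

* A two-sample t-test on three trials per arm has limited power; with the
  between-trial variability typical of small test sets, a positive
  improvement need not reach conventional significance levels.
* Mean Dice over a set mixing NV-present and NV-absent images blends the
  empty-mask convention (0 or 1) with overlap quality; the per-image table
  in `seg_metrics()` keeps the two interpretable separately.
* The simulator's lesion appearance models are deliberately simple and
  parameterized; tightening realism (lower contrast, more confusable
  lesions) will lower all accuracies and can shrink the assisted-arm
  margin.
* Determinism holds for a fixed platform/BLAS; bit-identical results across
  different numerical libraries are not guaranteed.
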