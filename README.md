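# segassist

Segmentation-assisted classification of proliferative diabetic retinopathy
(PDR) from colour fundus photographs — an R implementation of the
two-network pipeline in which a fully convolutional network (FCN) first
labels every pixel with a neovascularization (NV) probability, and that
probability map is fused onto the image as a fourth channel before
whole-image staging by a convolutional classifier.

## The problem

PDR, the stage of diabetic retinopathy that demands urgent treatment, is
defined by NV: thin, web-like vessels that are small and low-contrast.
Whole-image classifiers instead latch onto salient but non-defining
features — laser scars from *past* treatment, large hemorrhages — and
confuse NV with look-alike intraretinal microvascular abnormalities
(IRMA). Pixel-level supervision turns each image into hundreds of
thousands of training points for the lesion that actually matters; fusing
the resulting probability map into the classifier's input carries that
signal into staging without losing the original photograph:

* segmentation: green channel → FCN → per-pixel `P(NV)`, trained with
  per-pixel two-class cross-entropy; a transposed-convolution head
  (stride 32, kernel 64 at full 512 × 512 scale) restores input resolution.
* fusion: `(R, G, B, P(NV))`, RGB rescaled to [0, 1]; computed **once** per
  dataset, cached as 32-bit TIFF, provenance-locked to the
  segmentation checkpoint.
* staging into four categories (0 NPDR/no NV, 1 past NV, 2 ambiguous,
  3 active NV); baseline arm uses RGB only, assisted arm the 4-channel
  records; arms are compared over repeated trials by mean ± SD accuracy,
  per-category one-vs-rest ROC/AUC (Dice and IOU for segmentation), and a
  Welch t-test.

Because the original photographs and their NV annotations cannot be
redistributed, the package includes a seeded synthetic fundus simulator
(optic disc, branching vessels, NV webs, laser-scar dot grids, IRMA-like
segments, hemorrhages/exudates) that reproduces the statistical structure
of such a cohort, so the whole pipeline runs end to end on a laptop CPU.
See the vignette `vignettes/segmentation-assisted-classification.Rmd` for
the model, the simulator's design and its limits.

## Worked example

```r
library(segassist)

# a 200-image synthetic cohort in the 52/12/4/32% category mix,
# FCN trained once, maps fused once, three classifier trials per arm
res <- run_experiment(exp_config(master_seed = 1), work_dir = "exp")
print(res)
#> Trial report [baseline]: mean accuracy 0.7843 (SD 0.1672) over 3 trials
#>   per-category AUC: 0: 0.919, 1: 0.956, 2: 0.838, 3: 0.768
#> Trial report [assisted]: mean accuracy 0.8922 (SD 0.0170) over 3 trials
#>   per-category AUC: 0: 0.998, 1: 0.903, 2: 0.939, 3: 0.997
#> Arm comparison (welch_two_sample)
#>   baseline: mean 0.7843 (SD 0.1672, n=3)
#>   assisted: mean 0.8922 (SD 0.0170, n=3)
#>   improvement: 0.1078   t = 1.111, df = 2.04, p = 0.3802
#> Segmentation (test rows): mean Dice 0.5816, mean IOU 0.5291, presence accuracy 0.7059

glance(res)     # one-row summary: improvement, Welch t/p, Dice/IOU/presence
tidy(res)       # per-trial accuracies of both arms
autoplot(res)   # mean +/- SD bars with individual trials
```

Reading the output: the assisted arm's mean test accuracy exceeds the
baseline's because the probability channel makes the few small NV pixels —
the defining feature of category 3 — explicit, where the baseline must
infer them from raw RGB under augmentation jitter; note the baseline's
large between-trial SD — some trials discover the NV cue and some do not,
so with only three trials per arm the Welch test need not reach
significance even when the mean gap is large. Segmentation quality is
reported on classification test rows the FCN never saw; mean Dice blends
overlap quality on NV images with the empty-mask convention (1 when both
truth and prediction are empty, 0 when only one is) on NV-free images.

Lower-level pieces compose the same way the pipeline uses them:

```r
manifest <- generate_dataset(c(10, 5, 2, 8), rng_seed = 7, size = 64,
                             out_dir = "demo")
manifest <- assign_splits(manifest, split_spec(c(0.75, 0.08, 0.17),
                                               stratified = TRUE,
                                               rng_seed = 7))
fit  <- train_fcn(manifest, seg_config(epochs = 50, image_size = 64,
                                       upsample_stride = 2,
                                       upsample_filter = 4,
                                       pos_weight = 12))
fused <- batch_fuse(manifest, fit$model, "demo/fused")
```

A thin CLI wraps the same functions: `exec/segassist simulate|split|
train-seg|predict-seg|fuse|train-cls|experiment ...`.

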