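# encore

Enhancer window classification and boundary condensation from epigenetic
signal tracks.

## What it does

Genome-wide enhancer annotations from classical predictors are coarse:
they label kilobase windows, while the functional enhancer core is often
only 50–1500 bp.  `encore` treats enhancer discovery as a weakly
supervised object-detection problem in 1D:

1. **Classify.**  A convolutional neural network scores 4 kb genomic
   windows represented as 5 × 400 matrices — five epigenetic assays
   (chromatin accessibility in the middle row, flanked by H3K4me3,
   H3K9ac, H3K27ac and H3K4me1) by 400 bins of 10 bp mean signal.  The
   architecture is seven convolutional layers (a 5 × 10 two-dimensional
   stage that collapses the assay axis, then 1 × 4 one-dimensional
   layers) with squeeze-and-excitation gates between layers, two max-pool
   layers, two dense layers and a sigmoid head:
   `P(enhancer) = 1 / (1 + exp(-x))`.
   Training labels come from STARR-seq peaks corroborated by
   accessibility and histone peaks; negatives are background windows at a
   1:10 ratio, countered by class weights `w_c = N / (2 N_c)`.
2. **Condense.**  For every positive window, Grad-CAM weights each filter
   of a convolutional layer by the spatially averaged gradient of the
   class score, `a_k = (1/Z) Σ_i Σ_j ∂y/∂A_ij^k`, and forms the map
   `ReLU(Σ_k a_k A^k)`.  The map from the last 1D layer gives a per-bin
   (10 bp) importance score; bins scoring above the mean over all
   positive windows are merged into refined core-enhancer intervals —
   boundaries the classifier was never trained on.

The package also ships a synthetic five-assay genome generator with
ground-truth enhancer cores (accessibility peak + histone
peak–trough–peak shapes over autocorrelated background), so the whole
pipeline is testable without external data, plus evaluation utilities
(auROC/auPRC, k-fold and leave-one-chromosome/cell-type-out
cross-validation, boundary-recovery metrics).

## Worked example

```r
library(encore)

# a synthetic genome: 100 planted enhancers, five tracks, ground truth
sim <- simulate_dataset(sim_config(n_positive = 100, noise_scale = 0.3,
                                   seed = 11))
sim$dataset
#> <labeled_dataset> 1100 windows ( 100 positive / 1000 negative ), 5 x 400 matrices

# train the classifier (small model; a few epochs suffice here)
model <- build_model(model_config(n_filters = 16), sim$dataset$panel, seed = 2)
model <- train_model(model, sim$dataset,
                     train_config(learning_rate = 5e-4, epochs = 10, seed = 3))
tail(model$history, 2)
#>    epoch   train_loss     val_loss
#> 9      9 0.0002975088 1.421443e-05
#> 10    10 0.0001888255 1.118345e-05

val <- model$fit$val_idx
auroc(sim$dataset$label[val], predict(model, subset_dataset(sim$dataset, val)))
#> [1] 1

# scan the genome and condense positive windows to core enhancers
scan <- scan_genome(model, sim$tracks, sim$chrom_sizes)
ann <- condense(scan, model, sim$tracks)
ann
#> <condensed_annotation> 100 original / 128 refined elements; refined coverage 30.3% of original

boundary_recovery(ann$refined, sim$truth)$medians
#>   jaccard precision    recall
#> 0.3280455 0.3280455 1.0000000
```

The refined set shrinks the annotation to under a third of the merged
positive windows while recalling every true core completely; the
moderate per-enhancer Jaccard reflects that the flanking histone peaks
are genuinely informative to the classifier, so importance (and hence
the refined interval) extends somewhat beyond the accessibility core.
On low-noise genomes the median Jaccard rises to ~0.6 (see the
acceptance checks).

Positions-wise and feature-wise importance maps for a single window:

```r
m <- sim$dataset$x[, , 1]
s <- positionwise_scores(model, m)   # length 400, one score per 10 bp bin
f <- featurewise_scores(model, m)    # 5 x 400, one row per assay
```

A thin command-line front end is installed at
`system.file("cli", "encore.R", package = "encore")` with `simulate`,
`scan` and `eval` subcommands reading/writing bedGraph, BED and TSV.

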