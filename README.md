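# sliceprop

Volumetric segmentation from a single annotated slice per training volume.

Dense 3D annotation is the bottleneck of medical image segmentation.
`sliceprop` implements an incremental 2D self-labelling framework for the
extreme sparse regime in which each training volume of depth *z* carries a
manual annotation only on its central slice, at zero-based index
⌊*z*/2⌋. A compact 2D U-Net *f₁* (8 filters in the first layer, doubling
to 128 in the bottleneck) is first trained on those central slices with
5-fold cross-validation. Then, iteratively, the current model *fᵢ*
predicts the slices immediately adjacent to each volume's labelled
interval — a per-side budget of s = max(1, round(k·z/2)) slices, k = 5% by
default — and the predictions are thresholded at a confidence level
θ (default 0.7): pixels ≥ θ become pseudo-label foreground, and a slice
with no pixel above θ is still added as an all-background mask rather than
skipped. The model is fine-tuned on the cumulative pool (ground truth plus
all pseudo-labels, never augmented, warm-started) and the loop repeats
until every volume is fully pseudo-labelled. Optional loss weights over
the normalised slice index NSI = index/(z−1) (uniform, Gaussian,
stepwise) down-weight distal pseudo-labels; a random-expansion ablation
replaces adjacent selection with uniform draws at the same rate.

Held-out volumes are scored with DSC = 2TP/(2TP+FP+FN),
IoU = TP/(TP+FP+FN), TPR, TNR, and the 95th-percentile Hausdorff distance
(HD95) between 6-connected segmentation surfaces in millimetres, computed
with an exact anisotropic Euclidean distance transform.

There is no deep-learning framework underneath: the U-Net forward pass,
backpropagation and RMSprop optimiser are implemented natively in
Rcpp/Armadillo and validated against an independent pure-R reference
forward pass and double-precision finite differences.

## Worked example

Everything below runs on bundled synthetic phantoms (ellipsoidal
foreground blobs in Gaussian noise; no downloads). The default experiment
generates 28 volumes of shape 24×32×32 (20 train / 4 validation / 4 test)
and compares training regimes that share the same data and the same
initial model:

```r
library(sliceprop)

cmp <- run_comparison(experiment_config(seed = 1),
                      modes = c("central_only", "selflabel"))
cmp$selflabel$n_iterations
#> [1] 12
cmp$central_only$summary
#>   metric      mean           sd n
#> 1    dsc 0.8950748 0.0317905108 4
#> 2    iou 0.8111968 0.0518820574 4
#> 3    tpr 0.9890738 0.0075684329 4
#> 4    tnr 0.9893357 0.0004241309 4
#> 5   hd95 1.1035534 0.2071067812 4
cmp$selflabel$summary
#>   metric      mean           sd n
#> 1    dsc 0.9318520 0.0192771521 4
#> 2    iou 0.8728555 0.0336731416 4
#> 3    tpr 0.9780199 0.0115407139 4
#> 4    tnr 0.9942653 0.0005932673 4
#> 5   hd95 1.0000000 0.0000000000 4
```

Reading this: the central-slices-only baseline already finds the blob on
feature-rich slices (TPR 0.989) but hallucinates foreground on distal and
empty slices (TNR 0.989, mean test Dice 0.895, HD95 1.10 mm). Twelve
self-labelling iterations — exactly ⌈12/1⌉ for depth 24 at k = 5%, one
slice per side per iteration — lift mean test Dice to 0.932 and reduce
HD95 to 1.00 mm, mostly by teaching the model (via background-fill
pseudo-labels) which slices contain nothing. `cmp$selflabel$audit` logs
every generated slice with its iteration, NSI, source
(`pseudo`/`background_fill`), confidence statistics and loss weight.

The building blocks are exported individually — `phantom_params()` /
`generate_phantom_dataset()`, `model_spec()` /
`build_segmentation_network()` / `count_trainable_parameters()`,
`init_with_crossval()`, `run_selflabel()`, `confusion_and_metrics()`,
`hd95()`, `per_nsi_profile()`, NIfTI I/O via `read_volume()` /
`write_volume()` — and a thin command-line front end lives at
`inst/cli/sliceprop.R` (`simulate`, `run`, `evaluate`).

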