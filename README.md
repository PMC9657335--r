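# emgtsci

Detecting the electrophysiological signature of a traumatic spinal cord
injury (TSCI) in intramuscular electromyography (EMG), and comparing a
classical feature-based classifier against a compact deep network that
learns its own features.

## The problem

After a spinal cord lesion, the muscles innervated below the lesion show
perturbed electrical activity: fewer motor units (MUs) are recruited,
surviving units fire more slowly, and their motor unit potentials are
attenuated. A recorded intramuscular EMG signal is the superposition of
the motor unit potential trains (MUPTs) of all firing MUs plus
background noise, so the pre- vs post-lesion contrast is, in principle,
decodable from the raw signal. `emgtsci` implements a complete,
reproducible pipeline for this binary classification task
(pre-lesion = class 0, post-lesion = class 1):

1. **Synthetic data** — a seeded MUPT-superposition simulator produces
   labelled pre- and post-lesion recordings. The post-lesion regime is
   parameterized by `(recruitment fraction, rate scale, amplitude
   scale)`, default `(0.5, 0.8, 0.6)`.
2. **Signal conditioning** — zero-phase (forward–backward) 4th-order
   Butterworth bandpass, 10–450 Hz, plus a 60 Hz notch (Q = 30).
3. **Windowing** — disjoint 1000 ms windows (1000 samples at 1000 Hz),
   random over-sampling of the minority class, per-window min–max
   normalization to [0, 1], stratified 80:20 train/test split.
4. **Classical arm** — four EMG amplitude features per window (area
   `Σ|x|`, RMS, turn count, zero-crossing count), standardized then
   min–max rescaled with training-set parameters, classified by
   k-nearest neighbours with k = 9.
5. **Deep arm** — a 1-D CNN: four conv blocks
   (32×5/s2, 32×5/s2, 64×3/s1, 128×3/s1, each with ReLU + max-pool 2/2,
   dropout 0.1 after blocks 3–4), global average pooling, a dense
   ReLU layer of 100 units and one sigmoid output; 49,257 trainable
   parameters. Trained with Adam (learning rate 0.001, batch 128) on
   the binary cross-entropy loss
   `BC = -(1/n) Σᵢ [xᵢ log yᵢ + (1-xᵢ) log(1-yᵢ)]`.
   The convolution/pooling engine, backpropagation and the Adam
   optimizer are implemented in vectorized base R inside the package.
6. **Evaluation** — confusion matrix and five metrics (accuracy,
   sensitivity, specificity, precision, F-measure; positive class =
   post-lesion), on the held-out split and/or stratified 5-fold
   cross-validation, with side-by-side comparison tables and plots.

## Worked example

```r
library(emgtsci)

cfg <- default_run_config(master_seed = 1, output_dir = "emgtsci_out")
cfg$simulation$n_pre  <- 60L   # shrink the default 400/class for a quick look
cfg$simulation$n_post <- 60L
cfg$cnn$epochs <- 8L

res <- run_pipeline(cfg, verbose = TRUE)
res$knn_report
#> <evaluation_report> 1 folds
#> mean metrics (%):
#>    accuracy sensitivity specificity   precision   f_measure
#>         100         100         100         100         100
res$cnn_report
#> <evaluation_report> 1 folds
#> mean metrics (%):
#>    accuracy sensitivity specificity   precision   f_measure
#>       85.42       87.50       83.33       84.00       85.71
```

With 60 recordings per class and only 8 training epochs the kNN arm
already separates the two classes perfectly, while the CNN is still
converging (85% F-measure). At the default study conditions
(400 recordings per class, 30 epochs, ~5 minutes on one CPU) both arms
exceed 95% F-measure on the held-out windows and the CNN's train and
test loss curves decrease together without diverging. Artifacts —
`metrics_comparison.csv`, the grouped bar plot, `cnn_history.csv`, the
loss/accuracy curves and a checksummed `manifest.json` — are written to
`cfg$output_dir`.

Architecture introspection works without training anything:

```r
spec <- default_architecture()
derive_shapes(spec)          # 1000 -> 500 -> 250 -> 125 -> 63 -> 63 -> 32 -> 32 -> 16 -> GAP(128)
count_parameters(spec)$total
#> [1] 49257
```

A thin command-line wrapper is included:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "emgtsci.R", package = "emgtsci"))')" \
    run-all --seed 1 --out emgtsci_out
```

## Notes

- The simulator's sampling rate defaults to 1000 Hz, chosen so that one
  1000 ms analysis window is exactly 1000 samples (one sample per
  millisecond) and the 450 Hz bandpass cutoff is realizable. See the
  methods vignette (`vignettes/emgtsci-methods.Rmd`) for this and all
  other modelling choices, tunable parameters and limitations.
- All data in this package are synthetic; the simulator's lesion
  direction (reduced recruitment, rate and amplitude) is a modelling
  assumption and is fully configurable.
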