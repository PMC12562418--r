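# spectraseed

Identification of maize seed varieties from hyperspectral imaging data.
The package covers the full workflow a seed-phenotyping lab needs: reading
ENVI-style hyperspectral cubes, black/white reflectance calibration,
automatic seed segmentation and region-of-interest mean-spectrum
extraction, Savitzky–Golay smoothing, stratified splitting, PCA/LDA
exploratory projections, wavelength selection by the successive
projections algorithm (SPA) and competitive adaptive reweighted sampling
(CARS), and classification of 20 varieties with a residual–Mamba
one-dimensional network compared against seven reference classifiers.
Because curated seed cubes are rarely redistributable, a synthetic-data
module generates labelled spectra sets and full scenes with the documented
statistical structure of maize seed reflectance, so the entire pipeline is
testable offline.

## The model

A reflectance spectrum (320 bands, 380–1018 nm) is standardized and fed to
a 1D network:

* three residual convolution blocks (channels 64/128/256; each
  `conv → ReLU → conv → LayerNorm` + skip, then max-pool /2), giving a
  length-40 sequence of 256-channel features;
* learnable positional encodings and two stacked selective state-space
  (Mamba) blocks — gated, causal, with data-dependent step size Δ, input
  matrix *B* and output matrix *C*, a learned negative-real diagonal state
  matrix and linear cost in sequence length;
* dropout and a fully connected head to C = 20 logits.

Training minimises the label-smoothing cross-entropy

    Loss = − Σᵢ [(1 − ε)·yᵢ + ε/C] · log ŷᵢ ,   ε = 0.1

with Adam, halving the learning rate after 5 epochs without validation
improvement and stopping after 10. Evaluation follows the repeated-run
protocol: per-class TP/FP/FN, precision/recall/F1 (percent, two
decimals), overall accuracy per run, and average/highest accuracy across
seeds. The ablations `rescnn1d` (no Mamba), `mambacnn1d` (no residual
front end) and `cnn1d`, plus SVM, ELM, BP and LSTM baselines, share one
interface.

All network algebra (convolutions, layer norm, the selective scan, full
backpropagation) is implemented in single-threaded compiled kernels inside
the package — no external deep-learning runtime is required — and is
verified against double-precision reference implementations by finite
differences in the test suite.

## Worked example

```r
library(spectraseed)

# 4 varieties x 40 seeds of synthetic reflectance spectra
cfg <- synth_config(n_classes = 4, seeds_per_class = 40, n_bands = 64,
                    rng_seed = 7)
spectra <- sg_smooth(generate_spectra(cfg))
division <- stratified_split(spectra, test_fraction = 0.2, seed = 1)
sets <- standardize_spectra(spectra[division$train_idx, ],
                            test = spectra[division$test_idx, ])

model <- fit_baseline(sets$train, baseline_spec("rm1dnet",
                        residual_channels = c(8, 16, 16), state_dim = 4),
                      config = train_config(max_epochs = 20, batch_size = 16,
                                            scheduler_patience = 4,
                                            early_stop_patience = 8,
                                            n_runs = 1, seeds = 1),
                      seed = 42)
report <- evaluate_classifier(model, sets$test)
report
#> # Evaluation: accuracy 90.62%, macro P/R/F1 93.18/90.62/90.28 (4 classes)
glance(report)
#> # A tibble: 1 × 4
#>   accuracy macro_precision macro_recall macro_f1
#>      <dbl>           <dbl>        <dbl>    <dbl>
#> 1     90.6            93.2         90.6     90.3
```

Accuracy is the percentage of the 32 held-out seeds assigned their true
variety; the macro columns average per-class precision, recall and F1 over
the four varieties. A 20-epoch run of a deliberately small network on 128
training spectra is enough to sort four moderately separated varieties at
about 90% — the full-size protocol below does substantially better.

`tidy(report)` gives the per-class TP/FP/FN and precision/recall/F1 table;
`autoplot(spectra)` plots spectra by variety and `autoplot(report)` the
confusion matrix. At full scale, `run_experiment(experiment_config(...))`
trains every configured model on the full spectrum and on SPA/CARS-selected
bands, n runs each, and writes the summary, per-class detail, confusion
matrix and selection diagnostics as CSV/text with a config echo.

Wavelength selection on the training set:

```r
cars <- cars_select(sets$train, spectra_labels(sets$train),
                    n_iterations = 30, seed = 1)
glance(cars)
#> # A tibble: 1 × 3
#>   method n_selected best_iteration
#>   <chr>       <int>          <int>
#> 1 CARS           33              1
```

Here cross-validated error is lowest at the first iteration, so CARS keeps
the 33 bands surviving the first competitive resampling round;
`tidy(cars)` exposes the RMSECV and retained-count paths behind that
choice, and `autoplot(cars)` plots them.

A command-line entry point wraps the same functions:

```sh
inst/cli/spectraseed synth spectra --out spectra.tsv --seed 1
inst/cli/spectraseed preprocess --in spectra.tsv --out-train tr.tsv --out-test te.tsv
inst/cli/spectraseed select --in tr.tsv --method cars --out cars.txt
inst/cli/spectraseed --version
```

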