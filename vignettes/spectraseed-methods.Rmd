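---
title: "Methods: hyperspectral seed variety identification with spectraseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral seed variety identification with spectraseed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

Maize seed varieties differ by small, distributed features of their
visible/near-infrared reflectance spectra. spectraseed implements the full
workflow for identifying 20 varieties from hyperspectral images of seeds:

1. **Calibration.** Raw detector counts are converted to reflectance with
   the black/white correction $I_c = (I_\mathrm{raw} - I_\mathrm{dark}) /
   (I_\mathrm{white} - I_\mathrm{dark})$, applied per pixel and band
   (`calibrate()`). Reflectance is clipped to $[0, 1.5]$: specular pixels
   can legitimately exceed 1 and silently discarding them would hide
   calibration faults, so the clip count is reported.
2. **Segmentation and extraction.** Seeds are segmented by Otsu
   thresholding of the band-mean image and 4-connected component labelling;
   the largest axis-aligned rectangle inscribed in each seed mask is the
   region of interest, and the ROI's pixel-mean spectrum represents the
   seed (`segment_seeds()`, `largest_inscribed_rectangle()`,
   `extract_mean_spectra()`). Pixel rectangles are 0-based and half-open
   throughout.
3. **Preprocessing.** Savitzky–Golay smoothing with a three-point window
   (`sg_smooth()`), a stratified 8:2 train/test split
   (`stratified_split()`), and per-band standardization fitted on the
   training set only (`standardize_spectra()`). PCA and a
   shrinkage-regularised Fisher LDA (`pca_project()`, `lda_project()`)
   provide exploratory three-dimensional projections.
4. **Wavelength selection.** The successive projections algorithm
   (`spa_select()`) and competitive adaptive reweighted sampling with PLS
   (`cars_select()`), both authored here on top of a NIPALS PLS2
   implementation (`pls_fit()`).
5. **Classification.** The residual-Mamba one-dimensional network
   (`rm1dnet`) and seven reference classifiers under one interface
   (`baseline_spec()`, `fit_baseline()`), evaluated with repeated runs,
   confusion-matrix metrics, and average/highest accuracy
   (`repeated_eval()`, `eval_report()`, `run_experiment()`).

## The classifier

The network maps a standardized spectrum of $B$ bands to $C = 20$ class
logits:

* **Residual front end.** Three residual blocks with output channels 64,
  128 and 256, each `conv(k=3) → ReLU → conv(k=3) → LayerNorm` plus a skip
  connection (a $1{\times}1$ convolution where channel counts differ),
  each followed by max-pooling with factor 2. For $B = 320$ the pooled
  sequence length is $L = 320 / 2^3 = 40$.
* **State-space stage.** The pooled feature map gains a learnable
  positional encoding and passes through two stacked selective state-space
  (Mamba) blocks. Each block projects to an expanded width (factor 2),
  runs a depthwise causal convolution (width 4) and SiLU, then a selective
  scan whose step size $\Delta$ (softplus of a learned low-rank
  projection), input matrix $B_t$ and output matrix $C_t$ are
  data-dependent, with a learned negative-real diagonal state matrix
  ($A = -\exp(A_{\log})$, state size 16 per channel, initialised as the
  ramp $\log 1 \ldots \log 16$) and a skip gain $D$; a SiLU gate and an
  output projection close the block, which is residual. These internals
  follow the original selective-SSM formulation since the architecture
  description fixes only the block's role, not its hyperparameters.
  Each block is *pre-normalised* (LayerNorm on the block input, residual
  from the unnormalised input). This is the standard arrangement for
  stacked selective-SSM blocks and is load-bearing: without it the
  unnormalised residual stream grows multiplicatively through the scan and
  activations overflow within one forward pass.
* **Head.** Flatten, dropout 0.3, and a fully connected layer to 20
  logits.

Training minimises the label-smoothing cross-entropy

$$\mathcal{L} = -\sum_{i=1}^{C}\Big[(1-\varepsilon)\,y_i +
\frac{\varepsilon}{C}\Big]\log \hat y_i,\qquad \varepsilon = 0.1,$$

with Adam (initial rate $10^{-3}$), a reduce-on-plateau schedule that
halves the rate after five epochs without validation-accuracy improvement,
and early stopping after ten stagnant epochs. Because the original split
defines only train and test sets while the schedule monitors validation
accuracy, a stratified 10% of the training set is carved out as the
validation set; the test set is never touched during training. The weights
restored at the end are those of the best validation epoch, with accuracy
ties broken by the lower validation loss — on easy problems validation
accuracy saturates within an epoch or two and would otherwise freeze an
undertrained snapshot.

The ablation family shares the same engine: `rescnn1d` is the network with
zero Mamba blocks, `mambacnn1d` swaps the residual front end for plain
conv–ReLU–pool stages, and `cnn1d` keeps only the plain front end. The
remaining baselines are an RBF-kernel SVM (small internal CV grid over
cost and kernel width), an extreme learning machine (1000 random sigmoid
features, ridge $10^{-3}$, closed-form readout), a two-hidden-layer
perceptron (256/128), and an LSTM over the band sequence (hidden size 128,
last-state readout) — conventional defaults, exposed in the configuration,
since no reference settings exist for them.

All dense algebra runs in single-precision compiled kernels on one thread;
for fixed seeds two training runs produce bit-identical weights. Gradient
correctness of every kernel (convolution, pooling, layer normalisation,
the full selective scan) is established in the test suite by central
finite differences against double-precision reference implementations.

## Wavelength selection

* **SPA** builds a chain of minimally collinear bands: given the current
  chain, every remaining band column is projected onto the orthogonal
  complement of the chain's span and the largest residual norm wins. With
  `first_var = "auto"` all starts are tried and the chain with the lowest
  downstream least-squares RMSE is kept. The reported subset size is the
  arg-min of the cross-validated RMSE path by default; an `"elbow"`
  (maximum curvature) rule is also provided because the two conventions
  give very different sizes on real data and the literature uses both.
* **CARS** couples Monte Carlo subsampling (80% of samples per iteration,
  50 iterations, 5-fold RMSECV) with PLS coefficient magnitudes: an
  exponentially decreasing retention schedule $r_i = \lfloor a e^{-k i}
  \rceil$ pinned to $r_1 = B$ and $r_N = 2$ (enforced selection), followed
  by adaptive reweighted sampling proportional to coefficient magnitude
  (competitive selection). The retained set with minimum RMSECV wins.
  Classification responses are one-hot encoded (PLS-DA) and RMSECV is
  computed on the one-hot scale; the component count is chosen at most 10
  by inner cross-validation when not given. Coefficient ties break to the
  lower band index so runs are deterministic.

## The synthetic-data generator

The study's seed spectra are not publicly distributed, so the generator is
a first-class module that emulates their documented structure and makes
every downstream stage testable:

* the class-mean template is a logistic rise centred at 650 nm with width
  60 nm from a baseline of 0.1 to a plateau of 0.65, reproducing low
  reflectance over 380–550 nm, the rapid rise over 550–750 nm and the
  750–900 nm plateau;
* class identity lives in Gaussian bumps (widths 15–30 nm) confined to the
  discriminative windows 600–750 nm and 900–1018 nm, scaled by
  `class_separation`;
* within-variety variability is a smooth random cubic-spline curve over 8
  knots (amplitude about 0.02) plus i.i.d. per-band noise (default sd
  0.01), clipped to $[0, 1]$;
* the `"long_range"` mode draws the visible-range and NIR bump centres
  from small shared pools so that neither window alone identifies a class
  — only the pair does. This plants a genuine long-range spectral
  dependency for the state-space ablation comparison;
* scenes encode reflectance back to 12-bit-like raw counts
  (`raw = dark + reflectance (white − dark)`, dark ≈ 100 DN, white ≈ 3500
  DN) with Gaussian sensor noise on all three rasters, so calibration is
  exercised non-trivially; blobs sit on a cell grid with a safety margin,
  which guarantees disjoint ground-truth masks.

The default `class_separation = 1.4` was fixed once by the design rule
that a nearest-centroid oracle should reach roughly 95% test accuracy —
the regime in which the published per-class recalls (mostly 95–100%)
live — and is not revisited. No quantitative within/between-class variance
is documented for the real seeds, so these defaults are stand-ins, all
exposed in `synth_config()`.

What passing tests on this generator do show: the pipeline's algebra,
determinism, and the relative behaviour of the models under controlled
class structure. What they do not show: performance on real instrument
data, whose scattering artefacts, moisture effects, wavelength-dependent
sensor noise and embryo-side geometry the generator does not model.

## Numerical choices and degenerate inputs

* Savitzky–Golay with a three-point window: degree 2 reproduces any input
  exactly (a quadratic through three points), so the three-point smoother
  is implemented as the degree-1 kernel $(1/3, 1/3, 1/3)$ — the only
  choice that smooths at that window. Edges use the boundary polynomial
  fit (the first/last rows of the projection matrix).
* Split sizes are `round(test_fraction * n_c)` per class; classes with one
  sample are an error.
* Bands with zero training variance pass through standardization centred
  but unscaled, with a note.
* LDA shrinks the within-class scatter towards a scaled identity (1% by
  default) and falls back to an explicit ridge if it is still singular.
* Calibration refuses references with non-positive white-minus-dark pixels
  rather than emitting NaNs.
* Reported percentages round half away from zero to two decimals, the
  convention of the results tables the metrics mirror.
* Component labelling is 4-connected with a 50-pixel minimum area;
  touching seeds merge (documented behaviour, surfaced by a count
  mismatch).

## Scaled benchmark protocol

The acceptance benchmark trains the full-size architecture (320 bands,
channels 64/128/256, two Mamba blocks) on the full 3000-spectrum synthetic
set with the long-range class structure, using batch size 128 and at most
4 epochs per run with the plateau/early-stopping rules active, three seeds
per model. These sizes are the package's own scaled protocol: the network
reaches its accuracy plateau on this data within 2–4 epochs, and three
seeds suffice for the mean-accuracy comparison between the full network
and its no-Mamba ablation. `scripts/acceptance.R` re-runs one seed of the
same protocol plus the selection and projection stages and writes every
computed quantity as JSON.

## Known limitations

* The generator's class structure is idealised; absolute accuracies on it
  say nothing about instrument data (the study's own dataset is available
  only on request and is deliberately not required).
* BIP interleave, geometric/smile correction and non-rectangular ROI
  statistics are out of scope; manual embryo-side ROI selection is
  replaced by automatic segmentation, and externally drawn ROI files can
  be supplied instead (`read_rois()`).
* The LSTM baseline backpropagates through all 320 steps in R and is the
  slowest model at full scale; it is practical at reduced sizes.
* The selective scan is sequential (linear in sequence length); at
  $L = 40$ this is fast, but the implementation makes no attempt at the
  parallel-scan kernels used on GPUs.
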