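---
title: "Methods: synthetic NIR seed scenes and the discrimination pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic NIR seed scenes and the discrimination pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hyperseed` discriminates gene-edited rice seeds from their wild-type
acceptor lines using near-infrared hyperspectral images. This vignette is
the package's methodological record: the statistical model behind the
synthetic scene generator, the assumptions and tunable parameters of each
pipeline stage, the numerical conventions adopted where the underlying
procedures are conventionally under-specified, and what validation on
synthetic data does and does not establish.

## 1. Why a synthetic generator

Seed image archives from NIR line-scan instruments are rarely deposited,
and the phenotype of interest here — a *TGW6* knockout that slightly
enlarges the grain and raises its NIR reflectance without changing its
visual appearance — is subtle enough that every pipeline stage needs
quantitative tests. The generator is therefore a first-class module, not
a test fixture: it emits raw-count hypercubes with dark/white reference
frames whose calibration, segmentation and classification behaviour is
known by construction, so each stage can be validated against planted
ground truth.

## 2. The scene model

A scene (`scene_spec()` + `generate_scene()`) consists of:

* **Wavelength grid.** 256 uniformly spaced channels over
  874.41–1733.91 nm. Line-scan spectrographs in this range commonly
  report a channel count and end points rather than exact band centres;
  a uniform grid is the simplest internally consistent choice, and all
  band look-ups are nearest-neighbour so small grid misalignments are
  benign. Analyses restrict to 975–1646 nm because the synthetic sensor
  (like its physical counterparts) is noisier outside that window
  (`edge_noise_gain`, default 4).
* **Base spectrum.** A deterministic curve: flat 0.45 baseline plus
  three Gaussian features — a reflectance peak at 1122.81 nm
  (amplitude +0.12, width 30 nm) and valleys at 1200.19 nm (−0.09,
  22 nm) and 1483.46 nm (−0.13, 45 nm). These positions reproduce the
  peak/valley structure typical of unshelled rice in the NIR (C–H
  second-overtone bands near 1122/1200 nm, an N–H first-overtone band
  near 1483 nm). Amplitudes are tunable; setting them to zero yields a
  featureless baseline, which several tests exploit.
* **Seed geometry.** Each seed is a filled ellipse, rotated uniformly on
  `[0, pi)`. Major/minor axis lengths are drawn per class from truncated
  normals (±3 SD, floored at 1 px) with defaults taken from published
  per-class morphometry of the two rice varieties: for huaidao-1,
  wild-type length 11.20 ± 0.61 px vs mutant 11.76 ± 0.62 px, widths
  5.65 ± 0.44 vs 5.73 ± 0.37 px (`seed_shape_defaults()`). Planted area
  and perimeter are *derived* analytically from the ellipse rather than
  sampled independently — the four shape features are not geometrically
  independent, and sampling axes preserves the reported direction of the
  class effect (mutants larger in area, perimeter and length; width
  essentially unchanged). Seeds are placed on a shuffled, jittered grid
  whose cell size exceeds the largest seed, which guarantees
  disjointness; an image too small for the requested count raises a
  placement error.
* **Class contrast.** The mutant class multiplies reflectance by
  `class_offset` (default 1.02), across the whole spectrum — matching
  the observation that such mutants reflect uniformly more throughout
  the NIR, rather than in one band. `offset_windows` optionally confines
  the offset to given wavelength intervals, which is how tests plant
  *known* discriminative bands and ask whether selection recovers them.
* **Noise.** Two components: a per-seed multiplicative scatter factor
  `N(1, scatter_sd)` (default SD 0.006) shared by all of a seed's
  pixels, and additive per-pixel, per-band Gaussian noise
  (`noise_sd`, default 0.01 reflectance units, inflated by
  `edge_noise_gain` outside 975–1646 nm).
* **References and raw counts.** Dark and white references are
  single-scanline frames (columns × bands) at levels 100 and 4000
  counts with mild fixed-pattern noise, broadcast across image rows —
  the push-broom convention, where one reference line corrects every
  scanned line. Raw counts are
  `raw = dark + (white − dark) × reflectance + noise`, so calibration
  is exactly invertible when noise is off.

**Choice of the default contrast.** With a flat multiplicative offset
`delta = class_offset − 1` and per-seed scatter SD `s`, the seed-level
class separation is essentially one-dimensional (overall level), and the
Bayes-optimal accuracy is `pnorm(delta / (2 s))`. The defaults
(`delta = 0.02`, `s = 0.006`) put that at ≈ 95%, a realistic working
point for this application: hard enough that classifier and
band-selection quality matter, easy enough that a correct pipeline
should exceed 85% held-out accuracy routinely. Per-pixel noise barely
moves this figure because ROI averaging over a ~60-px seed and 199 bands
suppresses it.

`generate_spectral_dataset()` bypasses imaging and emits labelled
spectra directly (`base × offset × scatter + noise/sqrt(pixels)`), with
the additive term attenuated by the mean planted seed area so its rows
are statistically exchangeable with image-extracted ones. It exists
because classifier-level tests do not need the imaging stages and run an
order of magnitude faster.

What the generator does **not** emulate: within-seed spectral texture
(germ vs endosperm), touching or overlapping seeds, specular highlights,
spatial illumination gradients, smile/keystone distortion, and any
nonuniform instrument wavelength grid. Passing tests on synthetic scenes
therefore demonstrate the correctness of the algorithms under the stated
statistical model, not robustness to every artefact of real instruments.

## 3. Calibration and I/O

`calibrate()` applies `(raw − dark) / (white − dark)` elementwise.
References may be full cubes or single-row frames. Denominator entries
with `|white − dark| <= epsilon` (default `1e-6` × median white level)
carry no dynamic range; the default policy sets those outputs to `NA`
with a warning (`on_bad_pixel = "error"` aborts instead), and the count
is attached to the result. Spectral cropping uses a closed interval.
Cubes are stored as ENVI band-sequential float32 rasters with an ASCII
header carrying the wavelength list (round-trip precision 1e-4 nm);
BIL/BIP interleaves are read but not written.

## 4. Segmentation and morphometry

The segmentation band defaults to the one nearest 1139.26 nm, a
wavelength with good seed/background contrast in this range; ties
between equidistant bands resolve to the lower wavelength.
Thresholding is Otsu's method (no threshold tuning), components are
8-connected, and objects under `min_area = 10` px are discarded as
specks. Border-touching objects are kept but flagged. Touching seeds
merge into one object — a documented failure mode (no watershed
splitting is attempted), covered by a stress test.

Morphometry conventions, where several definitions circulate:

* **Area** counts all object pixels, contour included.
* **Perimeter** counts object pixels with at least one 4-adjacent
  background pixel (image borders count as background). The 4-adjacency
  contour is a convention choice; an 8-adjacency contour would give
  slightly smaller counts on diagonal edges.
* **Length/width** are the full major/minor axis lengths of the ellipse
  with the same second central moments as the blob, each pixel
  contributing its own unit-square variance (1/12). This estimator
  recovers planted ellipse axes to well under 2 px at these seed sizes
  and makes `width > 0` even for 1-px-thin objects.

Thousand-grain weight follows the standard protocol: TGW = 10 × the
mean of independent 100-seed sample masses, and trait gains are reported
as percent increase over the wild type, rounded half-up to one decimal.

## 5. Spectral extraction and denoising

Per-seed spectra are ROI means (object-wise averaging), computed after
cropping to 975–1646 nm and then denoised — denoising after cropping
keeps the noisy sensor edges from leaking into the wavelet coefficients.
The transform is a level-3 Daubechies-8 (16-tap) DWT, implemented
in-package with symmetric (edge-repeating) boundary extension. The
wavelet and depth are the field's common choice for NIR spectra of this
length; the thresholding rule — soft thresholding at the universal
threshold `sigma * sqrt(2 log n)`, with `sigma` estimated from the
finest detail coefficients via `MAD/0.6745` — is the standard default
where none is otherwise specified. Constants pass through unchanged and
smooth spectra are perturbed by well under 1% RMS, so the step is
conservative. Spectra must be at least 15 samples long (the filter
support); shorter inputs are rejected with the minimum named.

## 6. Kennard–Stone partitioning

`kennard_stone()` implements the classical max–min procedure on
Euclidean distances of the (preprocessed, unscaled) spectra: seed with
the farthest pair, then repeatedly add the sample farthest from the
selected set. All ties resolve to the lowest row index, making the split
a pure function of the data. The calibration size from a `cal:pred`
ratio is `round(n · r/(r+s))` with half-up rounding, so 660 seeds at 2:1
give exactly 440/220. The greedy construction makes selections nested in
`n_cal`, a property the tests assert. The split is computed on denoised
spectra, consistent with the pipeline order (denoise before partition).

## 7. PCA

`fit_pca()` is column-mean-centred PCA (no autoscaling — reflectance
bands share units and comparable variances) via SVD. Explained
percentages are eigenvalue shares of the total variance over *all*
components, so they sum to 100. Loadings are sign-fixed (largest element
positive) purely for reproducibility of loading-peak picking; scores are
flipped consistently. Constant matrices are rejected as degenerate.

## 8. Wavelength selection

**SPA.** `spa_chain()` is the projection recursion: starting from a
given band, repeatedly append the band whose component orthogonal to the
span of the chosen ones is largest (ties to the lowest index; chains are
built on mean-centred calibration spectra). `spa_select()` wraps it in
the standard model-selection loop: every start band × every subset size
up to `max_vars` (default 15, spanning the 8–12-band selections typical
of this application), each scored by the RMSE of an ordinary
least-squares fit of the numeric labels (1/2) evaluated on a validation
set; ties prefer fewer bands, then the lower start. Rank-deficient
designs fall back to a fixed `1e-8` ridge. The validation set is an
inner Kennard–Stone 2:1 sub-split of the calibration set — the final
prediction set is never consulted during selection, so reported
prediction accuracies are honestly out of sample.

With the default flat class offset every band carries the same class
signal, and SPA correctly concludes that very few bands (often one)
suffice — minimal redundancy is its design goal. Recovery of *specific*
planted bands is therefore tested with `offset_windows`, where SPA
reliably selects bands inside (within one grid step of) most planted
windows; exact one-to-one recovery of all planted bands is not expected
from a minimal-redundancy selector when the planted bands are mutually
correlated.

**PCA loadings.** `loading_peaks()` picks strict local maxima and minima
of the first `n_components = 3` loading curves whose topographic
prominence reaches 5% of the curve's range (both defaults tunable),
merges near-duplicates within one band, and pools across components.
On noisy low-variance components this admits many extrema; that
matches the observation that loading-based selections tend to be larger
and less discriminative than SPA's.

## 9. Classifiers

**SVM.** RBF-kernel C-SVM over a log2 grid, `c` in `2^-2..2^10` and `g`
in `2^-6..2^6`, scored by stratified 5-fold cross-validation on the
calibration set; ties prefer smaller `c`, then smaller `g`. Features are
used unscaled (reflectances are already commensurate; the wide `g` grid
absorbs the overall scale). Fold assignment is the only stochastic
element and derives from the function's `seed` argument.

**ELM.** Input weights and biases drawn once from `U(−1, 1)` and frozen;
logistic-sigmoid hidden layer; output weights (plus an output bias
column) solved by Moore–Penrose least squares against one-hot targets.
Inputs are min–max scaled to [0, 1] per band with calibration-set
ranges, as bounded inputs are assumed by the sigmoid convention. The
hidden-layer size is selected over 1–80 nodes on an inner Kennard–Stone
2:1 sub-split, ties to the smaller network. The output bias is a
deliberate (and common) extension of the minimal formulation: without
it, a network reduced to a single always-positive sigmoid feature
cannot place a decision threshold at all. Weights regenerate
deterministically from the seed, so retraining reproduces the model
bit for bit.

**Evaluation.** Accuracies are `100 × correct/total` per set, with 2 × 2
confusion tables; reports print to two decimals but store full
precision. `tidy()`/`glance()` expose them as tibbles.

## 10. Prediction maps

`predict_map()` is object-wise: one mean-spectrum prediction per seed,
painted over all its pixels — the mode that matches how such maps are
actually computed (a per-pixel diagnostic would classify individual
pixel spectra, which are far noisier than ROI means and are not what
the per-seed accuracy figures describe). The map replays exactly the
training preprocessing (crop, denoise, band restriction), so a seed's
map label provably equals the classifier's prediction on its dataset
row — there is no separate "visualization model". Rendering is a pure
function of the inputs; colours default to olive (wild type) and orange
(mutant) and the colour table must cover every predicted class.

## 11. Problem sizes and determinism

The shipped tests validate the full imaging pipeline at the study scale
of 330 seeds per class per scene (660-seed scenes, ~470 × 470 px × 256
bands) across ten generator seeds, with classifier unit tests on smaller
direct datasets chosen to exercise the same code paths quickly. The
acceptance script reruns one full scene plus a fresh 200-seed validation
scene and a planted-band recovery study. Every stochastic component —
scene synthesis, CV folds, ELM weights — flows from explicit integer
seeds, and the tests assert byte-identical artefacts (datasets,
selections, reports, rasters) across repeated runs.

## 12. Known limitations

* Synthetic validation only: see the generator caveats in §2. In
  particular the per-seed scatter is spectrally flat, so any method
  exploiting scatter *shape* is untested here.
* Two classes per variety; multi-class scenes are out of scope.
* No watershed splitting of touching seeds and no sub-pixel boundaries.
* The wavelet threshold assumes approximately white residual noise; on
  strongly structured noise the universal threshold is conservative.
* SPA's RMSEV criterion uses the 1/2 label encoding as a numeric
  response — standard practice in this literature, but a linear probe
  rather than a calibrated classifier.
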