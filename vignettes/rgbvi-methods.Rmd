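---
title: "Estimating multispectral vegetation indices from RGB plot images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating multispectral vegetation indices from RGB plot images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgbvi)
```

## The problem

A vegetation index (VI) is a scalar transformation of multispectral
reflectance that quantifies the presence and vigour of green vegetation.
The workhorse is NDVI,

$$\mathrm{NDVI} = \frac{\mathrm{NIR} - \mathrm{Red}}{\mathrm{NIR} + \mathrm{Red}},$$

together with its relatives GNDVI, RENDVI (red-edge), SAVI (soil-adjusted)
and EVI (aerosol-corrected). All of them need a near-infrared band, which
ordinary RGB cameras do not record. Multispectral cameras that do record NIR
trade away spatial resolution and add cost, which matters for
high-throughput phenotyping of breeding trials where thousands of single-row
plots are imaged repeatedly by UAV.

`rgbvi` implements a model-based alternative: learn the mapping from an RGB
image of a plot to the plot's mean multispectral VI with a small
convolutional network, using co-registered multispectral imagery only at
training time. The premise is that the spatial density and the colour of
vegetation in the visible bands together carry most of the information the
VI summarises. The package provides the full experimental loop — a synthetic
multispectral field simulator with known ground truth, plot sampling and
radiometric calibration, the regression network, three ablation baselines,
and an evaluation harness — so the method's behaviour can be studied
end-to-end without any external imagery.

## The regression target

The target for one plot is the **mean of the per-pixel VI map** over the
plot crop (mean pooling), not the VI of the mean reflectance. The two differ
on mixed soil/vegetation pixels; the mean-of-pixels convention makes the
plot VI exactly linear in the within-plot class fractions, and it is fixed
normatively throughout the package (`vi_map()` then `plot_mean_vi()`).
Pixels whose index denominator is exactly zero are masked out of the mean
rather than mapped to zero, so bare-soil noise cannot bias plot means.
Targets are computed on the native-resolution crop, before any resizing of
the RGB image.

SAVI and EVI need constants the index literature treats as standard:
`savi_L = 0.5`, EVI `G = 2.5, c1 = 6, c2 = 7.5, L = 1`. These are exposed in
`vi_params()` and are conventions, not fitted quantities.

## The network

`net_config()` describes the architecture:

```
conv(20 maps, 5x5, same) -> maxpool(2x2) ->
conv(50 maps, 5x5, same) -> maxpool(2x2) ->
flatten -> fc(500) -> ReLU -> dropout(0.5) -> fc(1)
```

The input is a 15 × 208 × 3 standardized plot crop (single-row plots are
long and thin: roughly 4 m of row at ~2 cm ground sampling distance gives
about 200 px × 8 px, resized to the fixed network input). Same-padding on
both convolutions is structural, not a preference: with valid convolutions
the 15-pixel height would collapse to zero before the second pooling layer
(15 → 11 → 5 → 1 → 0), so this layer stack is only realizable with
padding. Pooling is non-overlapping 2 × 2 with floor division, giving the
shape trace (15, 208) → (7, 104) → (3, 52) and a flattened length of
3 · 52 · 50 = 7800.

The loss is the Euclidean regression loss with the 1/(2N) normalization
convention of the classical Caffe-lineage frameworks,
$L = \frac{1}{2N}\sum_i (\hat{y}_i - y_i)^2$.

Training (`train_config()`) is plain SGD: momentum 0.9, weight decay 5e-4,
mini-batches of 72 images drawn in shuffled order, random horizontal flips
(probability 1/2, targets unchanged — row plots are left–right symmetric),
and the inverse-decay schedule

$$\mathrm{lr}(t) = 0.01 \,(1 + 0.9\,t)^{-0.75}$$

evaluated per iteration $t$ counted from zero. Note the decay coefficient
0.9 equals the momentum coefficient; both are fixed parts of the recipe,
and the schedule therefore decays hard — by iteration 100 the rate has
fallen thirtyfold. Dropout is active only during training; prediction is a
deterministic forward pass.

Two initialization choices are ours (the recipe leaves them open):
convolution kernels are zero-mean Gaussians with sd $1/\sqrt{\text{fan-in}}$
and fc layers are Glorot-uniform; and the output neuron's bias starts at the
training-target mean. The latter matters with this schedule: the global
offset of the response is the component gradient descent moves most slowly
once the rate has decayed, and starting it at the sample mean removed a
systematic shrinkage of held-out predictions (in a pilot fold, held-out R²
rose from 0.79 to 0.92 with no other change). Epochs default to 50 per
fold, the point where the training loss has plateaued under the decayed
rate; the count is configurable and is held identical across folds.

There is no deep-learning framework dependency: the forward pass, the
backward pass and the SGD loop are implemented in the package's compiled
core (single-precision im2col + BLAS GEMM, with a self-contained
Mersenne-Twister stream so a seed reproduces training bit-for-bit on any
platform). The backward pass is verified in the test suite against
finite differences of an independent, double-precision R implementation of
the forward pass.

## The simulator

`synth_config()` + `generate_field()` emulate the layout of a wheat breeding
trial: 3 bays × 576 single-row plots × 7 growth stages by default (the
reduced layouts used in tests are noted below). Each bay is rendered as a
five-band reflectance raster (blue, green, red, red-edge, NIR) with a plot
grid in world coordinates and an affine geotransform; `encode_dn()` and
`radiometric_scale()` round-trip the rasters through 16-bit digital numbers
and calibration against a reference panel of known reflectance, as a real
pipeline would.

Within a plot, pixels are i.i.d. vegetation-vs-soil draws with the plot's
cover probability; vegetation pixels are senescent with the plot's
senescence probability. This Bernoulli mixture is the simplest model that
makes spatial density informative; it does not attempt spatially correlated
canopies, radiative transfer, or photogrammetric artifacts, so conclusions
about those aspects of real data are out of reach by construction. Sensor
noise is zero-mean Gaussian in reflectance (sd 0.01 by default), clipped to
[0, 1].

Cover rises along a logistic season curve and senescence grows toward the
terminal stage. Each plot carries a persistent random deviation from the
stage curves (germplasm differences): the deviation's sd is
$2\,j\sqrt{p(1-p)}$ for stage value $p$ and jitter scale $j$ (default 0.25),
which vanishes at $p = 0$ and $p = 1$ so degenerate all-soil and full-canopy
configurations stay exact. Without such within-stage variation the
per-stage correlation between observed and estimated VI would be undefined.

All simulator randomness derives from one seed via labelled sub-streams:
scenes are deterministic functions of `(seed, bay, stage)`, per-plot effects
of `(seed, bay)`, so any scene can be regenerated in isolation.

### Spectra presets

`vi_spectra("default")` is a generic bright-soil / dark-green-canopy /
light-straw parameterization. Under it — and under any three-class Bernoulli
mixture whose classes are linearly independent in RGB space — the plot's
mean RGB determines the class fractions exactly, so the plot VI is a
*linear* function of mean colour and a linear baseline is near-optimal.
That is the regime of the headline estimation experiment, not of the
ablations.

`vi_spectra("ablation")` is constructed so that the ablations measure what
they claim to measure:

* all three classes share the same luma (0.299 R + 0.587 G + 0.114 B), so a
  grayscale rendering of a scene is nearly featureless and any model using
  it must fail — isolating the value of *spectral* information;
* the senescent visible spectrum lies on the soil–vegetation line in RGB
  space (at 40% of the way from soil to vegetation) while its NIR does not,
  so a fully senescent canopy is an RGB *metamer* of a 40%-cover healthy
  plot with a very different VI. Mean colour alone cannot separate the two;
  within-plot spatial texture can — isolating the value of *spatial*
  information.

Both presets are fixed constants of the package, chosen from these
geometric requirements.

## Evaluation

Estimation error per sample is the relative percentage error
$(\mathrm{VI}_{obs} - \mathrm{VI}_{est})/\mathrm{VI}_{obs} \times 100$ (an
overestimate is negative); samples with zero observed VI are excluded from
the moments and counted. Per growth stage the report carries mean ± sd of
the errors, the within-stage Pearson correlation, and box statistics
(type-7 quartiles, whiskers at the most extreme points within
$[q_1 - 1.5\,\mathrm{IQR},\, q_3 + 1.5\,\mathrm{IQR}]$). Pooled over stages,
estimated VI is regressed on observed VI by robust least squares:
iteratively reweighted with Tukey bisquare weights (tuning constant 4.685,
residual scale MAD/0.6745), iterated to a 1e-8 parameter tolerance or 50
iterations. When the residual scale is zero (exact fit) or no residual
exceeds the bisquare threshold, the fit coincides with OLS; R², RMSE and r
are reported against the robust line on all points, not refit by OLS.
Correlations are pooled across folds within a stage (per-fold-then-average
is the other defensible convention; pooling is what the report format
uses, and it is documented here once).

Validation designs: leave-one-bay-out (three folds; each fold trains on two
spatially distinct bays) for the main model and the spectral/spatial
ablations, and leave-one-stage-out for the temporal ablation. On the full
trial layout these give the bookkeeping counts 12096 total observations,
8064/4032 train/test per bay fold, and 10368/1728 per temporal split, with
72 ground-reference plots (2 survey lines × 12 plots × 3 bays) selected by
`ground_reference_plots()`.

## The ablation experiments

* **DNN-GRAY** (spectral): identical architecture with `in_channels = 1` on
  luma-converted images. Under the ablation preset its held-out RMSE should
  be at least ~1.5× the RGB model's — grayscale scenes there carry almost no
  class signal.
* **LR-RGB** (spatial): ordinary least squares of the VI on the three
  channel means of each plot ("spatially diminished" 1 × 1 × 3 images).
  Under the ablation preset the senescent metamerism makes VI a non-linear,
  non-unique function of mean colour once senescent stages are present, so
  LR-RGB should trail the network.
* **DNN-T** (temporal): the RGB network trained with one growth stage
  withheld and tested on it. Interpolating an interior stage works from
  neighbouring stages; extrapolating the terminal senescent stage — whose
  VI distribution the training set never saw — produces the largest mean
  signed error, the qualitative signature of temporal blindness.

## Problem sizes used by tests and the acceptance script

The full trial configuration (1728 plots × 7 stages, three bay folds,
network training per fold) is far beyond a desk-scale check. The suite
therefore runs scaled-down analogues, chosen once:

* estimation check: 3 bays × 64 plots × 7 stages (1344 samples), default
  spectra, noise sd 0.01, one bay fold, 50 epochs — held-out R² ≥ 0.9 and
  RMSE ≤ 0.05 are the pass conditions;
* ablation check: 3 bays × 32 plots × 7 stages (672 samples), ablation
  spectra, one bay fold per model, 30 epochs; DNN-T is trained on the three
  representative hold-outs {stage 2, stage 4, stage 7 (terminal)} rather
  than all seven;
* bookkeeping counts run on the full 3 × 576 × 7 metadata (no rasters are
  rendered for counting).

These synthetic analogues test the machinery and the ordering of the
ablations. They are not estimates of what the method achieves on real
field imagery, which depends on data this package does not ship.

## Numerical choices and degenerate inputs

* Rectangles rasterize to half-open pixel ranges `[floor(min), floor(max))`
  in 0-based continuous pixel coordinates — no boundary pixel is counted
  twice when rectangles tile.
* Resizing uses exact area-overlap averaging when an axis shrinks
  (radiometry-preserving: channel means are invariant to integer-factor
  downscales) and bilinear interpolation of pixel centres when it grows.
* Plots that fall outside the raster are skipped and reported, not fatal;
  empty stage groups are reported as missing.
* Max-pooling ties resolve to the first candidate in column order;
  deterministic but arbitrary, like every framework's.
* The digital-number gain is restricted to (0.5, 1] so quantization error
  stays below 1/dn_max after calibration.
* `robust_linefit()` refuses constant x; `vi_lm()` refuses rank-deficient
  designs and names the collinear channels.

## Limitations

The simulator's independence assumptions (pixel-level Bernoulli, Gaussian
band noise, global illumination) make its scenes easier than real
orthomosaics: no shadows, no registration error, no stitching seams, no
view-angle effects. A model that passes every check here can still fail on
real imagery; what the checks do establish is that the training loop
optimizes the stated loss, that the evaluation arithmetic is exact, and that
the spectral/spatial/temporal ablations order the models the way the
method's premise predicts whenever the scene geometry puts the information
where the premise says it is.
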