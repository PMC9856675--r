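---
title: "Decoding speech-categorization speed from EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding speech-categorization speed from EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Listeners categorize speech sounds with response times (RTs) that vary from
trial to trial. `rtdecoder` implements a decoding chain that asks which scalp
regions and which oscillatory bands carry information about whether an
upcoming behavioral response will be fast, medium or slow. The chain is:

1. partition the RT distribution into fast / medium / slow / outlier groups
   with a Gaussian mixture model selected by BIC;
2. augment the per-subject, per-category trial pools into many
   low-noise event-related potentials (ERPs) by controlled bootstrap
   averaging, and discard augmented samples whose PCA reconstruction error is
   atypical;
3. summarize each ERP as an RGB image of alpha/beta/gamma band power over
   the scalp;
4. train a convolutional network to classify the images into RT categories
   (with a tree-structured Parzen estimator available for hyperparameter
   search);
5. quantify what the network learned with Guided-GradCAM saliency,
   reduced to one activation value per (sample, electrode, band);
6. test the activation table with a factorial mixed-model ANOVA
   (electrode x band x category), Tukey posthoc contrasts, and a
   GMM-based high/relevant/low ranking of electrodes.

Because the underlying EEG corpus is not publicly distributable, the package
ships a synthetic-data generator that emulates preprocessed epoched EEG with
a planted, known spatial-spectral ground truth. Every stage is tested
against that ground truth.

# RT clustering

RTs are one-dimensional, so each mixture component is a univariate normal.
The selection grid crosses component counts (1-8 by default) with the four
conventional covariance labels; in one dimension spherical, diagonal and
full all mean "one variance per component" while tied shares a single
variance. All four labels are scored, so the grid mirrors the usual
multivariate sweep, and the model with the lowest
`BIC = p log(n) - 2 logLik` wins; ties break toward fewer components, then
spherical < diagonal < tied < full. EM uses 10 random restarts per
candidate (initial means drawn from the data, best log-likelihood kept)
with a variance floor of `1e-6 * var(x)` to avoid degenerate spikes.

The component-to-category map designates as *outlier* the smallest-weight
component among those whose mean exceeds the grand median — the
low-probability slow tail. The remaining components map to fast / medium /
slow by ascending mean. Outlier trials are excluded *before* augmentation:
pooling them into the slow category would inflate the very tail the
clustering isolates.

# Bootstrap augmentation

Within each (subject, category) pool, each iteration draws `r` distinct
trials without replacement and emits their average. Every `n_alpha`
iterations, `m = max(1, round(r * alpha_category))` of the most recently
drawn trials are permanently dropped, so later ERPs cannot keep reusing the
same trials — the dropout bounds the overlap between emitted samples.
Two boundary rules needed a decision:

* **Terminal pools.** When a pool shrinks to `r` or fewer trials the
  pseudocode would emit the mean of the remaining trials at every further
  iteration, duplicating one sample up to the iteration cap. Duplication
  contradicts the algorithm's anti-bias purpose, so the pool emits that
  terminal mean once and stops. The closed-form sample count
  (`expected_sample_count()`) and the event-level simulation oracle in the
  tests agree under this rule.
* **Rounding.** The drop count is `round(r * alpha)` with a minimum of 1,
  since a fractional prescription must still remove something.

With the study-scale defaults (`r = 50`, `alpha` = 0.3/0.2/0.1 for
fast/medium/slow, `n = 1500`, `n_alpha = 10`), `r` is about 5-6 % of a
~900-trial subject pool. For the 300-trial-per-subject synthetic cohort
used in the tests the same proportion gives `r = 15`, with `n = 60`
iterations per pool — the sizes are the package's choice of a cohort that
exercises every stage at desk scale.

# Eigenspace filtering

Augmented ERPs are flattened (channels x time), centered on the raw-trial
mean, and measured by their Euclidean residual from the span of the top-k
principal axes of the raw trials. Samples below the 25th or above the 75th
percentile of the residual distribution are discarded: the low tail is
near-duplicate, biased structure; the high tail is noise-dominated. Three
numerical choices:

* The PCA uses the Gram-matrix route (`n x n` eigendecomposition with the
  centering applied through inner-product identities), since the flattened
  dimension is far larger than the trial count; no centered copy of the
  large matrices is ever materialized.
* "Reconstruct with all components" would put every sample inside the raw
  span and make all residuals zero; a truncated basis is required for the
  error distribution to exist. The default keeps the smallest basis
  explaining 95 % of raw variance; an explicit component count can be
  passed instead (the chain tests use `k = 150`, which keeps the filter
  O(seconds) at desk scale).
* Percentiles are computed on the pooled residual distribution; a
  per-category option exists. Inclusive bounds with stable order make the
  50 % retention exact for continuous residuals.

# Spatial-spectral images

Band powers integrate a Welch power spectral density (Hann window, segment
length `min(256, epoch)` samples, 50 % overlap — unstated upstream, chosen
as the common default) over alpha 9-13, beta 14-30 and gamma 31-60 Hz via
the trapezoid rule, across the full epoch. The 3-D montage is projected by
an azimuthal equidistant projection about the vertex; each band plane is
min-max normalized per image, interpolated with an exact thin-plate spline
over the head disk (spline interpolation reproduces electrode values
exactly, which the electrode-pixel consistency tests rely on), clipped to
[0, 1], zeroed outside the head mask, and stacked Red = alpha,
Green = beta, Blue = gamma on a 32 x 32 grid. Anterior is row 1; columns
run subject-left to right. The representation is deliberately
time-collapsed: spectral content over the whole epoch, no temporal axis.

Two resolution-driven choices deserve a note. The head-disk radius is 1.06
times the outermost electrode's projected radius: at 32 pixels a tighter
rim leaves the inferior electrodes (CB1/CB2) less than half a pixel inside
the mask, so their nearest pixel can fall outside the disk and be zeroed.
And agreement between an electrode's normalized power and its nearest
pixel is gradient-limited — the nearest pixel sits up to ~0.7 px away, and
adjacent 10-10 electrodes project only 1.3-3 px apart at this resolution —
so the documented 0.05 agreement holds for smooth, dipole-like scalp
fields; per-electrode fields with large neighbor contrast need a finer
grid for the same fidelity.

# The decoder

`build_decoder()` assembles `[5x5 convolution (ELU) -> inception-style
reduction] x n_blocks`, flatten, fully connected layers with dropout, and a
3-unit softmax head. A reduction block runs three stride-2 branches in
parallel — a 3x3 convolution, a 1x1 then 3x3 convolution, and a 3x3
max-pool — concatenated on channels, each convolutional branch carrying
`ceiling(filters / 3)` channels; spatial size halves with ceiling
semantics. The reference configuration (52/104/156/208 filters, FC
713/1019, dropout 0.47, Adagrad at 0.006, 165 epochs, 25 % validation
split) is the package default; tests and the demo pipeline use compact
configurations of the same shape.

Training is categorical cross-entropy with minibatches, a stratified
validation split, best-validation-loss checkpointing (weights restored on
return), and learning-rate halving after 5 plateau epochs (floor `1e-5`).
Batch size defaults to 64. Everything is seeded: two runs with the same
seed produce identical histories. The engine is plain R: convolutions are
im2col gathers followed by BLAS matrix products, and all gradients are
analytic backprop (verified against finite differences in the tests).

The TPE search maximizes validation accuracy over a space of depth 2-4,
per-block filters 16-256 (log-uniform), FC width 64-1024, dropout 0.2-0.6,
learning rate 1e-4 to 1e-1 (log-uniform) and optimizer
{Adagrad, Adam, SGD}. Good/bad trial densities split at the 0.25 quantile,
20 candidate draws per proposal, kernel bandwidths from Silverman's rule
with a floor of 1/20 of the search span (the floor keeps late-stage
proposals exploratory). The documented default budget is 73 trials.

# Saliency quantification

GradCAM weights are spatial means of the target-class logit gradient at the
last spatial feature map (the standard "last convolutional layer" choice);
the rectified weighted channel sum is bilinearly upsampled to input size.
Guided backpropagation applies the guided rectifier rule at every ELU:
gradients pass only where the forward activation and the incoming gradient
are both positive (for strictly positive activations and gradients this
reduces exactly to the plain input gradient, which is how the
finite-difference tests pin it down). Guided-GradCAM is their elementwise
product, per input band plane.

The per-sample target class is the *predicted* class, matching how the maps
are read downstream ("predicted RT groups"); a true-class option exists.
Activations are `mean(|guided_gradcam|)` over the 3x3 pixel neighborhood
centered on each electrode's pixel (zero-padded at edges, so always a
sum/9). The absolute value reflects that downstream statistics operate on
non-negative activation magnitudes; the 3x3 mean is this package's declared
convention for reducing a pixel map to an electrode value.

# Statistics

The factorial model is `activation ~ electrode * band * category` with
sum-to-zero contrasts and type III tests. The default random-effects
structure is a random intercept per sample (each sample contributes 192
correlated rows; category then tests between samples, visible in its much
smaller denominator df); a per-subject option and a fixed-effects-only
fallback exist. Tukey HSD contrasts adjust over the within-cell family of
three category pairs, matching the per-electrode contrast triples in the
reporting style. The electrode ranking averages activations per electrode
within each (band, category), fits a 3-component univariate mixture, and
names tiers low / relevant / high by ascending component mean.

# The synthetic generator

Each trial is 1/f-spectrum background noise (10 µV RMS per channel) plus
stimulus-locked oscillatory bursts at the band centre frequencies,
Hann-gated to the post-stimulus interval, with small phase jitter
(sd 0.5 rad) so trial averaging behaves like evoked averaging. RTs come
from a four-component truncated-normal mixture — fast N(340, 70), medium
N(640, 65), slow N(1030, 140), outlier N(1800, 250), weights
.55/.27/.12/.06 on [100, 2500] ms — chosen so the MAP cluster ranges land
in the study's printed spans (about 100-504 / 506-770 / 772-1360 ms) with
the fast-majority imbalance. The sampling rate defaults to 500 Hz (the
source recordings' rate is not stated anywhere; 500 Hz is a common choice
that keeps the gamma band well inside Nyquist).

The planted effects are multiplicative amplitude factors per (electrode,
band, category). The default layout gives every category one localized
focus per band of comparable strength — left-frontal alpha (FT7/FC5/FC3)
scaled 3.0/1.5/0.75 across fast/medium/slow, a medium alpha focus at CP1
and a slow occipital alpha focus; a fast left-central beta focus (C5/C1), a
medium right-prefrontal beta focus (AF4/F2) and a slow right-cerebellar
beta focus (CB2). The balance is deliberate: per-image min-max
normalization means a category whose plane contains one uniquely bright
electrode has its *background* compressed relative to categories without
one, and an unbalanced design lets a classifier decode that global
brightness artifact instead of the planted locations. With one comparable
focus per band per category, where power concentrates is the only
decodable signal, and saliency must point at the planted sites.

What the generator does *not* emulate: volume conduction from realistic
sources, ocular/muscle artifacts, inter-subject anatomical variability,
non-stationary background spectra. Passing tests therefore show the chain
recovers structure of the planted kind; they do not certify performance on
recorded EEG.

# Problem sizes used by the test suite

The recovery test runs the full chain on 12 subjects x 300 trials (3,600
epochs at 64 channels x 500 samples), bootstrap `r = 15`, `n = 60` per
pool (~2,100 augmented ERPs, ~1,050 after filtering), a 2-block decoder
(8/16 filters, FC 32) trained 20 epochs on an 80/20 split, saliency on the
held-out fifth, and the mixed-model ANOVA on the resulting ~40,000-row
activation table. These sizes are the package's desk-scale rendition of the
study conditions: large enough for the planted three-way structure to be
unambiguous, small enough to run routinely. Unit tests use much smaller
fixtures throughout.

# Known limitations

* The decoder engine is CPU-only and favors clarity over speed; it is not
  intended for large production-scale image corpora.
* Guided backpropagation is defined for rectifier-family activations; for
  activations without a guided rule the implementation falls back to the
  plain gradient with a warning.
* The eigenspace filter assumes the raw-trial matrix fits in memory; very
  large cohorts would need a streaming Gram accumulation.
* The three-way ANOVA with 576 fixed-effect cells and a per-sample random
  intercept takes minutes on large activation tables; the fixed-effects
  path is orders of magnitude faster and is what the null-calibration
  study uses.
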