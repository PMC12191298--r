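---
title: "Multi-domain feature fusion for ECG myocardial-infarction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-domain feature fusion for ECG myocardial-infarction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgmff)
```

## The problem and the model

Myocardial infarction (MI) leaves characteristic marks on the 12-lead ECG:
ST-segment shifts, T-wave inversion and pathological Q waves, distributed
over lead subsets that depend on the infarct region. A classifier working
only on the raw time-domain trace sees single-point amplitude information;
spectral and time-frequency descriptions of the same beat carry
complementary evidence. `ecgmff` implements a three-branch fused
convolutional classifier over three views of each heartbeat:

* **time domain** — the segmented 12-lead beat itself, a 12 x 651 matrix at
  1000 Hz (250 samples before the R peak, the R sample, 400 after);
* **frequency domain** — the one-sided DFT magnitude spectrum of the lead-II
  beat, smoothed by piecewise aggregation approximation (PAA), min-max
  rescaled to [-1, 1] and encoded as a Gramian Angular Field (GAF),
  `G[i,j] = sin(phi_i - phi_j)` with `phi = arccos` of the rescaled series —
  a square image whose pixels encode pairwise spectral phase relations;
* **time-frequency domain** — the discrete Stockwell (S-) transform of the
  lead-II beat, a frequency-scaled-Gaussian-window spectrogram restricted to
  the 0-45 Hz diagnostic band and rendered as a magnitude image.

The time-domain branch is a 1D SE-ResNet18: first convolution of kernel 15
with 64 filters and stride 2, four stages of widths 64/128/256/512 with two
residual blocks each (kernel 7), a squeeze-and-excitation block in every
residual block (per-stage reductions 4/8/16/32) and dropout 0.2 between each
block's convolutions and after the global pooling. The two image branches
are plain 2D ResNet18 trunks (7x7 then 3x3 kernels) over single-channel
inputs. Each branch ends in global average pooling; the three 512-wide
feature vectors are concatenated and a fully connected layer plus softmax
produces class probabilities. Training uses cross-entropy, SGD with learning
rate 0.001 and momentum 0.9, batch size 64 and 60 epochs.

Two tasks share this architecture: *detection* (healthy vs MI, 2 outputs)
and *localization* (infarct region, 10-12 outputs). Metrics are accuracy,
sensitivity, precision, specificity and F1 per class (one-vs-rest,
macro-averaged for multi-class tasks) and the overall accuracy `AccT`, the
summed per-class true positives over all evaluated beats.

## Preprocessing

Raw records pass through four stages.

1. **Baseline removal.** A two-stage running-median cascade estimates the
   baseline per lead and is subtracted. The window lengths are not dictated
   by the method itself; we use the standard two-scale practice of a 200 ms
   window (spanning the P-QRS complex) followed by 600 ms (spanning the T
   wave), both configurable.
2. **Wavelet denoising.** Each lead is decomposed to 5 levels with the db6
   wavelet (its morphology resembles the QRS complex). For detail level `b`
   the noise scale is `sigma_b = median(|d_b|) / 0.6745` (0.6745 is the 75%
   point of the standard normal, making the estimator consistent for
   Gaussian noise), and the level threshold is
   `TE_b = sigma_b * sqrt(2 * log(||d_b||) / log(b + 1))`, `||d_b||` the
   Euclidean norm of the level's detail coefficients and logarithms natural.
   Coefficients at or below `TE_b` in magnitude are zeroed; those above are
   shrunk by `TE_b` with their sign preserved. We apply the rule to the
   coefficient magnitudes (a literal reading of the condition on the signed
   coefficient would zero every negative coefficient, contradicting the sign
   factor in the shrinkage branch), threshold detail coefficients only, and
   clamp the radicand at zero so `TE_b >= 0` when a level norm falls below
   one. The transform is a periodized orthogonal DWT implemented in the
   package; its analysis convention matches the common periodization layout
   and reconstruction is exact to machine precision.
3. **R-peak detection.** The classic Pan-Tompkins chain — 5-15 Hz band-pass,
   five-point differentiation, squaring, 150 ms moving-window integration,
   adaptive dual thresholds with search-back and a 200 ms refractory period.
   Filtering is applied zero-phase so detected indices need no lag
   correction; each index is refined to the local extremum of the band-passed
   signal within +/-50 ms. Detection runs on lead II (the lead the imaging
   path uses); indices are shared across all 12 leads.
4. **Segmentation.** A fixed [R-250, R+400] window at 1000 Hz (651 samples);
   records at other rates are polyphase-resampled first. Beats whose window
   crosses a record boundary are dropped rather than padded — padding would
   fabricate signal.

## Imaging choices

The spectrum fed to the GAF is the one-sided DFT *magnitude* (not power or
log-magnitude; the source method leaves this open and magnitude is the most
direct reading of "spectrum"), with the DC bin retained. The GAF is the
difference-field variant (sine of pairwise angular differences) exactly as
the closed matrix form prescribes; its diagonal is identically zero, it is
antisymmetric, and all entries lie in [-1, 1]. The polar radius `r_i = t_i/N`
is computed and attached but does not enter the matrix — it is part of the
polar encoding, not of `G`. Image side length defaults to 224 via PAA (the
source never states image dimensions) and is configurable; the test suite
and the acceptance run use 16 so that a full training run fits in minutes.

The discrete S-transform is computed in the spectral domain: for frequency
bin `k > 0` the voice is the inverse DFT over `m` of
`X[k+m] * exp(-2 pi^2 m^2 / k^2)`. This form satisfies, exactly, the
marginal identity that summing the transform over time returns the DFT
coefficient at each positive frequency — the property the test suite asserts
at 1e-8. At `f = 0` the analysis window degenerates; that row is set to the
signal mean, the standard discrete-ST convention. For imaging the magnitude
is restricted to (0, 45] Hz, resized by exact area interpolation and scaled
to [0, 1]. Images feed the networks as single-channel matrices; colormapped
renderings (a grayscale PNG writer is included) are for documentation only.

## The network, in base R

No deep-learning framework is attached: the layers (1D/2D convolution via
im2col and BLAS, batch normalization, max pooling, SE attention, dropout,
dense) and SGD with momentum are implemented in the package, and every
backward pass is verified against central finite differences in the test
suite (worst relative error below 1e-4 on a fused three-branch model).
Two architectural ambiguities were resolved as follows: SE blocks and
dropout live only in the 1D branch (the parameter table shows the 2D column
as a plain ResNet18; the prose sentence about SE "in each residual block" is
read as describing the 1D variant), and the three branches are fused by
feature concatenation into a single softmax head trained end to end (the
single-classifier diagram wins over the looser "outputs integrated"
phrasing). The two 2D branches do not share weights.

A `width_multiplier` scales all stage widths; 1 is the full 512-wide model,
and desk-scale runs use 1/4 (widths 16/32/64/128). One numerical choice
matters at this scale: with a ~140-beat training set an epoch holds only
three batches, so batch-norm running averages (momentum 0.1) lag the final
weights. After the last epoch the package therefore recomputes every
batch-norm layer's inference statistics exactly — one frozen-weight pass
over the training data accumulating channel means and the
law-of-total-variance estimate of the channel variances. This is the
standard "precise BN" correction; without it, evaluation-mode accuracy on
the training set itself can sit far below the training-mode accuracy purely
through statistics drift.

## Evaluation protocols

* **Intra-patient:** beat-level stratified random split 7:2:1
  (train/validation/test). Beats from one patient may appear on both sides —
  the easier, conventional protocol.
* **Inter-patient:** patient-level 7:3 split with no patient id shared
  across partitions and no separate validation set; the harder protocol that
  measures generalization to unseen patients. A class whose patients cannot
  cover both partitions stays wholly in training, with a warning.
* **Cross-validation:** 10-fold by default, fold assignment beat-level
  (stratified) intra or patient-level inter, exactly partitioning the data.
  Cross-validation and the fixed-ratio splits are independent protocols.
* **Ablation:** any non-empty subset of the three branches; smaller models
  drop the unused branches and shrink the fusion head.

Multi-class sensitivity/precision/specificity/F1 are macro-averages of
per-class one-vs-rest values. No learning-rate schedule, early stopping or
class re-weighting is applied. Training is declared stochastic; every split,
fold assignment and fit is nonetheless deterministic given its seed.

## What the synthetic generator emulates — and what it does not

`generate_record()` builds 12-lead records at 1000 Hz from per-lead scaled
sums of Gaussian bumps (P, Q, R, S, T), with configurable heart rate and RR
jitter, and adds three noise components: sinusoidal baseline wander
(default 0.1 mV at 0.3 Hz), 50 Hz powerline interference (0.03 mV) and white
broadband noise (0.02 mV). MI-like classes apply an ST-segment shift
(+0.2 mV plateau between the J point and T onset), T-wave inversion on three
leads and a deepened Q wave, on lead subsets that follow conventional
infarct-to-lead mappings. Ground-truth R-peak indices are stored so detector
accuracy is measurable; matching tolerance is +/-50 ms.

These fixtures exercise every operator in the pipeline — detection,
denoising, segmentation, imaging, training — but they are not physiological:
real ECG has beat-to-beat morphology variation, non-stationary noise,
arrhythmia, electrode artefacts, and far subtler class differences. The
defaults make the two classes strongly separable by design, so the
end-to-end check (a reduced-width model reaching at least 95% inter-patient
detection accuracy on synthetic data) validates the machinery, not clinical
performance; headline clinical numbers require the real PTB/PTB-XL corpora
and full-scale training, both outside this package's scope.

## Problem sizes used by the tests and the acceptance run

The acceptance run generates 8 records per class (10 s at 72 bpm), yielding
about 180 beats; trains the width-1/4 model on 16x16 images for the full 60
epochs under the inter-patient split; and reports detection metrics on the
held-out patients, alongside the R-peak recovery rate over five noisy
records, the wavelet denoiser's SNR-improvement rate over 50 trials at 5 dB
input SNR, the GAF and S-transform property deviations, and the metric
suite's hand-example values. The unit suite uses smaller models (width 1/16
to 1/8, images 8x8) so the whole test run completes in a few minutes.

## Known limitations

* Pure-R training is CPU-bound; the full-width model on real corpora is out
  of reach here by design.
* Pan-Tompkins runs on a single configurable lead; no multi-lead consensus.
* The WFDB reader covers the header + format-16 layout used by PTB-style
  records, not the full format zoo.
* The generator's class priors and noise are idealized; no attempt is made
  to mimic real PTB class imbalance.
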