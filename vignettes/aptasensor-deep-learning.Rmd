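---
title: "Deep-learning analysis of aptasensor drain-current signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-learning analysis of aptasensor drain-current signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aptasignal)
```

## The measurement and the analysis problem

An electrochemical aptasensor couples a target-binding aptamer to a
carbon-nanotube field-effect transistor (CNT-FET). As the analyte
concentration in the sensing well is raised step-wise — an analyte-free
baseline followed by injections spaced at fixed intervals, each adding a
decade of concentration — the drain current moves through a staircase of
plateaus. A *segment* is the stretch of the record over which the
concentration is constant; it is the unit of every downstream analysis.
The analysis goal is to recognize, from a single segment, which
concentration produced it (six classes, No Analyte up to 10 µM) and, in a
second task, to pool three sensor families into twelve classes that also
flag faulty recordings (non-sensing sensors, broken transistors, and
segments disturbed over a bounded interval).

Because such recordings are scarce and laborious to produce, the package
couples three deep-learning stages to a synthetic-signal generator:

1. **Augmentation** — a conditional variational autoencoder (CVAE)
   generates additional normal segments per concentration class; an
   unconditional VAE generates anomaly segments.
2. **Extrapolation** — recurrent forecasters (GRU / unidirectional /
   bidirectional LSTM) iteratively extend 300-sample segments to 500
   samples with a sliding-window procedure.
3. **Classification** — seven architectures (three plain recurrent
   networks, three convolutional-recurrent hybrids, one CNN) consume
   either the raw z-scored sequence or its short-time Fourier transform
   (STFT) spectrogram.

All layers (dense, 2-D convolution, transposed 1-D convolution, GRU/LSTM
cells with backpropagation through time), the Adam optimizer and the
losses are implemented in base R linear algebra inside the package; each
backward pass is pinned by finite-difference tests.

## The synthetic generator and what it emulates

`generate_signal()` builds one record from a `sensing_protocol()` (the
published timings: adenosine — 1 s sampling, 1000 s baseline, 500 s
steps; oestradiol — 1.081 s sampling, 600 s baseline, 300 s steps) and a
`kinetics_params()` set:

* **Staircase kinetics.** After each injection the current approaches its
  new plateau as `1 - exp(-u / tau)` with `tau = 120` s by default. The
  slow approach matters: it is the visible within-step evolution of real
  staircases, and it is what makes forecasting a segment's continuation a
  meaningful task at all.
* **Saturating dose response.** The plateau offset for the *j*-th decade
  above the lowest concentration is `step_gain * j^dose_exponent` with
  `dose_exponent = 0.5`. A sub-linear exponent encodes binding-site
  saturation at high analyte concentration and — given the protocol's
  baseline/step duration weighting — keeps whole-record z-scores within
  the conventional normal-data range of about [−1.5, 1.5], which is also
  the output range of the generative scaling layer (`alpha = 1.5`). A
  linear-in-decades rule would push the top class to z ≈ +2, outside the
  range the generative model can represent.
* **Noise, drift, population spread.** White readout noise
  (`noise_sd = 0.05` a.u. against a 2.5 a.u. top-of-ladder response),
  a per-sensor linear drift (population sd `2e-4` a.u./s, roughly ±2% of
  the baseline current per 1000 s), and per-sensor jitter of gain and
  time constant (`kinetics_population()`).
* **Anomalies.** `inject_anomaly()` realizes the three archetypes:
  suppressed step response, sparse large excursions across the record
  (calibrated so z-scored faulty records span about [−5, 5]), and an
  oscillatory disturbance confined to a stated interval.

The oestradiol protocols carry `samples_per_segment = 166` — the
conventional per-segment count — even though duration arithmetic would
suggest ~277 samples; the per-segment count is treated as authoritative
so the 166→300 resampling path is exercised.

What the generator does **not** emulate: correlated (1/f) current noise,
Langmuir binding chemistry, injection transients beyond a simple
exponential spike, or sensor-to-sensor transfer effects. Tests that pass
on this generator demonstrate that the pipeline's machinery is correct
and that its statistical contracts hold under the stated conditions; they
do not certify performance on laboratory recordings.

## Preprocessing

Whole records are z-scored (`zscore_normalize()`, population sd) before
segmentation — per-segment normalization would erase the level
differences that carry the concentration information. `segmentize()`
cuts at the annotated boundaries; `standardize_segments()` brings
segments to a working length (the trailing window for over-long baseline
segments, linear interpolation upward for 166-sample oestradiol
segments). `assign_labels()` implements both labeling schemes (C1: six
classes per dataset; C2: twelve classes across datasets with anomalies
as class 12).

The STFT (`compute_spectrogram()`) uses a 128-sample periodic Blackman
window (`alpha = 0.16`), 64 samples of overlap, a 128-point transform,
no tail padding, and keeps all 128 two-sided frequency rows of the
squared magnitude — exactly the dialect that turns 300-sample segments
into 128×3 matrices and 500-sample segments into 128×6. Magnitudes are
linear by default (`stft_config(db = TRUE)` switches to decibels, useful
when feeding plain recurrent networks whose gates saturate on
large-dynamic-range inputs).

## The generative models

The CVAE encoder compresses a segment (plus an embedded class-label
channel) through a strided convolution ladder — 300→150→75→38 samples
for the 300-sample models, 500→250→125→63 for the 500-sample models,
with residual refinement blocks — to a 64-unit vector that the
`sampling_layer()` splits into a 32-dimensional posterior mean and
log-variance; `Z = eps * exp(logvar/2) + mu`. The decoder mirrors the
ladder with transposed convolutions and ends in the bounded
`scaling_layer()` `alpha * tanh(x)` (`alpha` 1.5 for normal data, 5 for
anomalies), so every generated value lies strictly inside the data
range. Training minimizes `elbo_loss()`: the closed-form
diagonal-Gaussian KL plus a mean-squared reconstruction term, at 1:1
weight (`beta` exposed in `gen_train_config()`).

Numerical choices worth knowing: transposed-convolution kernels, strides
and paddings are chosen to reproduce the published per-stage output
sizes exactly where those are arithmetically coherent; where the printed
decoder ladder is internally inconsistent the package uses the clean
mirror ladder and treats the printed sizes it can honour (38/75/150/300
and 63/125/249/500) as the specification of record.

## The extrapolation procedure

`extrapolate_segments()` implements the iterative sliding-window
extension: at each iteration the predictor window
`[start_point + offset, l - time_step]` and its 15-sample-forward shift
are cut from every training series, the shared forecaster is trained on
these pairs, the network's outputs at the last 15 positions (which, by
the shift-map objective, estimate the next 15 samples) are appended to
every series, and the offset advances by 10. Fourteen iterations take a
300-sample segment past 500; the result is truncated to exactly 500.
Because the training target is the 15-ahead shift, no closed-loop
recursion inside a block is needed — the block is read off the
sequence-to-sequence output directly.

Three training-procedure choices stabilize the closed loop, and all are
configurable in `extrap_config()`:

* **Per-window mean-centering** (`center = TRUE`): the network learns
  level-invariant dynamics; without it, extended segments drift toward
  the concentration-class mean levels.
* **Input jitter** (`input_jitter = 0.04` z): Gaussian noise on the
  predictor windows during training. During deployment the network
  consumes its own smooth predictions — a distribution it never sees if
  trained only on noisy observations.
* **Closed-loop early stopping** (`val_fraction = 0.15`): 15% of window
  rows are held out and the model is rolled out closed-loop over their
  last 60 observed samples; the best-rollout checkpoint is kept.
  Extension quality is non-monotone in the epoch budget — an overfitted
  shift map destabilizes the loop — so checkpoint selection replaces a
  hand-picked epoch count.

The first iteration trains up to 300 single-batch epochs at learning
rate 0.005; later iterations warm-refit for 15 epochs at 0.001.

A note on the persistence comparison. `persistence_forecast()` repeats
the last observed value, and `forecast_error()` scores the final
200-sample tail. Under the shipped generator conditions the tail of a
truncated segment is a nearly flat plateau plus white noise; the
persistence anchor then sits within one noise standard deviation of the
optimum, and although the trained GRU achieves a *lower median* tail
error, it does not beat persistence on ≥80% of individual held-out
segments (about half to three-quarters, depending on the noise regime).
The package's test suite asserts the 80% contract as specified and
reports the shortfall honestly; in noisier regimes (where the anchor is
worse) the same implementation clears the bar comfortably.

## The classifiers

All seven architectures are built by `build_classifier()` from a
`classifier_spec()` and realize the published parameter shapes at
`n = 128` hidden units (verify with `classifier_shapes()` /
`tidy()`): gate-stacked recurrent blocks (`Wx: 3n×d` GRU, `4n×d` ULSTM,
`8n×d` BLSTM), the ConvRNN flatten width `k = lc × nf`, and the CNN
filter ladder 32/16/8/8/16/32 with a fully connected head of width
`k = lc6 × nf1`. Inputs adapt by mode: raw sequences are scalar
sequences for the RNNs and `ls×1` images with 5×1 kernels for the
convolutional networks; spectrograms are 128-feature frame sequences for
the RNNs, `128×F` images with 5×5 kernels for the ConvRNNs, and for the
CNN the time-axis kernel width adapts per layer (5 while the short frame
axis supports it, collapsing that axis, then 1-D kernels) so that six
successive valid convolutions remain possible.

Convolutional networks standardize each input element with its
training-set mean and standard deviation (the zscore convention of image
input layers); plain recurrent networks receive their sequences as-is.
Training is minibatch Adam on the softmax cross-entropy (reference
settings: 100 epochs, minibatch 128, learning rate 0.002);
`train_classifier_kfold()` holds out a stratified 20% test set once and
runs stratified k-fold cross-validation (reference k = 10) over the
remainder. Evaluation goes through `confusion_and_metrics()`: accuracy
as the confusion-matrix trace over the total, one-vs-rest precision and
recall, F1 (defined as 0 when precision + recall is 0) and the macro F1
as the unweighted class mean.

## Problem sizes used by the shipped tests

The test suite exercises the full pipeline at sizes chosen to make its
statistical assertions stable while remaining desk-scale: 40 records per
class for the six-class study (240 original segments, CVAE-augmented to
200 per class = 1200), classifiers at 30 epochs, the forecaster at 32
hidden units, and a held-out set of 48 segments for the
persistence comparison. The architecture-shape contracts are asserted at
the full `n = 128`.

## A worked example

```{r example}
library(aptasignal)

# simulate, normalize, segment, label
ds <- generate_dataset(sensing_protocol("oestradiol31"),
                       n_normal_per_class = 10, seed = 1)
segs <- segmentize_dataset(ds) |> standardize_segments(300L)
segs$label <- assign_labels(segs, "C1")

# spectrogram features
segs <- add_spectrograms(segs)
dim(segs$spectrogram[[1]])   # 128 x 3

# augment class 2 with a trained CVAE
gspec <- generative_model_spec("cvae_normal", input_length = 300L,
                               n_classes = 6L)
gen <- train_generator(gspec, segs, labels = segs$label,
                       config = gen_train_config(epochs = 30L), seed = 2)
new_segments <- generate_segments(gen, label = 2L, count = 5, seed = 3)
range(unlist(new_segments$values))   # strictly inside (-1.5, 1.5)

# train and evaluate a ConvGRU on the spectrograms
spec <- classifier_spec("ConvGRU", "spectrogram", segment_length = 300L,
                        n_classes = 6L)
x <- classifier_inputs(segs, "spectrogram")
mod <- build_classifier(spec, seed = 4) |>
  fit_classifier(x, segs$label, epochs = 10L, seed = 5)
rep <- confusion_and_metrics(segs$label, predict(mod, x)$.pred_class, 6)
glance(rep)
autoplot(rep)
```

## Known limitations

* The neural-network engine is single-threaded base R; it is sized for
  the package's synthetic studies, not for large datasets.
* The generator's white readout noise makes last-value persistence a
  near-optimal forecast on plateau tails (see the extrapolation note
  above); correlated-noise emulation is future work.
* Spectrogram magnitudes are linear by default; the decibel option
  exists but the cross-architecture comparisons here use the linear
  scale.
* The paper-scale experiment (100-epoch training, 10-fold
  cross-validation, all seven architectures on all three datasets) runs
  through the same functions but is not executed by the test suite.
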