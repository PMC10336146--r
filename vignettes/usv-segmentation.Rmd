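---
title: "Segmenting mouse ultrasonic vocalizations with small neural networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting mouse ultrasonic vocalizations with small neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mouse pups and adults communicate with ultrasonic vocalizations (USVs):
brief calls between 30 and 110 kHz that appear as bright ridges in a
spectrogram. Most downstream analyses — call counting, call-type
classification, comparisons between genotypes or treatments — depend on
first *segmenting* the recording: deciding, for every time frame, whether
a call is present, and turning those frame decisions into call intervals
with accurate start and end points.

`squeakseg` implements this segmentation pipeline end to end:

1. **Spectrogram.** Mono PCM recordings (nominally 250 kHz, 16-bit) are
   transformed with a 512-coefficient STFT at a step of 8 samples, using
   a Kaiser window of length 512 with shape parameter 5 — the same
   rendering settings under which the target annotations were produced.
   One frame therefore spans 32 µs, and 2048 frames span exactly
   65.536 ms.
2. **Chunking.** Full-track spectrograms are far too wide for one
   network input, so they are cut into `M × 2048` chunks with 50%
   overlap.
3. **Frame labelling.** One of three small segmenter networks maps each
   chunk to 2048 per-frame confidences in [0, 1] (architectures below).
4. **Merging.** Per-chunk decisions are combined with an element-wise OR
   over overlapping positions. Because OR of thresholded values equals
   thresholding the per-frame maximum, the package merges confidences
   with `pmax()` once and thresholds at `t_c` (default 0.5); the two
   views are interchangeable and the tests assert it.
5. **Morphological post-processing.** Binary closing then opening with a
   flat 1-D kernel fills short interior gaps and deletes short spurious
   runs. Default kernel lengths per architecture are 135 (AE), 150
   (UNET) and 65 (RNN) frames; `select_kernel()` retunes them by finding
   the kernel where training-set detection precision and recall cross.
6. **Evaluation.** Frame-wise precision/recall/accuracy/FPR pooled over
   test tracks, plus interval-level matching: a predicted call is a true
   positive when its IoU with a ground-truth call strictly exceeds
   `t_iou` (default 0.6), a ground-truth call is missed when no single
   prediction exceeds that threshold. Relative length errors
   `(l_GT − l_pr)/l_GT` of detected calls are summarised and compared
   between methods with the two-sided Wilcoxon rank-sum test.

## The three segmenters

All three networks receive an `M × n` chunk (`M = 256` frequency bins,
`n = 2048` frames at full scale) and emit `n` sigmoid confidences.

* **AE** — a convolutional auto-encoder. Encoder: six 3×3
  convolutions with 8, 8, 16, 16, 32, 32 filters (ReLU, He-normal
  initialization), each followed by 2×2 max pooling; an average pool
  over the frequency axis then yields a 1-D latent sequence. Decoder:
  six stages of 1-D up-sampling (factor 2) each followed by two
  length-3 1-D convolutions with (32,32), (32,32), (16,16), (16,16),
  (8,8), (4,1) filters; the final single-filter convolution carries the
  sigmoid. About 35k parameters.
* **UNET** — five 3×3 stride-2 convolutions with 8, 16, 32, 64, 96
  filters; a decoder of four (up-sample ×2, 3×3 convolution with 64,
  32, 16, 8 filters) stages whose outputs are concatenated with the
  matching encoder level; a final up-sampling and two convolutions (8
  and 1 filters, sigmoid on the last). The frequency axis is removed by
  average pooling only *after* the sigmoid, so encoder/decoder
  concatenations stay shape-coherent. Our literal transcription has
  184,809 parameters, 1.2% below the published 187,113; the residual
  gap reflects wiring details (exact concatenation points, the last two
  convolutions' dimensionality) the description leaves open, so the
  printed count is treated as a soft checksum (±5%) rather than a hard
  target.
* **RNN** — three convolution blocks (16 filters 3×3, then 32 and 64
  filters 5×5), each with batch normalization, ReLU and 2×2 max
  pooling; frequency average pooling; GRUs with 32, 16 and 1 units;
  dropout 0.3; dense layers with 256, 256 and 2048 neurons (batch norm,
  ReLU and dropout 0.4 after the first two); sigmoid. At ~735k
  parameters it is by far the largest of the three — and, as in the
  original study, not the best performer.

Unstated details we fixed once and kept: AE kernels default to 3×3 /
length-3 (matching the UNET's stated house style); "same" padding
everywhere so the stated pooling factors alone determine shapes; batch
size 32; no class weighting; every chunk of every training track is a
training sample, including all-noise chunks.

### Training

Binary cross-entropy loss, Adam, early stopping on validation loss with
patience 10 within at most 100 epochs, and 5-fold cross-validation *at
track level* (all chunks of a track stay in one fold) over a
learning-rate grid to pick the rate. Published best ranges are
5·10⁻⁵–10⁻⁷ (RNN), 10⁻⁴–10⁻⁶ (AE) and 10⁻⁴–10⁻⁷ (UNET); small synthetic
problems tolerate larger rates. One integer seed drives weight
initialization, shuffling, the validation split, and dropout, so
training is bit-reproducible here (there is no GPU nondeterminism: the
networks run on a built-in CPU autodiff core).

### Why the networks are built in-package

The segmenters run on a small reverse-mode autodiff tape written for
this package: im2col-based convolutions whose patch assembly is
compiled C++ and whose products are BLAS calls, 2×2 max pooling,
nearest-neighbour up-sampling, batch normalization, GRU layers with
full backpropagation through time, dropout, and Adam. Every operator is
verified against central finite differences in the test suite, and the
three assembled architectures are re-checked end to end the same way.
This keeps the dependency surface to base R plus Rcpp while making the
computation fully inspectable.

## The synthetic-data generator

Real recordings are large and cannot ship with the package, so
`generate_track()` synthesizes recordings with exact ground truth. Call
onsets follow a renewal process (exponential gaps plus a 30 ms
refractory minimum), durations are log-normal, and each call is a
frequency-modulated tone in one of six stereotyped shapes — flat,
upward, downward, chevron, short (≤10 ms) and frequency step (two flat
segments with an instantaneous jump) — embedded in white noise at a
controlled in-band SNR (signal power over noise power within
30–110 kHz).

Defaults are anchored to the recording campaign the pipeline targets:
3-minute tracks at 250 kHz and ~84 calls per minute (49,750 calls over
198 three-minute tracks). Those same counts imply that USV frames and
noise frames stand in a ratio of roughly 1:1.6, which at 84 calls/min
requires a mean call duration near 0.27 s; we therefore use log-normal
durations with median 0.23 s and σ_log = 0.5 (mean ≈ 0.26 s, coverage
≈ 0.36). Chevron calls are up-then-down linear sweeps; the shapes are
parameterizations of the standard call taxonomy, not acoustic models of
the mouse vocal tract.

`generate_spectrogram_fixture()` renders the same generative process
directly into a spectrogram matrix (bright ridges over a Gaussian dB
noise floor), skipping audio synthesis. Its frame hop and frequency
resolution are free parameters, which is what makes training
experiments affordable in tests. What these fixtures do *not* emulate:
reverberation and microphone coloration, amplitude modulation within
calls, harmonics, cage noise with spectral structure, and annotation
jitter from human raters. Passing the recovery test therefore shows the
pipeline's machinery is correct and trainable — not that the tiny
models would reach the published accuracy on real recordings.

## Numerical and boundary conventions

* Frames are 0-based; all intervals are half-open `[start, end)`;
  `time_to_frame()` rounds to the nearest frame.
* STFT framing has no centering or padding: frame *k* covers samples
  `[k·hop, k·hop + n_fft)`, so `N = ⌊(n_samples − n_fft)/hop⌋ + 1`.
  The DC row is dropped, leaving `M = 256` rows — divisible by the 2⁶
  pooling of the AE and the 2⁵ strides of the UNET.
* Amplitudes are dB magnitudes floored at −90 dB and min-max scaled to
  [0, 1] per chunk by default (per-track and raw modes are available);
  frame labels are amplitude-independent, so the normalization mode
  cannot change ground truth.
* The tail of a track gets one final padded chunk whose padding value
  is the spectrogram minimum (the noise floor), so no artificial edge
  is introduced; padded positions are dropped before merging.
* Morphology treats out-of-range positions as 0 for both dilation and
  erosion, so boundary-touching calls can shrink by up to ⌊K/2⌋ frames;
  the sliding-window oracle in the tests mirrors this convention. For
  even K the structuring-element origin sits at ⌊K/2⌋, giving a
  one-frame asymmetry.
* Closing precedes opening (a flag allows the reverse for ablation),
  and a single kernel length serves both operations.
* Detection matching is deliberately *not* one-to-one: every prediction
  is judged against its best-IoU ground-truth call and every
  ground-truth call against the best single prediction, with strict
  `>` at the threshold. Two predictions both exceeding the threshold on
  one call count as two true positives; a greedy one-to-one mode exists
  for sensitivity analysis. Undefined ratios (0/0) propagate as `NA`,
  never as 0 or 1.
* The rank-sum test uses the exact distribution when both samples have
  ≤10 observations and no ties, otherwise the normal approximation with
  tie correction (no continuity correction).

## The desk-scale recovery experiment

`run_desk_experiment()` is the package's built-in end-to-end check,
also reproduced by `scripts/acceptance.R`: 20 synthetic fixture tracks
of 30 s each at a 2 ms frame hop with 32 frequency bins and 20 dB
in-band SNR, split 4:1 at track level; a tiny-width AE (encoder filters
8, 8, 16) trained for at most 10 epochs with Adam at 2·10⁻³ on all
2048-frame chunks of the training tracks; prediction, OR-merging,
post-processing with a 5-frame kernel, and evaluation on the held-out
tracks at `t_iou = 0.5`. These sizes were chosen once as the smallest
configuration that exercises every pipeline stage with a comfortably
learnable signal; the full-width architectures and full-rate
spectrograms are available unchanged for real data.

On this configuration the held-out frame precision and recall land
around 0.99, detection precision at 1.00, and detection recall between
about 0.86 and 0.96 across seeds; the residual detection misses are
dominated by the shortest calls, whose 5-frame extent sits at the
post-processing kernel length and below the 8-frame effective time
resolution of the tiny encoder.

## Known limitations

* Arbitrary sampling rates are accepted but only flagged, not
  resampled; the calibration arithmetic assumes the nominal 250 kHz.
* Only 50% chunk overlap is supported, as in the original design.
* The spectrogram path loads a full track into memory (~1.9 GB for a
  3-minute track at full resolution); streaming is out of scope.
* The CLI's import adapter for third-party annotation formats is a
  stub: only the package's own `track_id,start_s,end_s` CSV dialect is
  parsed.
* Training the full-width networks on a real 158-track corpus is a
  GPU-scale job outside the scope of the test suite; the package
  provides the machinery, not the wall-clock budget.
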