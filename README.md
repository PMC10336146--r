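# squeakseg

Segmentation of mouse ultrasonic vocalizations (USVs) in audio
recordings. Mice communicate with calls between 30 and 110 kHz; almost
every downstream analysis — call counting, call-type classification,
genotype or treatment comparisons — depends on first detecting, frame by
frame, where those calls sit in the spectrogram and turning the frame
decisions into accurate call intervals. `squeakseg` implements that
pipeline for the people who run such studies: behavioural
neuroscientists and bioacousticians working with ultrasound recordings,
and methods developers who want a fully testable reference
implementation.

## What it does

For a recording `x` sampled at 250 kHz, the package

1. computes a Kaiser-window magnitude spectrogram `S` (512 Fourier
   coefficients, step 8 samples, so one frame every 32 µs and 2048
   frames = 65.536 ms);
2. cuts `S` into `M × n` chunks (`n = 2048`) with 50% overlap;
3. labels each frame of each chunk with one of three small neural
   segmenters — a convolutional auto-encoder (AE), a U-Net (UNET), or a
   convolutional-recurrent GRU network (RNN) — each mapping a chunk to
   sigmoid confidences `y ∈ [0,1]^n`, trained with binary cross-entropy
   and Adam under track-level k-fold cross-validation with early
   stopping;
4. merges overlapping chunk predictions with an element-wise OR (after
   thresholding at `t_c`, default 0.5);
5. cleans the track-level binary vector with 1-D binary **closing then
   opening** (flat kernel; defaults 135/150/65 frames for AE/UNET/RNN),
   filling short gaps and deleting isolated spikes;
6. scores the result: frame-wise precision, recall, accuracy and FPR,
   and detection-level matching where a predicted interval is a true
   positive iff its intersection-over-union with a ground-truth call
   satisfies `IoU > t_IoU` (default 0.6), plus relative length errors
   `(l_GT − l_pr)/l_GT` with a Wilcoxon rank-sum comparison between
   methods.

Because real annotated corpora are too large to ship, the package
includes a first-class synthetic generator: renewal-process call onsets,
log-normal durations, six stereotyped call shapes (flat, upward,
downward, chevron, short, frequency step) rendered as
frequency-modulated tones at a controlled in-band SNR — as audio
(`generate_track()`) or directly as spectrogram fixtures
(`generate_spectrogram_fixture()`), both with exact ground truth.

The three networks run on a compact reverse-mode autodiff core built
into the package (C++ patch assembly + BLAS products, GRU with full
backpropagation through time); every operator and all three assembled
architectures are finite-difference checked in the test suite.

## Worked example

```r
library(squeakseg)

tr <- generate_track(synth_config(duration_s = 5, snr_db = 15, seed = 42),
                     track_id = "demo")
tr
#> <usv_synthetic_track> demo: 5.0 s, 7 calls, 38.4% USV frames

spec <- compute_spectrogram(tr$recording, stft_config(), track_id = "demo")
spec
#> <usv_spectrogram> demo: 256 bins x 156187 frames, hop 0.032 ms, 0.5-125.0 kHz

head(tr$gt_intervals, 3)
#> # A tibble: 3 × 4
#>   track_id shape   start_s end_s
#>   <chr>    <chr>     <dbl> <dbl>
#> 1 demo     upward    0.114 0.485
#> 2 demo     chevron   0.648 0.949
#> 3 demo     upward    1.55  1.68
```

The track holds 7 calls covering 38% of its frames (the generator's
defaults reproduce the ~1:1.6 USV:noise frame balance of the recordings
the pipeline was designed around). The spectrogram is the pipeline's
working representation: 256 frequency bins up to 125 kHz, one column
per 32 µs frame.

The built-in end-to-end experiment trains a tiny-width AE on 20
synthetic fixture tracks (30 s each, split 4:1) and evaluates the
held-out tracks at `t_IoU = 0.5`:

```r
ex <- run_desk_experiment(seed = 1)
ex$report
#> <usv_eval_report> 4 track(s), t_IoU 0.50
#>   frames:    precision 0.9949  recall 0.9854  accuracy 0.9936  FPR 0.0025
#>   detection: precision 1  recall 0.8602  (TP 160, FP 0, FN 26)
```

Frame metrics near 0.99 say the per-frame labelling is essentially
solved at this SNR; detection precision 1.00 with recall 0.86 says
every reported call is real, while the residual misses are the shortest
calls (≤10 ms, at the post-processing kernel's own length). Compare
`ex$report_raw` to see what morphological post-processing contributes
(here it lifts detection precision from 0.994 to 1 by deleting spike
detections).

`tidy()`, `glance()` and `autoplot()` methods are provided for models,
evaluation reports, and PR curves; a thin CLI
(`inst/cli/squeakseg.R`) exposes `synth`, `spectrogram`, `train`,
`predict`, `tune-kernel`, `evaluate` and `run` subcommands over WAV and
CSV files.

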