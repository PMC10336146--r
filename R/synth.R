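#' Synthetic USV track configuration
#'
#' Describes the generative process for synthetic mouse ultrasonic
#' vocalization recordings: a renewal process of call onsets (exponential
#' gaps plus a refractory minimum gap), log-normal call durations, one of
#' six time-frequency shapes per call, and broadband Gaussian noise at a
#' controlled in-band signal-to-noise ratio.
#'
#' Default rates mirror the recording campaign the pipeline was built for:
#' 3-minute tracks sampled at 250 kHz, roughly 84 calls per minute, and
#' call durations whose mean (~0.26 s) reproduces a USV:noise frame ratio
#' of about 1:1.7.
#'
#' @param duration_s Track length in seconds.
#' @param rate Sampling rate in Hz.
#' @param calls_per_minute Expected call rate.
#' @param duration_meanlog,duration_sdlog Log-normal call duration
#'   parameters (seconds).
#' @param duration_range_s Hard clamp on call durations.
#' @param snr_db In-band SNR: call power over noise power inside the
#'   30-110 kHz band. `Inf` renders noise-free audio.
#' @param shape_mix Named probabilities over the six call shapes; must sum
#'   to 1.
#' @param f_range_hz Frequency band that bounds every call.
#' @param min_gap_s Minimum silent gap between consecutive calls.
#' @param amplitude Peak call amplitude on the linear full-scale-1 axis.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 180, rate = 250000,
                         calls_per_minute = 84,
                         duration_meanlog = log(0.23), duration_sdlog = 0.5,
                         duration_range_s = c(0.005, 1.5),
                         snr_db = 10,
                         shape_mix = c(flat = 0.25, upward = 0.2,
                                       downward = 0.2, chevron = 0.15,
                                       short = 0.1, frequency_step = 0.1),
                         f_range_hz = c(30000, 110000),
                         min_gap_s = 0.03, amplitude = 0.1, seed = 1L) {
  shapes <- c("flat", "upward", "downward", "chevron", "short", "frequency_step")
  if (!setequal(names(shape_mix), shapes)) {
    abort_squeakseg("`shape_mix` must name all six call shapes.",
                    "squeakseg_bad_config")
  }
  if (abs(sum(shape_mix) - 1) > 1e-8) {
    abort_squeakseg("`shape_mix` probabilities must sum to 1.",
                    "squeakseg_bad_config")
  }
  if (min_gap_s < 0) abort_squeakseg("`min_gap_s` must be >= 0.",
                                     "squeakseg_bad_config")
  structure(list(duration_s = duration_s, rate = rate,
                 calls_per_minute = calls_per_minute,
                 duration_meanlog = duration_meanlog,
                 duration_sdlog = duration_sdlog,
                 duration_range_s = duration_range_s,
                 snr_db = snr_db, shape_mix = shape_mix[shapes],
                 f_range_hz = f_range_hz, min_gap_s = min_gap_s,
                 amplitude = amplitude, seed = seed),
            class = "synth_config")
}

# Run `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Draw call onsets/durations/shapes for one track. Pure placement step,
# shared by the audio and direct-spectrogram renderers.
draw_call_specs <- function(cfg) {
  mean_dur <- exp(cfg$duration_meanlog + cfg$duration_sdlog^2 / 2)
  period <- 60 / cfg$calls_per_minute
  mean_open_gap <- period - cfg$min_gap_s - mean_dur
  if (cfg$calls_per_minute > 0 && mean_open_gap <= 0) {
    abort_squeakseg(
      "Infeasible packing: calls_per_minute x mean duration exceeds the track.",
      "squeakseg_infeasible_packing")
  }
  calls <- list()
  t <- 0
  while (cfg$calls_per_minute > 0) {
    gap <- stats::rexp(1, rate = 1 / mean_open_gap) + cfg$min_gap_s
    start <- t + gap
    dur <- stats::rlnorm(1, cfg$duration_meanlog, cfg$duration_sdlog)
    dur <- min(max(dur, cfg$duration_range_s[1]), cfg$duration_range_s[2])
    if (start + dur >= cfg$duration_s) break
    shape <- sample(names(cfg$shape_mix), 1, prob = cfg$shape_mix)
    band <- draw_call_band(shape, cfg$f_range_hz)
    if (shape == "short") dur <- min(dur, 0.010)
    calls[[length(calls) + 1L]] <-
      tibble::tibble(shape = shape, start_s = start, duration_s = dur,
                     f_lo = band[1], f_hi = band[2],
                     amplitude = cfg$amplitude)
    t <- start + dur
  }
  if (length(calls) == 0) {
    return(tibble::tibble(shape = character(), start_s = numeric(),
                          duration_s = numeric(), f_lo = numeric(),
                          f_hi = numeric(), amplitude = numeric()))
  }
  dplyr::bind_rows(calls)
}

# Frequency extent per shape, kept inside the USV band.
draw_call_band <- function(shape, f_range) {
  span <- switch(shape,
                 flat = stats::runif(1, 1000, 4000),
                 short = stats::runif(1, 1000, 4000),
                 upward = stats::runif(1, 10000, 40000),
                 downward = stats::runif(1, 10000, 40000),
                 chevron = stats::runif(1, 10000, 30000),
                 frequency_step = stats::runif(1, 10000, 30000))
  lo <- stats::runif(1, f_range[1], f_range[2] - span)
  c(lo, lo + span)
}

# Instantaneous frequency trajectory of one call at `n` sample points.
call_freq_trajectory <- function(shape, n, f_lo, f_hi) {
  u <- seq(0, 1, length.out = n)
  switch(shape,
         flat = rep((f_lo + f_hi) / 2, n),
         short = rep((f_lo + f_hi) / 2, n),
         upward = f_lo + (f_hi - f_lo) * u,
         downward = f_hi - (f_hi - f_lo) * u,
         chevron = f_lo + (f_hi - f_lo) * (1 - abs(2 * u - 1)),
         frequency_step = ifelse(u < 0.5, f_lo, f_hi))
}

#' Generate a synthetic USV recording with exact ground truth
#'
#' Calls are frequency-modulated tones (with a short raised-cosine onset
#' and offset ramp) embedded in white Gaussian noise scaled so that the
#' requested in-band SNR holds over the 30-110 kHz band.
#'
#' @param cfg A [synth_config()].
#' @param track_id Identifier for the generated track.
#' @param stft An [stft_config()] used to derive the ground-truth frame
#'   label vector.
#' @return A list of class `usv_synthetic_track`: `recording`
#'   (`usv_audio`), `gt_intervals` (tibble: `track_id`, `shape`,
#'   `start_s`, `end_s`), `gt_labels` (binary vector over STFT frames),
#'   and `calls` (the full call table).
#' @export
generate_track <- function(cfg = synth_config(), track_id = "synth",
                           stft = stft_config()) {
  with_seed(cfg$seed, {
    calls <- draw_call_specs(cfg)
    n <- round(cfg$duration_s * cfg$rate)
    if (is.finite(cfg$snr_db)) {
      band_frac <- diff(cfg$f_range_hz) / (cfg$rate / 2)
      sigma2 <- (cfg$amplitude^2 / 2) / band_frac / 10^(cfg$snr_db / 10)
      x <- stats::rnorm(n, sd = sqrt(sigma2))
    } else {
      x <- numeric(n)
    }
    for (i in seq_len(nrow(calls))) {
      i0 <- round(calls$start_s[i] * cfg$rate) + 1L
      len <- max(round(calls$duration_s[i] * cfg$rate), 8L)
      if (i0 + len - 1L > n) len <- n - i0 + 1L
      f <- call_freq_trajectory(calls$shape[i], len, calls$f_lo[i], calls$f_hi[i])
      phase <- 2 * pi * cumsum(f) / cfg$rate
      ramp <- pmin(1, seq_len(len) / max(1, round(0.1 * len)))
      env <- ramp * rev(ramp)
      x[i0:(i0 + len - 1L)] <- x[i0:(i0 + len - 1L)] +
        calls$amplitude[i] * env * sin(phase)
    }
    samples <- as.integer(round(pmin(pmax(x, -1), 1) * 32767))
    rec <- usv_audio(samples, cfg$rate)
    intervals <- tibble::tibble(track_id = track_id, shape = calls$shape,
                                start_s = calls$start_s,
                                end_s = calls$start_s + calls$duration_s)
    labels <- intervals_to_labels(intervals, n_frames(n, stft),
                                  cfg = stft, rate = cfg$rate)
    structure(list(recording = rec, gt_intervals = intervals,
                   gt_labels = labels, calls = calls, track_id = track_id),
              class = "usv_synthetic_track")
  })
}

#' @export
print.usv_synthetic_track <- function(x, ...) {
  cat(sprintf("<usv_synthetic_track> %s: %.1f s, %d calls, %.1f%% USV frames\n",
              x$track_id, x$recording$n_samples / x$recording$rate,
              nrow(x$gt_intervals), 100 * mean(x$gt_labels)))
  invisible(x)
}

#' Rasterize call intervals to a frame label vector
#'
#' Frame `k` (0-based) is labelled 1 iff it falls in
#' `[time_to_frame(start_s), time_to_frame(end_s))` for some interval;
#' intervals are half-open. Ground-truth intervals must be disjoint.
#'
#' @param intervals A data frame with `start_s` and `end_s` columns (or
#'   `start_frame`/`end_frame`).
#' @param N Number of frames in the track.
#' @param cfg,rate Frame timing, as in [time_to_frame()]. Alternatively
#'   pass `frame_hop_s` directly.
#' @param frame_hop_s Seconds per frame; overrides `cfg`/`rate` when given.
#' @return Integer 0/1 vector of length `N`.
#' @export
intervals_to_labels <- function(intervals, N, cfg = stft_config(),
                                rate = 250000, frame_hop_s = NULL) {
  N <- as.integer(N)
  y <- integer(N)
  if (is.null(intervals) || nrow(intervals) == 0) return(y)
  if (all(c("start_frame", "end_frame") %in% names(intervals))) {
    a <- as.integer(intervals$start_frame)
    b <- as.integer(intervals$end_frame)
  } else {
    hop_s <- if (!is.null(frame_hop_s)) frame_hop_s else cfg$hop / rate
    a <- as.integer(round(intervals$start_s / hop_s))
    b <- as.integer(round(intervals$end_s / hop_s))
  }
  o <- order(a)
  a <- a[o]; b <- b[o]
  if (any(a[-1] < b[-length(b)])) {
    abort_squeakseg("Ground-truth intervals overlap; they must be disjoint.",
                    "squeakseg_overlapping_intervals")
  }
  if (any(a < 0) || any(b > N)) {
    abort_squeakseg("Interval extends outside the track.",
                    "squeakseg_interval_out_of_range")
  }
  for (i in seq_along(a)) if (b[i] > a[i]) y[(a[i] + 1L):b[i]] <- 1L
  y
}

#' Draw a synthetic spectrogram fixture directly
#'
#' Bypasses audio synthesis: renders bright time-frequency ridges for each
#' call straight into a Gaussian noise-floor matrix in dB units. The
#' ground-truth semantics are identical to [generate_track()], but the
#' frame hop and frequency resolution are free parameters, which makes
#' these fixtures fast enough for unit tests and small training runs.
#'
#' @param cfg A [synth_config()]; `snr_db` sets ridge height above the
#'   noise floor in dB.
#' @param M Number of frequency bins (the band 0..rate/2 is divided evenly).
#' @param frame_hop_s Seconds per spectrogram frame.
#' @param noise_floor_db,noise_sd_db Noise-floor mean and standard
#'   deviation in dB.
#' @param track_id Identifier.
#' @return A list of class `usv_fixture`: `spectrogram`
#'   (`usv_spectrogram`), `gt_labels`, `gt_intervals`, `calls`.
#' @export
generate_spectrogram_fixture <- function(cfg = synth_config(), M = 64L,
                                         frame_hop_s = 0.002,
                                         noise_floor_db = -80,
                                         noise_sd_db = 3,
                                         track_id = "fixture") {
  with_seed(cfg$seed, {
    calls <- draw_call_specs(cfg)
    N <- as.integer(floor(cfg$duration_s / frame_hop_s))
    values <- matrix(stats::rnorm(M * N, noise_floor_db, noise_sd_db),
                     nrow = M, ncol = N)
    freq_hz <- (1:M) * (cfg$rate / 2) / M
    ridge_db <- noise_floor_db + cfg$snr_db
    for (i in seq_len(nrow(calls))) {
      k0 <- as.integer(round(calls$start_s[i] / frame_hop_s))
      k1 <- as.integer(round((calls$start_s[i] + calls$duration_s[i]) / frame_hop_s))
      k1 <- min(k1, N)
      if (k1 <= k0) next
      len <- k1 - k0
      f <- call_freq_trajectory(calls$shape[i], len, calls$f_lo[i], calls$f_hi[i])
      bins <- pmin(pmax(round(f / ((cfg$rate / 2) / M)), 1L), M)
      cols <- (k0 + 1L):k1
      values[cbind(bins, cols)] <- ridge_db
      above <- pmin(bins + 1L, M)
      below <- pmax(bins - 1L, 1L)
      values[cbind(above, cols)] <- pmax(values[cbind(above, cols)], ridge_db - 6)
      values[cbind(below, cols)] <- pmax(values[cbind(below, cols)], ridge_db - 6)
    }
    intervals <- tibble::tibble(track_id = track_id, shape = calls$shape,
                                start_s = calls$start_s,
                                end_s = calls$start_s + calls$duration_s)
    labels <- intervals_to_labels(intervals, N, frame_hop_s = frame_hop_s)
    spec <- new_spectrogram(values, frame_hop_s = frame_hop_s,
                            freq_hz = freq_hz, rate = cfg$rate,
                            cfg = stft_config(normalization = "per-chunk-minmax"),
                            track_id = track_id)
    structure(list(spectrogram = spec, gt_labels = labels,
                   gt_intervals = intervals, calls = calls,
                   track_id = track_id),
              class = "usv_fixture")
  })
}
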