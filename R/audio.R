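#' STFT configuration
#'
#' Parameters of the short-time Fourier transform used to render
#' spectrograms. The defaults reproduce the Avisoft settings used to
#' annotate the recordings this pipeline targets: 512 Fourier
#' coefficients, a step (hop) of 8 samples, and a Kaiser window of length
#' 512 with beta 5. At 250 kHz this yields one time frame every 32 us and
#' 256 frequency bins after the DC row is dropped.
#'
#' @param n_fft Window / FFT length in samples.
#' @param hop Step size in samples between consecutive frames.
#' @param window Window type; only `"kaiser"` is supported.
#' @param kaiser_beta Kaiser window shape parameter.
#' @param log_floor_db Magnitude floor, in dB, applied before normalization.
#' @param normalization One of `"per-chunk-minmax"` (each model input chunk
#'   is min-max scaled to `[0, 1]` when the spectrogram is split),
#'   `"per-track-minmax"` (the whole spectrogram is scaled once), or
#'   `"none"` (dB values kept as-is).
#' @return An object of class `stft_config`.
#' @export
stft_config <- function(n_fft = 512L, hop = 8L, window = "kaiser",
                        kaiser_beta = 5, log_floor_db = -90,
                        normalization = c("per-chunk-minmax",
                                          "per-track-minmax", "none")) {
  normalization <- match.arg(normalization)
  n_fft <- as.integer(n_fft)
  hop <- as.integer(hop)
  if (hop < 1L) abort_squeakseg("`hop` must be >= 1.", "squeakseg_bad_config")
  if (n_fft < hop) abort_squeakseg("`n_fft` must be >= `hop`.", "squeakseg_bad_config")
  if (!identical(window, "kaiser")) {
    abort_squeakseg("Only the Kaiser window is supported.", "squeakseg_bad_config")
  }
  structure(list(n_fft = n_fft, hop = hop, window = window,
                 kaiser_beta = kaiser_beta, log_floor_db = log_floor_db,
                 normalization = normalization),
            class = "stft_config")
}

#' Read a mono PCM 16-bit WAV file
#'
#' Minimal RIFF/WAVE reader for the uncompressed 16-bit mono recordings the
#' pipeline expects. Multichannel and non-PCM files are rejected with
#' distinct error classes rather than silently converted.
#'
#' @param path Path to a `.wav` file.
#' @return An object of class `usv_audio` with fields `samples` (integer
#'   PCM values), `rate` (Hz), and `n_samples`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    abort_squeakseg(sprintf("WAV file not found: %s", path),
                    "squeakseg_wav_unreadable")
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort_squeakseg(sprintf("Not a RIFF/WAVE file: %s", path),
                    "squeakseg_wav_unreadable")
  }
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      audio_format <- readBin(raw_fmt[1:2], "integer", 1, size = 2,
                              endian = "little", signed = FALSE)
      n_channels <- readBin(raw_fmt[3:4], "integer", 1, size = 2,
                            endian = "little", signed = FALSE)
      rate <- readBin(raw_fmt[5:8], "integer", 1, size = 4, endian = "little")
      bits <- readBin(raw_fmt[15:16], "integer", 1, size = 2,
                      endian = "little", signed = FALSE)
      fmt <- list(audio_format = audio_format, n_channels = n_channels,
                  rate = rate, bits = bits)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) {
        abort_squeakseg("WAV data chunk precedes fmt chunk.",
                        "squeakseg_wav_unreadable")
      }
      if (fmt$audio_format != 1L) {
        abort_squeakseg(
          sprintf("WAV encoding %d is not PCM; only uncompressed PCM is supported.",
                  fmt$audio_format),
          "squeakseg_wav_not_pcm")
      }
      if (fmt$bits != 16L) {
        abort_squeakseg(sprintf("Only 16-bit PCM is supported (got %d bits).",
                                fmt$bits),
                        "squeakseg_wav_not_pcm")
      }
      if (fmt$n_channels != 1L) {
        abort_squeakseg(
          sprintf("WAV file has %d channels; only mono input is supported.",
                  fmt$n_channels),
          "squeakseg_wav_multichannel")
      }
      samples <- readBin(con, "integer", size / 2, size = 2, endian = "little",
                         signed = TRUE)
      break
    } else {
      # skip unknown chunk (word-aligned)
      readBin(con, "raw", size + (size %% 2))
    }
  }
  if (is.null(samples)) {
    abort_squeakseg(sprintf("No data chunk found in %s", path),
                    "squeakseg_wav_unreadable")
  }
  if (fmt$rate != 250000L) {
    rlang::inform(sprintf("WAV sampling rate is %d Hz (pipeline nominal: 250000 Hz).",
                          fmt$rate),
                  class = "squeakseg_rate_note")
  }
  usv_audio(samples, fmt$rate)
}

#' Construct an audio recording object
#'
#' @param samples Integer PCM sample values in the signed 16-bit range.
#' @param rate Sampling rate in Hz.
#' @return An object of class `usv_audio`.
#' @export
usv_audio <- function(samples, rate) {
  samples <- as.integer(samples)
  if (any(samples < -32768L | samples > 32767L)) {
    abort_squeakseg("Samples outside the signed 16-bit range.",
                    "squeakseg_bad_audio")
  }
  if (rate <= 0) abort_squeakseg("`rate` must be positive.", "squeakseg_bad_audio")
  structure(list(samples = samples, rate = as.integer(rate),
                 n_samples = length(samples)),
            class = "usv_audio")
}

#' @export
print.usv_audio <- function(x, ...) {
  cat(sprintf("<usv_audio> %d samples @ %d Hz (%.3f s)\n",
              x$n_samples, x$rate, x$n_samples / x$rate))
  invisible(x)
}

#' Write a mono PCM 16-bit WAV file
#'
#' @param rec A `usv_audio` object (or integer sample vector).
#' @param path Output path.
#' @param rate Sampling rate, used only when `rec` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, rate = 250000L) {
  if (!inherits(rec, "usv_audio")) rec <- usv_audio(rec, rate)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  n_bytes <- 2L * rec$n_samples
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(rec$rate), con, size = 4, endian = "little")
  writeBin(as.integer(rec$rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(rec$samples, con, size = 2, endian = "little")
  invisible(path)
}

#' Number of STFT frames for a track length
#'
#' Frames are laid out without centering or padding: frame `k` (0-based)
#' covers samples `[k * hop, k * hop + n_fft)`, so
#' `N = floor((n_samples - n_fft) / hop) + 1`.
#'
#' @param n_samples Track length in samples.
#' @param cfg An [stft_config()].
#' @return Integer frame count.
#' @export
n_frames <- function(n_samples, cfg = stft_config()) {
  if (n_samples < cfg$n_fft) {
    abort_squeakseg("Track shorter than one analysis frame.",
                    "squeakseg_track_too_short")
  }
  as.integer((n_samples - cfg$n_fft) %/% cfg$hop + 1L)
}

#' Convert a frame index to seconds (and back)
#'
#' Frame indices are 0-based; frame `k` starts at `k * hop / rate` seconds.
#' `time_to_frame()` rounds to the nearest frame.
#'
#' @param k Frame index (0-based), vectorized.
#' @param t Time in seconds, vectorized.
#' @param cfg An [stft_config()] supplying the hop.
#' @param rate Sampling rate in Hz.
#' @return Seconds (`frame_to_time`) or integer frame indices
#'   (`time_to_frame`).
#' @export
frame_to_time <- function(k, cfg = stft_config(), rate = 250000) {
  if (any(k < 0)) abort_squeakseg("Frame index must be >= 0.",
                                  "squeakseg_bad_index")
  k * cfg$hop / rate
}

#' @rdname frame_to_time
#' @export
time_to_frame <- function(t, cfg = stft_config(), rate = 250000) {
  if (any(t < -1e-12)) abort_squeakseg("Time must be >= 0.", "squeakseg_bad_index")
  as.integer(round(t * rate / cfg$hop))
}

#' Compute a magnitude spectrogram
#'
#' Short-time Fourier transform with a Kaiser window, magnitude in dB with
#' a floor, and optional min-max normalization. The DC row is dropped so
#' the matrix has `n_fft / 2` frequency rows (256 with the defaults),
#' evenly divisible by the pooling/stride factors of all three segmenter
#' architectures.
#'
#' @param rec A `usv_audio` object.
#' @param cfg An [stft_config()].
#' @param track_id Identifier stored with the spectrogram.
#' @return An object of class `usv_spectrogram`: a list with `values`
#'   (M x N matrix, frequency x time), `freq_hz` (bin center frequencies),
#'   `frame_hop_s`, `rate`, `cfg`, and `track_id`.
#' @export
compute_spectrogram <- function(rec, cfg = stft_config(), track_id = "track") {
  stopifnot(inherits(rec, "usv_audio"))
  N <- n_frames(rec$n_samples, cfg)
  win <- as.numeric(signal::kaiser(cfg$n_fft, cfg$kaiser_beta))
  M <- cfg$n_fft %/% 2L
  x <- as.numeric(rec$samples) / 32768
  values <- matrix(0, nrow = M, ncol = N)
  floor_lin <- 10^(cfg$log_floor_db / 20)
  block <- 8192L
  starts0 <- (seq_len(N) - 1L) * cfg$hop            # 0-based frame starts
  for (b0 in seq(1L, N, by = block)) {
    b1 <- min(b0 + block - 1L, N)
    idx <- outer(seq_len(cfg$n_fft), starts0[b0:b1], `+`)
    frames <- matrix(x[idx], nrow = cfg$n_fft) * win
    sp <- stats::mvfft(frames)
    mag <- Mod(sp[2:(M + 1L), , drop = FALSE])
    values[, b0:b1] <- 20 * log10(pmax(mag, floor_lin))
  }
  if (cfg$normalization == "per-track-minmax") {
    rng <- range(values)
    span <- rng[2] - rng[1]
    values <- if (span > 0) (values - rng[1]) / span else values * 0
  }
  new_spectrogram(values, frame_hop_s = cfg$hop / rec$rate,
                  freq_hz = (1:M) * rec$rate / cfg$n_fft,
                  rate = rec$rate, cfg = cfg, track_id = track_id)
}

# Internal constructor shared with the fixture generator.
new_spectrogram <- function(values, frame_hop_s, freq_hz, rate, cfg, track_id) {
  stopifnot(is.matrix(values), all(is.finite(values)),
            length(freq_hz) == nrow(values))
  structure(list(values = values, freq_hz = freq_hz,
                 frame_hop_s = frame_hop_s, rate = rate, cfg = cfg,
                 track_id = track_id),
            class = "usv_spectrogram")
}

#' @export
print.usv_spectrogram <- function(x, ...) {
  cat(sprintf("<usv_spectrogram> %s: %d bins x %d frames, hop %.6g ms, %.1f-%.1f kHz\n",
              x$track_id, nrow(x$values), ncol(x$values),
              x$frame_hop_s * 1000, min(x$freq_hz) / 1000, max(x$freq_hz) / 1000))
  invisible(x)
}

#' @export
dim.usv_spectrogram <- function(x) dim(x$values)
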