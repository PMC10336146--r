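#' Split a spectrogram into 50%-overlapping model-input chunks
#'
#' Chunks of `n` frames start at origins `0, n/2, n, ...`; the last origin
#' is the smallest multiple of `n/2` such that the chunk reaches the end
#' of the track, so every frame is covered by at least one chunk. A final
#' partial chunk is padded up to `n` frames with the spectrogram minimum
#' (the noise floor) and carries `valid_len`, the number of real frames.
#'
#' When the spectrogram's STFT configuration requests per-chunk min-max
#' normalization it is applied here, after padding.
#'
#' @param spec A `usv_spectrogram`.
#' @param n Chunk length in frames (must be even).
#' @param overlap Overlap fraction; only 0.5 is supported.
#' @return A list of chunks; each chunk is a list with `values` (M x n
#'   matrix), `origin` (0-based first frame), `valid_len`, and `n`.
#' @export
split_spectrogram <- function(spec, n = 2048L, overlap = 0.5) {
  stopifnot(inherits(spec, "usv_spectrogram"))
  n <- as.integer(n)
  if (n %% 2L != 0L) abort_squeakseg("Chunk length `n` must be even.",
                                     "squeakseg_bad_chunking")
  if (!isTRUE(all.equal(overlap, 0.5))) {
    abort_squeakseg("Only 50% chunk overlap is supported.",
                    "squeakseg_bad_chunking")
  }
  N <- ncol(spec$values)
  if (N < 1L) abort_squeakseg("Empty spectrogram.", "squeakseg_bad_chunking")
  half <- n %/% 2L
  o_max <- if (N <= n) 0L else as.integer(ceiling((N - n) / half)) * half
  origins <- seq(0L, o_max, by = half)
  pad_value <- min(spec$values)
  per_chunk <- identical(spec$cfg$normalization, "per-chunk-minmax")
  lapply(origins, function(o) {
    valid <- min(n, N - o)
    v <- matrix(pad_value, nrow = nrow(spec$values), ncol = n)
    v[, seq_len(valid)] <- spec$values[, (o + 1L):(o + valid), drop = FALSE]
    if (per_chunk) {
      rng <- range(v)
      span <- rng[2] - rng[1]
      v <- if (span > 0) (v - rng[1]) / span else v * 0
    }
    list(values = v, origin = o, valid_len = as.integer(valid), n = n)
  })
}

#' Slice a track-level label vector into chunk-aligned targets
#'
#' Companion to [split_spectrogram()]: produces, for the same chunk grid,
#' the per-chunk binary target vectors used for training (padded tail
#' positions are set to 0 and excluded from `valid_len`).
#'
#' @param y Binary label vector of length N.
#' @param n Chunk length in frames.
#' @param overlap Overlap fraction; only 0.5 is supported.
#' @return A list of lists with `pred` (length-`n` 0/1 vector), `origin`,
#'   `valid_len`, `n`.
#' @export
split_labels <- function(y, n = 2048L, overlap = 0.5) {
  y <- check_labels(y)
  n <- as.integer(n)
  if (n %% 2L != 0L) abort_squeakseg("Chunk length `n` must be even.",
                                     "squeakseg_bad_chunking")
  if (!isTRUE(all.equal(overlap, 0.5))) {
    abort_squeakseg("Only 50% chunk overlap is supported.",
                    "squeakseg_bad_chunking")
  }
  N <- length(y)
  half <- n %/% 2L
  o_max <- if (N <= n) 0L else as.integer(ceiling((N - n) / half)) * half
  lapply(seq(0L, o_max, by = half), function(o) {
    valid <- min(n, N - o)
    v <- integer(n)
    v[seq_len(valid)] <- y[(o + 1L):(o + valid)]
    list(pred = v, origin = o, valid_len = as.integer(valid), n = n)
  })
}

#' Merge per-chunk predictions back into a track-level vector
#'
#' Overlapping positions are combined with an element-wise OR for binary
#' predictions; because OR on thresholded values equals thresholding the
#' per-frame maximum, real-valued confidences are merged with `pmax()` and
#' the same function serves both. Padded tail positions (beyond each
#' chunk's `valid_len`) are discarded before merging.
#'
#' @param chunk_preds List of chunk predictions: each a list with `pred`
#'   (length-`n` vector), `origin`, and `valid_len`.
#' @param N Track length in frames.
#' @return A vector of length `N` (integer when all inputs are binary).
#' @export
merge_predictions <- function(chunk_preds, N) {
  N <- as.integer(N)
  covered <- logical(N)
  out <- rep(-Inf, N)
  for (ch in chunk_preds) {
    valid <- as.integer(ch$valid_len)
    o <- as.integer(ch$origin)
    if (valid < 1L) next
    idx <- (o + 1L):min(o + valid, N)
    out[idx] <- pmax(out[idx], ch$pred[seq_along(idx)])
    covered[idx] <- TRUE
  }
  if (!all(covered)) {
    abort_squeakseg(sprintf("Chunk set does not cover all %d frames (first gap at frame %d).",
                            N, which(!covered)[1] - 1L),
                    "squeakseg_coverage_gap")
  }
  binary <- all(vapply(chunk_preds, function(ch)
    all(ch$pred[seq_len(ch$valid_len)] %in% c(0, 1)), logical(1)))
  if (binary) as.integer(out) else out
}
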