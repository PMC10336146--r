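# Chunk-like samples on the same [0, 1] scale the pipeline feeds models.
make_toy_dataset <- function(n_samples, M = 16L, n = 64L, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_samples), function(i) {
    y <- intervals_to_labels(random_intervals(2, span = n), n)
    x <- matrix(runif(M * n, 0, 0.3), M, n)
    on <- which(y == 1)
    if (length(on)) x[sample(M %/% 2, 1) + 2, on] <- 1  # bright ridge
    list(x = x, y = y)
  })
}
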