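# Independent oracles and small fixture builders used across tests.

# Exhaustive-distance kNN oracle: per-query loop over all training rows,
# plain sort on distance with index tie-break. Independent of knn_predict.
oracle_knn <- function(train, labels, queries, k) {
  apply(queries, 1L, function(q) {
    d <- sqrt(colSums((t(train) - q)^2))
    nn <- order(d, seq_along(d))[seq_len(k)]
    as.integer(sum(labels[nn]) > k / 2)
  })
}

# Squared single-pass magnitude response of a rational digital filter at
# frequency f (Hz) for sampling rate fs: the expected forward-backward gain.
oracle_filter_gain2 <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  h <- sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1))
  Mod(h)^2
}

# RMS of the interior of a signal (edge transients excluded).
interior_rms <- function(x, drop_frac = 0.1) {
  n <- length(x)
  keep <- seq(floor(n * drop_frac) + 1L, ceiling(n * (1 - drop_frac)))
  sqrt(mean(x[keep]^2))
}

# A tiny, linearly separable segment dataset: class 0 windows fluctuate
# around a low level, class 1 around a high level (values kept in [0, 1]).
make_separable_dataset <- function(n_per_class = 30L, len = 50L, seed = 42L) {
  set.seed(seed)
  low <- matrix(runif(n_per_class * len, 0.05, 0.35), n_per_class, len)
  high <- matrix(runif(n_per_class * len, 0.65, 0.95), n_per_class, len)
  segment_dataset(rbind(low, high), rep(c(0L, 1L), each = n_per_class))
}

# Small CNN architecture used where training speed matters more than the
# reference geometry.
small_architecture <- function(input_length = 50L) {
  architecture_spec(input_length, list(
    layer_spec("conv1d", filters = 4L, kernel = 5L, stride = 2L),
    layer_spec("relu"),
    layer_spec("maxpool1d"),
    layer_spec("conv1d", filters = 8L, kernel = 3L, stride = 1L),
    layer_spec("relu"),
    layer_spec("maxpool1d"),
    layer_spec("gap"),
    layer_spec("dense", units = 10L),
    layer_spec("relu"),
    layer_spec("dense", units = 1L),
    layer_spec("sigmoid")
  ))
}
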