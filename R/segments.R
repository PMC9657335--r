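#' Segment dataset container
#'
#' Holds fixed-length analysis windows as rows of a matrix, together with
#' their binary class labels (0 = pre-lesion, 1 = post-lesion) and
#' per-segment provenance (which recording, which offset).
#'
#' @param segments Numeric matrix, one window per row.
#' @param labels Integer vector of 0/1 labels, one per row.
#' @param source Optional data frame with one row per segment
#'   (columns `recording`, `offset`).
#' @return An object of class `segment_dataset`.
#' @export
segment_dataset <- function(segments, labels, source = NULL) {
  if (!is.matrix(segments)) stop_invalid("segments must be a matrix")
  labels <- check_binary_labels(labels)
  if (nrow(segments) != length(labels)) {
    stop_invalid("nrow(segments) must equal length(labels)")
  }
  if (is.null(source)) {
    source <- data.frame(recording = rep(NA_integer_, nrow(segments)),
                         offset = rep(NA_integer_, nrow(segments)))
  }
  if (nrow(source) != nrow(segments)) {
    stop_invalid("source must have one row per segment")
  }
  structure(
    list(segments = segments, labels = labels,
         window_length = ncol(segments), source = source),
    class = "segment_dataset"
  )
}

#' @export
print.segment_dataset <- function(x, ...) {
  cat(sprintf("<segment_dataset> %d segments x %d samples; labels: 0=%d, 1=%d\n",
              nrow(x$segments), x$window_length,
              sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}

#' Cut a signal into disjoint fixed-length windows
#'
#' Consecutive non-overlapping windows of `window_length` samples; the
#' trailing remainder shorter than one window is discarded, so the
#' output has `floor(length(samples) / window_length)` rows.
#'
#' @param samples Numeric signal vector.
#' @param window_length Window length in samples (> 0); 1000 samples at
#'   1000 Hz is the canonical 1000 ms analysis window.
#' @return Numeric matrix with one window per row (possibly 0 rows).
#' @export
#' @examples
#' segment_signal(1:25, 10)  # 2 rows; samples 21:25 discarded
segment_signal <- function(samples, window_length = 1000L) {
  window_length <- check_count(window_length, "window_length", lower = 1L)
  n_win <- floor(length(samples) / window_length)
  if (n_win == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = window_length))
  }
  matrix(samples[seq_len(n_win * window_length)],
         nrow = n_win, ncol = window_length, byrow = TRUE)
}

#' Balance classes by random over-sampling
#'
#' Duplicates rows of the minority class, sampled uniformly with
#' replacement, until both classes have the majority count. Every
#' original row is preserved (originals first, duplicates appended).
#'
#' @param segments Numeric matrix of windows.
#' @param labels 0/1 labels per row; both classes must be present.
#' @param seed Integer seed making the draw deterministic.
#' @return List with `segments`, `labels` and `origin` (the original row
#'   index every output row came from).
#' @export
balance_oversample <- function(segments, labels, seed = 1) {
  labels <- check_binary_labels(labels)
  counts <- c(sum(labels == 0L), sum(labels == 1L))
  if (any(counts == 0L)) {
    stop_invalid("both classes must be present to balance")
  }
  n_needed <- max(counts) - min(counts)
  origin <- seq_along(labels)
  if (n_needed > 0L) {
    minority <- if (counts[1] < counts[2]) 0L else 1L
    idx_min <- which(labels == minority)
    extra <- with_seed(seed, sample(idx_min, n_needed, replace = TRUE))
    segments <- rbind(segments, segments[extra, , drop = FALSE])
    labels <- c(labels, labels[extra])
    origin <- c(origin, extra)
  }
  list(segments = segments, labels = labels, origin = origin)
}

#' Min-max normalize a window to \[0, 1\]
#'
#' `(x - min) / (max - min)` elementwise. A constant window (zero range)
#' maps to all zeros rather than dividing by zero.
#'
#' @param segment Non-empty numeric vector.
#' @return Numeric vector with minimum 0 and maximum 1 (all zeros when
#'   the input is constant).
#' @export
#' @examples
#' minmax_normalize(c(-1, 0, 1))
minmax_normalize <- function(segment) {
  if (length(segment) == 0L) stop_invalid("segment must be non-empty")
  rng <- range(segment)
  if (rng[1] == rng[2]) {
    return(rep(0, length(segment)))
  }
  (segment - rng[1]) / (rng[2] - rng[1])
}

# Row-wise min-max normalization of a window matrix.
normalize_segments <- function(segments) {
  if (nrow(segments) == 0L) return(segments)
  lo <- apply(segments, 1L, min)
  hi <- apply(segments, 1L, max)
  span <- hi - lo
  span[span == 0] <- 1   # constant rows map to 0
  (segments - lo) / span
}

#' Stratified train/test split
#'
#' Splits a [segment_dataset()] into disjoint, exhaustive train and test
#' parts, stratified by label: each class contributes
#' `round(test_fraction * n_class)` segments to the test set.
#'
#' @param dataset A [segment_dataset()].
#' @param test_fraction Held-out fraction, strictly between 0 and 1
#'   (default 0.2 for the 80:20 split).
#' @param seed Integer seed for the random assignment.
#' @return List with elements `train` and `test`, both `segment_dataset`s.
#' @export
split_train_test <- function(dataset, test_fraction = 0.2, seed = 1) {
  if (!inherits(dataset, "segment_dataset")) {
    stop_invalid("dataset must be a segment_dataset")
  }
  check_scalar_number(test_fraction, "test_fraction", lower = 0, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  labels <- dataset$labels
  test_idx <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    if (length(idx) < 2L) {
      stop_invalid("class ", cls, " has fewer than 2 segments")
    }
    n_test <- round(test_fraction * length(idx))
    picked <- with_seed(derive_seed(seed, paste0("split_", cls)),
                        sample(idx, n_test))
    test_idx <- c(test_idx, picked)
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(labels), test_idx)
  subset_sd <- function(idx) {
    segment_dataset(dataset$segments[idx, , drop = FALSE],
                    labels[idx], dataset$source[idx, , drop = FALSE])
  }
  list(train = subset_sd(train_idx), test = subset_sd(test_idx))
}

#' Run the full pre-processing chain on raw recordings
#'
#' Executes the conditioning pipeline in its fixed order: zero-phase
#' bandpass + notch filtering, disjoint 1000 ms segmentation, random
#' over-sampling to balance the classes, per-window min-max
#' normalization, and the stratified 80:20 split.
#'
#' @param recordings List of `emg_recording` objects (all sharing one
#'   sampling rate; mismatched rates are an error, not resampled).
#' @param window_length Window length in samples.
#' @param band_spec,notch_spec Filter specifications; pass `NULL` to skip
#'   a stage.
#' @param balance Balance classes by over-sampling (default `TRUE`).
#' @param normalize Per-window min-max normalization (default `TRUE`).
#' @param test_fraction Held-out fraction for the split.
#' @param seed Integer seed driving over-sampling and the split.
#' @return List with `train`, `test` (both [segment_dataset()]) and
#'   `full` (the balanced, normalized dataset before splitting).
#' @export
preprocess_recordings <- function(recordings, window_length = 1000L,
                                  band_spec = filter_spec(),
                                  notch_spec = filter_spec("notch"),
                                  balance = TRUE, normalize = TRUE,
                                  test_fraction = 0.2, seed = 1) {
  if (length(recordings) == 0L) stop_invalid("no recordings supplied")
  fs_all <- vapply(recordings, `[[`, numeric(1), "sampling_rate")
  if (length(unique(fs_all)) != 1L) {
    stop_invalid("recordings have mismatched sampling rates; resampling is not supported")
  }
  fs <- fs_all[1]
  seg_list <- vector("list", length(recordings))
  lab_list <- vector("list", length(recordings))
  src_list <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    x <- recordings[[i]]$samples
    if (!is.null(band_spec)) x <- bandpass_filter(x, fs, band_spec)
    if (!is.null(notch_spec)) x <- notch_filter(x, fs, notch_spec)
    segs <- segment_signal(x, window_length)
    seg_list[[i]] <- segs
    lab_list[[i]] <- rep(recordings[[i]]$label, nrow(segs))
    src_list[[i]] <- data.frame(
      recording = rep(i, nrow(segs)),
      offset = (seq_len(nrow(segs)) - 1L) * window_length
    )
  }
  segments <- do.call(rbind, seg_list)
  labels <- unlist(lab_list)
  source <- do.call(rbind, src_list)
  if (balance) {
    bal <- balance_oversample(segments, labels, seed = derive_seed(seed, "balance"))
    segments <- bal$segments
    labels <- bal$labels
    source <- source[bal$origin, , drop = FALSE]
  }
  if (normalize) {
    segments <- normalize_segments(segments)
  }
  full <- segment_dataset(segments, labels, source)
  split <- split_train_test(full, test_fraction, seed = derive_seed(seed, "split"))
  list(train = split$train, test = split$test, full = full)
}

#' Export a segment dataset as CSV
#'
#' One row per segment, the window samples as columns and the class
#' label as the final `label` column.
#'
#' @param dataset A [segment_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segments_csv <- function(dataset, path) {
  df <- as.data.frame(dataset$segments)
  names(df) <- paste0("s", seq_len(ncol(df)))
  df$label <- dataset$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
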