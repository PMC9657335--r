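#' Classical EMG amplitude features
#'
#' Four standard time-domain amplitude features computed per analysis
#' window, in the fixed column order area, RMS, turns, zero crossings.
#'
#' * **Area**: integrated rectified amplitude, `sum(abs(x))`.
#' * **RMS**: `sqrt(mean(x^2))`.
#' * **Turns**: number of interior local extrema whose amplitude differs
#'   from the previously counted turn by more than a threshold — the
#'   classical Willison-style complexity measure. On raw recordings the
#'   classical threshold is 100 uV; after per-window min-max
#'   normalization physical units are gone, so the default threshold is
#'   derived from the training data's amplitude range instead.
#' * **Zero crossings**: thresholded sign changes between adjacent
#'   samples, a proxy for frequency content.
#'
#' @param segment Non-empty numeric vector.
#' @param threshold Non-negative amplitude threshold (turns, zero
#'   crossings).
#' @return A single number (`feature_area`, `feature_rms`) or count
#'   (`feature_turns`, `feature_zero_crossings`).
#' @name emg_features
NULL

#' @rdname emg_features
#' @export
#' @examples
#' feature_area(c(0.5, -0.5, 1))   # 2
#' feature_rms(c(3, 4))            # sqrt(12.5)
#' feature_turns(c(0, 1, 0, 1, 0), 0.5)          # 3
#' feature_zero_crossings(c(1, -1, 1, -1), 0)    # 3
feature_area <- function(segment) {
  if (length(segment) == 0L) stop_invalid("segment must be non-empty")
  sum(abs(segment))
}

#' @rdname emg_features
#' @export
feature_rms <- function(segment) {
  if (length(segment) == 0L) stop_invalid("segment must be non-empty")
  sqrt(mean(segment^2))
}

#' @rdname emg_features
#' @export
feature_zero_crossings <- function(segment, threshold = 0) {
  check_scalar_number(threshold, "threshold", lower = 0)
  if (length(segment) < 2L) return(0L)
  # exact zeros carry the previous nonzero sign, so e.g. (1, 0, 1) is not
  # a crossing but (1, 0, -1) is counted once
  s <- sign(segment)
  for (i in seq_along(s)) {
    if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  }
  d <- abs(diff(segment))
  sum(s[-length(s)] * s[-1L] < 0 & d > threshold)
}

#' @rdname emg_features
#' @export
feature_turns <- function(segment, threshold = 0) {
  check_scalar_number(threshold, "threshold", lower = 0)
  n <- length(segment)
  if (n < 3L) return(0L)
  d <- diff(segment)
  # interior points where the slope changes sign (plateaus carry the
  # previous slope direction)
  s <- sign(d)
  for (i in seq_along(s)) {
    if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  }
  is_turn <- s[-length(s)] * s[-1L] < 0
  count <- 0L
  ref <- segment[1L]
  for (i in which(is_turn)) {
    amp <- segment[i + 1L]
    if (abs(amp - ref) > threshold) {
      count <- count + 1L
      ref <- amp
    }
  }
  count
}

#' Build the 4-column feature matrix for the kNN arm
#'
#' Computes area, RMS, turns and zero crossings for every segment, then
#' applies the two-step scaling in the fixed order standardize (z-score)
#' then min-max rescale to \[0, 1\], with both sets of parameters fitted
#' exclusively on the training rows. Test rows are transformed with the
#' training parameters and may therefore fall outside \[0, 1\].
#'
#' Default thresholds: turns threshold `0.1 * (max - min)` of the
#' training segments' pooled amplitude distribution (the classical
#' 100 uV Willison threshold is meaningless after min-max
#' normalization); zero-crossing threshold 0.
#'
#' @param train A [segment_dataset()] used to fit the scaling.
#' @param test Optional [segment_dataset()] transformed with the training
#'   parameters.
#' @param turns_threshold,zc_threshold Feature thresholds; `NULL` selects
#'   the defaults above.
#' @return An object of class `feature_matrix`: list with `train`
#'   (n x 4 matrix), `test` (or `NULL`), `raw_train`, `raw_test`
#'   (unscaled features), `scaling` (per-column mean/sd/min/max) and
#'   `thresholds`.
#' @export
build_feature_matrix <- function(train, test = NULL,
                                 turns_threshold = NULL, zc_threshold = 0) {
  if (!inherits(train, "segment_dataset") || nrow(train$segments) == 0L) {
    stop_invalid("train must be a non-empty segment_dataset")
  }
  if (is.null(turns_threshold)) {
    rng <- range(train$segments)
    turns_threshold <- 0.1 * (rng[2] - rng[1])
  }
  extract <- function(segments) {
    t(apply(segments, 1L, function(x) {
      c(area = feature_area(x),
        rms = feature_rms(x),
        turns = feature_turns(x, turns_threshold),
        zero_crossings = feature_zero_crossings(x, zc_threshold))
    }))
  }
  raw_train <- extract(train$segments)
  raw_test <- if (!is.null(test)) extract(test$segments) else NULL

  mu <- colMeans(raw_train)
  sd_ <- apply(raw_train, 2L, stats::sd)
  dead <- !is.finite(sd_) | sd_ == 0
  if (any(dead)) {
    warning("zero-variance training feature column(s) mapped to 0: ",
            paste(colnames(raw_train)[dead], collapse = ", "), call. = FALSE)
    sd_[dead] <- 1
  }
  z_train <- sweep(sweep(raw_train, 2L, mu), 2L, sd_, "/")
  lo <- apply(z_train, 2L, min)
  hi <- apply(z_train, 2L, max)
  span <- hi - lo
  dead2 <- span == 0
  span[dead2] <- 1
  rescale <- function(raw) {
    z <- sweep(sweep(raw, 2L, mu), 2L, sd_, "/")
    out <- sweep(sweep(z, 2L, lo), 2L, span, "/")
    out[, dead | dead2] <- 0
    out
  }
  structure(
    list(train = rescale(raw_train),
         test = if (!is.null(raw_test)) rescale(raw_test) else NULL,
         raw_train = raw_train, raw_test = raw_test,
         scaling = list(mean = mu, sd = sd_, min = lo, max = hi),
         thresholds = c(turns = turns_threshold, zero_crossings = zc_threshold)),
    class = "feature_matrix"
  )
}

#' Export a feature table as CSV
#'
#' @param features n x 4 feature matrix (columns area, rms, turns,
#'   zero_crossings).
#' @param labels 0/1 labels, one per row.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, labels, path) {
  df <- as.data.frame(features)
  names(df) <- c("area", "rms", "turns", "zero_crossings")
  df$label <- check_binary_labels(labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
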