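fs <- 1000
t10 <- seq(0, 10 - 1 / fs, by = 1 / fs)

test_that("bandpass gain matches the squared analytic magnitude response", {
  expect_identical(bandpass_filter(numeric(2000), fs), numeric(2000))

  bf <- signal::butter(2, c(10, 450) / (fs / 2), type = "pass")
  for (f in c(1, 100, 200)) {
    x <- sin(2 * pi * f * t10)
    g_measured <- interior_rms(bandpass_filter(x, fs)) / interior_rms(x)
    g_oracle <- oracle_filter_gain2(bf$b, bf$a, f, fs)
    expect_equal(g_measured, g_oracle, tolerance = 0.02)
  }

  x100 <- sin(2 * pi * 100 * t10)
  g100 <- interior_rms(bandpass_filter(x100, fs)) / interior_rms(x100)
  expect_gte(g100, 0.95)
  expect_lte(g100, 1.05)

  x1 <- sin(2 * pi * 1 * t10)
  expect_lt(interior_rms(bandpass_filter(x1, fs)) / interior_rms(x1), 0.05)

  expect_error(bandpass_filter(x100, 800), "Nyquist")
  expect_error(bandpass_filter(numeric(10), fs), "too short")
})

test_that("notch removes 60 Hz and passes 30 Hz, matching the analytic oracle", {
  expect_identical(notch_filter(numeric(2000), fs), numeric(2000))

  nf <- emgtsci:::design_notch(60, fs, 30)
  x60 <- sin(2 * pi * 60 * t10)
  x30 <- sin(2 * pi * 30 * t10)
  g60 <- interior_rms(notch_filter(x60, fs)) / interior_rms(x60)
  g30 <- interior_rms(notch_filter(x30, fs)) / interior_rms(x30)
  expect_lt(g60, 0.1)
  expect_equal(g60, oracle_filter_gain2(nf$b, nf$a, 60, fs), tolerance = 0.01)
  expect_gte(g30, 0.9)
  expect_lte(g30, 1.1)
  expect_equal(g30, oracle_filter_gain2(nf$b, nf$a, 30, fs), tolerance = 0.02)
})

test_that("forward-backward filtering is zero-phase (cross-correlation peaks at lag 0)", {
  x <- sin(2 * pi * 50 * t10)
  y <- bandpass_filter(x, fs)
  cc <- stats::ccf(y, x, lag.max = 10, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf), 1, 1], 0)
})

test_that("segmentation follows the floor rule and concatenates back to a prefix", {
  expect_identical(nrow(segment_signal(numeric(5000), 1000)), 5L)
  m <- segment_signal(seq_len(2500), 1000)
  expect_identical(nrow(m), 2L)
  expect_identical(as.numeric(t(m)), as.numeric(1:2000))
  expect_identical(nrow(segment_signal(numeric(999), 1000)), 0L)
  expect_error(segment_signal(1:10, 0), "invalid argument")
})

test_that("random over-sampling equalizes counts and preserves every original row", {
  set.seed(1)
  segs <- matrix(rnorm(8 * 5), 8, 5)
  labels <- c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L)
  bal <- balance_oversample(segs, labels, seed = 2)
  expect_identical(sum(bal$labels == 0L), 5L)
  expect_identical(sum(bal$labels == 1L), 5L)
  expect_identical(bal$segments[1:8, ], segs)

  # already balanced -> unchanged
  bal2 <- balance_oversample(segs[1:6, ], c(0L, 0L, 0L, 1L, 1L, 1L), seed = 2)
  expect_identical(bal2$segments, segs[1:6, ])

  # appended rows are copies of minority originals
  big <- matrix(rnorm(202 * 4), 202, 4)
  lab_big <- c(0L, 0L, rep(1L, 200))
  bal3 <- balance_oversample(big, lab_big, seed = 3)
  added <- bal3$segments[203:nrow(bal3$segments), , drop = FALSE]
  expect_true(all(apply(added, 1L, function(r) {
    any(apply(big[1:2, , drop = FALSE], 1L, function(o) all(o == r)))
  })))
  expect_identical(bal3$origin[203:400] %in% 1:2, rep(TRUE, 198))

  expect_identical(balance_oversample(big, lab_big, seed = 3)$origin, bal3$origin)
  expect_error(balance_oversample(big, rep(1L, 202), seed = 1), "both classes")
})

test_that("min-max normalization maps windows onto [0, 1]", {
  expect_equal(minmax_normalize(c(-1, 0, 1)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(minmax_normalize(c(2, 4, 6, 8)), c(0, 1 / 3, 2 / 3, 1))
  expect_error(minmax_normalize(numeric(0)), "non-empty")

  set.seed(7)
  m <- emgtsci:::normalize_segments(matrix(rnorm(50), 5, 10))
  expect_equal(apply(m, 1L, min), rep(0, 5))
  expect_equal(apply(m, 1L, max), rep(1, 5))
})

test_that("the stratified split is a disjoint, exhaustive, seeded partition", {
  set.seed(9)
  ds <- segment_dataset(matrix(rnorm(100 * 4), 100, 4),
                        rep(c(0L, 1L), each = 50))
  sp <- split_train_test(ds, 0.2, seed = 4)
  expect_identical(nrow(sp$train$segments), 80L)
  expect_identical(nrow(sp$test$segments), 20L)
  expect_identical(sum(sp$test$labels == 0L), 10L)
  expect_identical(sum(sp$test$labels == 1L), 10L)

  all_rows <- rbind(sp$train$segments, sp$test$segments)
  expect_identical(nrow(all_rows), 100L)
  expect_identical(sort(c(rowSums(sp$train$segments), rowSums(sp$test$segments))),
                   sort(rowSums(ds$segments)))

  sp2 <- split_train_test(ds, 0.2, seed = 4)
  expect_identical(sp$test$segments, sp2$test$segments)

  tiny <- segment_dataset(matrix(rnorm(12), 3, 4), c(0L, 1L, 1L))
  expect_error(split_train_test(tiny, 0.2), "fewer than 2")
})

test_that("the end-to-end pre-processing chain emits normalized, balanced, split windows", {
  recs <- generate_dataset(3, 5, simulation_config(duration = 2), seed = 13)
  prep <- preprocess_recordings(recs, window_length = 1000L, seed = 13)
  expect_identical(prep$full$window_length, 1000L)
  # balanced: oversampling lifts the pre-lesion class to the post count
  expect_identical(sum(prep$full$labels == 0L), sum(prep$full$labels == 1L))
  expect_true(all(prep$full$segments >= 0 & prep$full$segments <= 1))
  expect_identical(nrow(prep$train$segments) + nrow(prep$test$segments),
                   nrow(prep$full$segments))

  # mismatched sampling rates are refused, not resampled
  recs2 <- recs
  recs2[[1]]$sampling_rate <- 2000
  expect_error(preprocess_recordings(recs2), "mismatched sampling rates")
})
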