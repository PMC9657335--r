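test_that("the default architecture matches the reference layer table exactly", {
  spec <- default_architecture()
  kinds <- vapply(spec$layers, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "conv1d"), 4L)
  drops <- Filter(function(l) l$kind == "dropout", spec$layers)
  expect_equal(vapply(drops, `[[`, numeric(1), "rate"), c(0.1, 0.1))
  expect_identical(kinds[length(kinds)], "sigmoid")
  expect_identical(spec$layers[[length(spec$layers) - 1L]]$units, 1L)

  sh <- derive_shapes(spec)
  conv_pool <- sh[sh$kind %in% c("conv1d", "maxpool1d"), ]
  expect_identical(conv_pool$length, c(500L, 250L, 125L, 63L, 63L, 32L, 32L, 16L))
  expect_identical(conv_pool$channels, c(32L, 32L, 32L, 32L, 64L, 64L, 128L, 128L))
  expect_identical(sh$channels[sh$kind == "gap"], 128L)
  # stride-1 same-padded convolution preserves temporal length (63 -> 63)
  expect_identical(sh$length[7], 63L)

  pc <- count_parameters(spec)
  expect_identical(pc$per_layer[pc$per_layer > 0],
                   c(192L, 5152L, 6208L, 24704L, 12900L, 101L))
  expect_identical(pc$total, 49257L)
})

test_that("shape derivation rejects impossible architectures", {
  bad <- architecture_spec(4L, list(
    layer_spec("dense", units = 3L)
  ))
  expect_error(derive_shapes(bad), "flattened")
})

test_that("binary cross-entropy matches elementwise brute force", {
  expect_lt(bc_loss(1 - 1e-7, 1), 1e-6)
  expect_equal(bc_loss(0.5, 1), 0.6931472, tolerance = 1e-6)
  expect_equal(bc_loss(c(0.8, 0.2), c(1, 0)), 0.2231436, tolerance = 1e-6)

  set.seed(31)
  for (i in 1:10) {
    n <- sample(1:100, 1)
    y <- runif(n, 1e-6, 1 - 1e-6)
    x <- sample(c(0L, 1L), n, replace = TRUE)
    brute <- -sum(vapply(seq_len(n), function(j) {
      x[j] * log(y[j]) + (1 - x[j]) * log(1 - y[j])
    }, numeric(1))) / n
    expect_equal(bc_loss(y, x), brute, tolerance = 1e-12)
  }
  expect_error(bc_loss(c(0.5, 0.5), 1), "equal length")
})

test_that("backpropagation matches numerical gradients", {
  spec <- small_architecture(20L)
  model <- structure(list(spec = spec,
                          params = emgtsci:::init_cnn_params(spec, 7)),
                     class = "cnn_model")
  set.seed(1)
  x <- matrix(runif(4 * 20), 4, 20)
  y <- c(0, 1, 1, 0)
  fw <- emgtsci:::cnn_forward(model, x, keep_cache = TRUE)
  grads <- emgtsci:::cnn_backward(model, fw$caches, (fw$prob - y) / length(y))
  eps <- 1e-6
  loss_at <- function(m) bc_loss(emgtsci:::cnn_forward(m, x)$prob, y)
  for (i in seq_along(model$params)) {
    if (is.null(model$params[[i]])) next
    for (nm in c("w", "b")) {
      picks <- seq_len(min(length(model$params[[i]][[nm]]), 6L))
      for (j in picks) {
        up <- model; up$params[[i]][[nm]][j] <- up$params[[i]][[nm]][j] + eps
        dn <- model; dn$params[[i]][[nm]][j] <- dn$params[[i]][[nm]][j] - eps
        num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
        expect_equal(grads[[i]][[nm]][j], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("training records history, is seeded-deterministic, and reduces the loss", {
  ds <- make_separable_dataset(40L, 50L)
  sp <- split_train_test(ds, 0.25, seed = 1)
  cfg <- training_config(batch_size = 16L, epochs = 1L, seed = 3)
  m1 <- train_cnn(small_architecture(50L), sp$train, sp$test, cfg)
  expect_identical(nrow(m1$history), 1L)
  expect_identical(names(m1$history),
                   c("epoch", "train_loss", "test_loss", "train_acc", "test_acc"))

  cfg6 <- training_config(batch_size = 16L, epochs = 6L, seed = 3)
  m6a <- train_cnn(small_architecture(50L), sp$train, sp$test, cfg6)
  m6b <- train_cnn(small_architecture(50L), sp$train, sp$test, cfg6)
  expect_equal(m6a$history$train_loss[6], m6b$history$train_loss[6], tolerance = 1e-6)
  expect_equal(m6a$history$test_loss[6], m6b$history$test_loss[6], tolerance = 1e-6)

  # optimization sanity on separable data, across 3 seeds
  for (s in 1:3) {
    cfg_s <- training_config(batch_size = 16L, epochs = 6L, seed = s)
    m <- train_cnn(small_architecture(50L), sp$train, sp$test, cfg_s)
    expect_lt(m$history$train_loss[6], m$history$train_loss[1])
  }
})

test_that("prediction thresholds probabilities at 0.5 toward class 0", {
  ds <- make_separable_dataset(20L, 50L)
  sp <- split_train_test(ds, 0.25, seed = 2)
  m <- train_cnn(small_architecture(50L), sp$train, sp$test,
                 training_config(batch_size = 16L, epochs = 4L, seed = 1))
  pr <- predict_cnn(m, sp$test$segments)
  expect_true(all(pr$probabilities > 0 & pr$probabilities < 1))
  expect_identical(pr$labels, as.integer(pr$probabilities > 0.5))
  expect_error(predict_cnn(m, matrix(0, 2, 49)), "expects")
})

test_that("training history CSV round-trips", {
  ds <- make_separable_dataset(10L, 50L)
  sp <- split_train_test(ds, 0.2, seed = 5)
  m <- train_cnn(small_architecture(50L), sp$train, sp$test,
                 training_config(batch_size = 8L, epochs = 2L, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_history_csv(m, path)
  back <- read.csv(path)
  expect_equal(back$train_loss, m$history$train_loss, tolerance = 1e-12)
})
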