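test_that("motor unit potential template is biphasic, zero-mean and peak-normalized", {
  expect_identical(generate_mup_template(0, 10, 1000), rep(0, 10))

  w1 <- generate_mup_template(1, 10, 1000)
  expect_length(w1, 10L)
  expect_equal(max(abs(w1)), 1, tolerance = 1e-9)
  expect_lt(abs(mean(w1)), 1e-6)
  # biphasic: one positive and one negative lobe
  expect_gt(max(w1), 0)
  expect_lt(min(w1), 0)

  # linearity oracle: doubling the amplitude doubles every sample
  w2 <- generate_mup_template(2, 10, 1000)
  expect_equal(w2, 2 * w1, tolerance = 1e-12)

  expect_error(generate_mup_template(1, -5, 1000), "invalid argument")
  expect_error(generate_mup_template(1, 10, 0), "invalid argument")
})

test_that("firing trains are strictly increasing, seeded, with the right rate", {
  expect_identical(generate_firing_train(10, 0, seed = 1), numeric(0))
  expect_identical(generate_firing_train(0, 5, seed = 1), numeric(0))
  expect_error(generate_firing_train(-1, 5), "invalid argument")

  tr <- generate_firing_train(10, 100, jitter_cv = 0.1, seed = 3)
  expect_true(all(diff(tr) > 0))
  expect_true(all(tr >= 0 & tr < 100))
  expect_identical(tr, generate_firing_train(10, 100, jitter_cv = 0.1, seed = 3))

  # count oracle: expected rate * duration = 1000 discharges; direct
  # simulation over 50 seeds must stay within +/- 20%
  counts <- vapply(1:50, function(s) {
    length(generate_firing_train(10, 100, jitter_cv = 0.1, seed = s))
  }, numeric(1))
  expect_true(all(counts >= 800 & counts <= 1200))
  expect_equal(mean(counts), 1000, tolerance = 0.05)

  # inter-pulse interval variability tracks the requested CV
  ipi <- diff(generate_firing_train(10, 500, jitter_cv = 0.2, seed = 9))
  expect_equal(sd(ipi) / mean(ipi), 0.2, tolerance = 0.15)
})

test_that("a recording with no motor units is pure Gaussian noise at the requested level", {
  cfg <- simulation_config(duration = 10, n_motor_units = 0, noise_sigma = 1, seed = 11)
  rec <- synthesize_recording(cfg)
  expect_length(rec$samples, 10000L)
  rms <- sqrt(mean(rec$samples^2))
  expect_gte(rms, 0.95)
  expect_lte(rms, 1.05)
})

test_that("recordings are bit-identical under the same seed and labelled by lesion", {
  cfg <- simulation_config(duration = 1, seed = 5)
  expect_identical(synthesize_recording(cfg)$samples, synthesize_recording(cfg)$samples)
  expect_identical(synthesize_recording(cfg)$label, 0L)

  cfg_post <- cfg
  cfg_post$lesion <- lesion_regime()
  expect_identical(synthesize_recording(cfg_post)$label, 1L)
})

test_that("the lesion regime reduces signal power (direct simulation oracle)", {
  rms_pair <- vapply(1:50, function(s) {
    pre <- simulation_config(duration = 1, seed = s)
    post <- pre
    post$lesion <- lesion_regime(0.5, 0.8, 0.6)
    c(sqrt(mean(synthesize_recording(pre)$samples^2)),
      sqrt(mean(synthesize_recording(post)$samples^2)))
  }, numeric(2))
  expect_gt(mean(rms_pair[1, ]), mean(rms_pair[2, ]))
})

test_that("recording power is monotone in motor unit count and amplitude scale", {
  mean_rms <- function(n_mu, amp_scale) {
    mean(vapply(1:20, function(s) {
      cfg <- simulation_config(duration = 1, n_motor_units = n_mu,
                               noise_sigma = 0, seed = s,
                               lesion = lesion_regime(1, 1, amp_scale))
      sqrt(mean(synthesize_recording(cfg)$samples^2))
    }, numeric(1)))
  }
  expect_lte(mean_rms(5, 1), mean_rms(15, 1))
  expect_lte(mean_rms(15, 1e-6), mean_rms(15, 0.5))
  expect_lte(mean_rms(15, 0.5), mean_rms(15, 1))
})

test_that("identity lesion regime reproduces pre-lesion samples exactly", {
  pre <- simulation_config(duration = 1, seed = 21)
  post <- pre
  post$lesion <- lesion_regime(1, 1, 1)
  expect_equal(synthesize_recording(post)$samples, synthesize_recording(pre)$samples)
})

test_that("noiseless synthetic EMG keeps >= 80% of its power in 10-450 Hz", {
  cfg <- simulation_config(duration = 4, noise_sigma = 0, seed = 8)
  x <- synthesize_recording(cfg)$samples
  sp <- stats::spec.pgram(stats::ts(x, frequency = 1000), taper = 0, plot = FALSE)
  in_band <- sp$freq >= 10 & sp$freq <= 450
  expect_gte(sum(sp$spec[in_band]) / sum(sp$spec), 0.8)
})

test_that("generate_dataset delivers the requested labelled counts deterministically", {
  expect_identical(generate_dataset(0, 0, seed = 1), list())

  base <- simulation_config(duration = 0.5)
  ds <- generate_dataset(3, 5, base, lesion_regime(), seed = 7)
  labels <- vapply(ds, `[[`, integer(1), "label")
  expect_identical(sum(labels == 0L), 3L)
  expect_identical(sum(labels == 1L), 5L)

  ds2 <- generate_dataset(3, 5, base, lesion_regime(), seed = 7)
  expect_identical(lapply(ds, `[[`, "samples"), lapply(ds2, `[[`, "samples"))

  # distinct recordings draw distinct per-recording seeds
  expect_false(identical(ds[[1]]$samples, ds[[2]]$samples))
})

test_that("recording text files round-trip losslessly", {
  rec <- synthesize_recording(simulation_config(duration = 0.3, seed = 2),
                              meta = list(subject = 4, side = "left", day = 12))
  path <- withr::local_tempfile(fileext = ".txt")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_identical(back$label, rec$label)
  expect_identical(back$sampling_rate, rec$sampling_rate)
  expect_identical(back$meta$side, "left")

  dir <- withr::local_tempdir()
  ds <- generate_dataset(2, 2, simulation_config(duration = 0.2), seed = 3)
  write_dataset(ds, dir)
  back_ds <- read_dataset(dir)
  expect_identical(vapply(back_ds, `[[`, integer(1), "label"),
                   vapply(ds, `[[`, integer(1), "label"))
  expect_equal(back_ds[[3]]$samples, ds[[3]]$samples, tolerance = 1e-12)
})
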