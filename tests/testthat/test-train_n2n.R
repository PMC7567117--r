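# Normalization, patch sampling, augmentation, losses, and the Adagrad loop.

test_that("normalize_image gives population mean 0 / sd 1 and inverts", {
  r <- normalize_image(matrix(c(0, 2, 0, 2), 2, 2))
  expect_equal(as.vector(r$data), c(-1, 1, -1, 1))
  expect_equal(r$stats, list(mean = 1, std = 1))

  x <- matrix(rnorm(128 * 128, 5, 3), 128, 128)
  r <- normalize_image(x)
  expect_lt(abs(mean(r$data)), 1e-6)
  expect_lt(abs(sqrt(mean(r$data^2)) - 1), 1e-6)
  expect_equal(denormalize_image(r$data, r$stats), x, tolerance = 1e-12)

  r2 <- normalize_image(r$data)  # idempotent on normalized data
  expect_equal(r2$data, r$data, tolerance = 1e-9)
  expect_equal(r2$stats$mean, 0, tolerance = 1e-9)
  expect_equal(r2$stats$std, 1, tolerance = 1e-9)

  expect_error(normalize_image(matrix(3, 4, 4)), "degenerate")
})

test_that("patch sampling is aligned, uniform, and seed-deterministic", {
  pair <- noise_pair(matrix(rnorm(60 * 60), 60, 60),
                     matrix(rnorm(60 * 60), 60, 60))
  # patch == image: single valid position
  full <- cryodenoise:::with_seed(1, sample_patch_pairs(pair, 60L, 3L))
  for (p in full) {
    expect_identical(p$a, pair$even$data)
    expect_identical(p$b, pair$odd$data)
    expect_equal(c(p$y0, p$x0), c(0L, 0L))
  }
  # alignment: both patches cut at identical coordinates
  ps <- cryodenoise:::with_seed(2, sample_patch_pairs(pair, 20L, 5L))
  for (p in ps) {
    expect_identical(p$a, pair$even$data[p$y0 + 1:20, p$x0 + 1:20])
    expect_identical(p$b, pair$odd$data[p$y0 + 1:20, p$x0 + 1:20])
  }
  expect_identical(cryodenoise:::with_seed(7, sample_patch_pairs(pair, 20L, 10L)),
                   cryodenoise:::with_seed(7, sample_patch_pairs(pair, 20L, 10L)))
  # uniformity of top-left corners over the valid 9x9 grid (chi-square)
  draws <- cryodenoise:::with_seed(3, sample_patch_pairs(pair, 52L, 6000L))
  cells <- table(factor(vapply(draws, function(p) p$y0 * 9 + p$x0, numeric(1)),
                        levels = 0:80))
  chi2 <- sum((cells - 6000 / 81)^2 / (6000 / 81))
  expect_lt(chi2, qchisq(0.99, df = 80))
  expect_warning(sample_patch_pairs(pair, 100L, 1L), "shrunk")
})

test_that("augmentation is the dihedral group acting identically on both", {
  m <- matrix(as.numeric(1:9), 3, 3)
  r90 <- cryodenoise:::apply_dihedral
  expect_identical(r90(r90(r90(r90(m, 1), 1), 1), 1), m)   # 4 x 90 deg
  expect_identical(r90(r90(m, 4), 4), m)                   # mirror twice
  arr <- lapply(0:7, function(t) r90(m, t))
  expect_equal(length(unique(arr)), 8L)                    # all distinct
  for (a in arr) expect_identical(sort(as.vector(a)), sort(as.vector(m)))
  # the same transform is applied to both patches
  out <- cryodenoise:::with_seed(5, augment_pair(m, m + 100))
  expect_identical(out$b - 100, out$a)
  expect_error(augment_pair(matrix(1:6, 2, 3), matrix(1:6, 2, 3),
                            transform = 1L), "non-square")
})

test_that("pair_loss matches its definitions", {
  expect_equal(pair_loss(matrix(1, 3, 3), matrix(1, 3, 3), "l2"), 0)
  expect_equal(pair_loss(matrix(1, 3, 3), matrix(1, 3, 3), "l1"), 0)
  expect_equal(pair_loss(matrix(1, 3, 3), matrix(1, 3, 3), "l0"), 81e-16,
               tolerance = 1e-3)
  p <- matrix(c(0, 2), 1, 2); t <- matrix(c(1, 1), 1, 2)
  expect_equal(pair_loss(p, t, "l1"), 1)
  expect_equal(pair_loss(p, t, "l2"), 1)
  expect_error(pair_loss(matrix(1, 2, 2), matrix(1, 3, 3), "l2"), "mismatch")
})

test_that("L2 loss of normalized images equals 2 - 2 * CCC", {
  for (i in 1:20) {
    a <- normalize_image(matrix(rnorm(32 * 32), 32, 32))$data
    b <- normalize_image(matrix(rnorm(32 * 32), 32, 32))$data
    expect_equal(pair_loss(a, b, "l2"), 2 - 2 * ccc(a, b), tolerance = 1e-10)
  }
})

test_that("training is bitwise deterministic given the seeds", {
  pairs <- tiny_pairs(4L, h = 48L, w = 48L)
  cfg <- train_config(loss_mode = "l1", lr = 0.01, epochs = 3L, batch = 2L,
                      patch = 48L, seed = 9L)
  spec <- model_spec("unet_small", base_width = 4L, depth = 2L, seed = 4L)
  f1 <- train_denoiser(pairs, spec, cfg)
  f2 <- train_denoiser(pairs, spec, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("training reduces held-out Noise2Noise loss below untrained", {
  pairs <- tiny_pairs(6L, h = 48L, w = 48L, snr = 0.3, seed = 21L)
  hold <- tiny_pairs(2L, h = 48L, w = 48L, snr = 0.3, seed = 77L)
  spec <- model_spec("unet_small", base_width = 4L, depth = 2L, seed = 4L)
  cfg <- train_config(loss_mode = "l2", lr = 0.01, epochs = 6L, batch = 2L,
                      patch = 48L, seed = 1L)
  fit <- train_denoiser(pairs, spec, cfg, val_pairs = hold)
  untrained <- build_model(spec)
  base <- mean(vapply(hold, function(p) {
    a <- normalize_image(p$even$data)$data
    b <- normalize_image(p$odd$data)$data
    0.5 * (pair_loss(forward(untrained, a), b, "l2") +
           pair_loss(forward(untrained, b), a, "l2"))
  }, numeric(1)))
  val <- attr(fit$history, "val")
  expect_equal(length(fit$history), 6L)
  expect_lt(val[6], base)
  expect_lt(fit$history[6], fit$history[1])
})

test_that("loss symmetry: swapping halves leaves the training loss equal", {
  pairs <- tiny_pairs(3L, h = 32L, w = 32L, seed = 8L)
  swapped <- lapply(pairs, function(p) noise_pair(p$odd, p$even))
  cfg <- train_config(lr = 0.01, epochs = 2L, batch = 3L, patch = 32L,
                      augment = FALSE, seed = 2L)
  spec <- model_spec("affine", seed = 1L)
  f1 <- train_denoiser(pairs, spec, cfg)
  f2 <- train_denoiser(swapped, spec, cfg)
  expect_equal(f1$history, f2$history, tolerance = 1e-12)
})

test_that("configuration errors are caught early", {
  pairs <- tiny_pairs(2L, h = 32L, w = 32L)
  expect_error(train_denoiser(pairs, model_spec("affine"),
                              train_config(patch = 16L)),
               "receptive field")
  expect_error(train_config(loss_mode = "huber"), "l1")
})
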