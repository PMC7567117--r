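# Architectures: parameter counts, shape preservation, receptive fields
# (against a brute-force influence-footprint oracle), checkpoints.

test_that("affine model has exactly one 31x31 kernel plus bias", {
  m <- build_model(model_spec("affine"))
  expect_equal(n_parameters(m), 31 * 31 + 1)
  expect_equal(unname(dim(m$params$out$w)), c(31L, 31L, 1L, 1L))
  # stated init: affine weights start at zero -> output is identically zero
  x <- matrix(rnorm(40 * 40), 40, 40)
  expect_true(all(forward(m, x) == 0))
})

test_that("identity-impulse affine kernel is the identity map", {
  m <- build_model(model_spec("affine"))
  m$params$out$w[16, 16, 1, 1] <- 1
  x <- matrix(rnorm(50 * 37), 50, 37)
  expect_equal(forward(m, x), x, tolerance = 1e-12)
})

test_that("unknown architectures are refused with the valid list", {
  expect_error(model_spec("resnet"), "affine.*unet")
})

test_that("all architectures preserve spatial shape", {
  x <- matrix(rnorm(64 * 64), 64, 64)
  for (arch in c("affine", "fcnn", "constant")) {
    m <- seeded_model(arch)
    expect_identical(dim(forward(m, x)), dim(x))
  }
  # pooled models, including sides not divisible by 2^depth
  m <- seeded_model("unet_small", base_width = 4L)
  expect_identical(dim(forward(m, x)), dim(x))
  odd <- matrix(rnorm(50 * 70), 50, 70)
  expect_identical(dim(forward(m, odd)), dim(odd))
  m3 <- seeded_model("unet3d", base_width = 2L, depth = 2L)
  v <- array(rnorm(24^3), c(24, 24, 24))
  expect_identical(dim(forward(m3, v)), dim(v))
  v2 <- array(rnorm(20 * 24 * 28), c(20, 24, 28))
  expect_identical(dim(forward(m3, v2)), dim(v2))
  expect_error(forward(m3, x), "3D model")
  expect_error(forward(m, v), "2D model")
})

test_that("receptive fields match the stacked-convolution recurrence", {
  expect_equal(receptive_field(model_spec("affine")), 31L)
  expect_equal(receptive_field(model_spec("fcnn")), 31L)  # 11 + 10 + 10
  expect_equal(receptive_field(model_spec("constant")), 1L)
})

test_that("influence footprint never exceeds the computed receptive field", {
  # brute-force oracle: perturb one pixel, measure the output footprint
  footprint <- function(m, n) {
    x <- matrix(rnorm(n * n), n, n)
    x2 <- x; x2[n %/% 2, n %/% 2] <- x2[n %/% 2, n %/% 2] + 1
    d <- abs(forward(m, x2) - forward(m, x)) > 1e-12
    idx <- which(d, arr.ind = TRUE)
    max(max(idx[, 1]) - min(idx[, 1]), max(idx[, 2]) - min(idx[, 2])) + 1L
  }
  m <- seeded_model("fcnn")
  expect_equal(footprint(m, 64L), 31L)
  m <- seeded_model("unet_small", base_width = 3L)
  rf <- m$receptive_field
  span <- footprint(m, 160L)
  expect_lte(span, rf)
  expect_gte(span, rf - 2L * m$align)  # bound is tight up to pool alignment
})

test_that("pure convolution stacks are translation equivariant off-border", {
  m <- seeded_model("fcnn")
  n <- 72L; s <- 8L
  x <- matrix(rnorm(n * n), n, n)
  xs <- matrix(0, n, n); xs[(s + 1):n, ] <- x[1:(n - s), ]
  y <- forward(m, x); ys <- forward(m, xs)
  core <- (16 + s + 1):(n - 16)
  expect_equal(ys[core, 17:(n - 16)], y[core - s, 17:(n - 16)],
               tolerance = 1e-10)
})

test_that("checkpoints round trip spec and parameters", {
  tmp <- withr::local_tempfile(fileext = ".ckpt")
  m <- seeded_model("unet_small", base_width = 4L)
  save_denoiser(m, tmp)
  m2 <- load_denoiser(tmp)
  expect_identical(m2$params, m$params)
  expect_identical(m2$spec, m$spec)
  x <- matrix(rnorm(32 * 32), 32, 32)
  expect_identical(forward(m2, x), forward(m, x))
  saveRDS(list(a = 1), tmp)
  expect_error(load_denoiser(tmp), "not a cryodenoise checkpoint")
})

test_that("forward refuses degenerate inputs", {
  m <- seeded_model("fcnn")
  expect_error(forward(m, matrix(numeric(0), 0, 0)), "zero-extent")
})
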