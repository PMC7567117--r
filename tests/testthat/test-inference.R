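# Tile planning and stitch-exact padded inference.

test_that("plan_tiles enumerates half-open cores that partition the image", {
  plan <- plan_tiles(c(100L, 100L), patch = 40L, pad = 10L)
  ax <- plan$axes[[1]]
  expect_equal(ax$core0, c(0L, 40L, 80L))
  expect_equal(ax$core1, c(40L, 80L, 100L))
  expect_equal(ax$pad0, c(0L, 30L, 70L))
  expect_equal(ax$pad1, c(50L, 90L, 100L))

  one <- plan_tiles(c(4000L, 4000L), patch = 4000L, pad = 500L)
  expect_equal(nrow(one$axes[[1]]), 1L)
  expect_equal(one$axes[[1]]$core1, 4000L)

  p0 <- plan_tiles(c(64L, 64L), patch = 32L, pad = 0L)
  expect_identical(p0$axes[[1]]$pad0, p0$axes[[1]]$core0)
  expect_identical(p0$axes[[1]]$pad1, p0$axes[[1]]$core1)

  # alignment rounding for pooled models: pad up, patch down
  pa <- plan_tiles(c(128L, 128L), patch = 50L, pad = 10L, align = 16L)
  expect_equal(pa$patch, 48L)
  expect_equal(pa$pad, 16L)
})

test_that("single-tile denoise equals the whole-image forward pass bitwise", {
  m <- seeded_model("fcnn")
  x <- matrix(rnorm(64 * 64), 64, 64)
  nz <- normalize_image(x)
  manual <- denormalize_image(forward(m, nz$data), nz$stats)
  expect_identical(denoise_image(m, x, patch = 64L, pad = 0L), manual)
  expect_identical(denoise_image(m, x, patch = 100L, pad = 500L), manual)
})

test_that("pad >= ceil(RF/2) makes patched output equal the whole image", {
  m <- seeded_model("fcnn")
  x <- matrix(rnorm(96 * 96), 96, 96)
  whole <- denoise_image(m, x, patch = 96L)
  pad <- ceiling(m$receptive_field / 2)
  tiled <- denoise_image(m, x, patch = 48L, pad = pad)
  expect_lt(max(abs(tiled - whole)), 1e-10)
  # negative control: unpadded tiles leave visible seams
  seam <- max(abs(denoise_image(m, x, patch = 48L, pad = 0L) - whole))
  expect_gt(seam, 1e-6)
  # output invariant to the patch size given sufficient padding
  tiled2 <- denoise_image(m, x, patch = 32L, pad = pad)
  expect_lt(max(abs(tiled2 - whole)), 1e-10)
})

test_that("volume tiling matches the whole-volume oracle", {
  m <- seeded_model("unet3d", base_width = 3L, depth = 2L)
  v <- array(rnorm(40^3), c(40, 40, 40))
  whole <- denoise_volume(m, v, patch = 40L)
  tiled <- denoise_volume(m, v, patch = 20L)  # default pad = ceil(rf/2)
  expect_lt(max(abs(tiled - whole)), 1e-10)
  expect_identical(dim(tiled), dim(v))
  expect_error(denoise_volume(seeded_model("fcnn"), v), "2D")
  expect_error(denoise_image(m, matrix(rnorm(16), 4, 4)), "3D")
})

test_that("denoising commutes with affine intensity rescaling", {
  m <- seeded_model("affine")
  x <- matrix(rnorm(48 * 48), 48, 48)
  y <- denoise_image(m, x, patch = 48L)
  y2 <- denoise_image(m, 3.5 * x + 11, patch = 48L)
  expect_equal(y2, 3.5 * y + 11, tolerance = 1e-9)
})

test_that("constant images are refused (normalization degenerate)", {
  m <- seeded_model("affine")
  expect_error(denoise_image(m, matrix(2, 32, 32)), "degenerate")
})

test_that("image_plane containers pass through with metadata intact", {
  m <- seeded_model("fcnn")
  img <- image_plane(matrix(rnorm(32 * 32), 32, 32), pixel_size = 0.9,
                     origin_name = "t")
  out <- denoise_image(m, img, patch = 32L)
  expect_s3_class(out, "image_plane")
  expect_equal(out$pixel_size, 0.9)
})
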