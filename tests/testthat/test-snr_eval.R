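# Both SNR estimators, low-pass baselines, display scaling.

test_that("ccc is the Pearson correlation with hand-checked values", {
  a <- matrix(rnorm(64), 8, 8)
  expect_equal(ccc(a, a), 1)
  expect_equal(ccc(a, -a), -1)
  expect_equal(ccc(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1)
  expect_equal(ccc(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(ccc(matrix(1, 2, 2), matrix(rnorm(4), 2, 2)), "constant")
  expect_error(ccc(matrix(rnorm(4), 2, 2), matrix(rnorm(9), 3, 3)),
               "mismatch")
})

test_that("snr_split implements 10*log10(p / (1 - p)) with sentinels", {
  # exact correlations from orthogonal equal-norm constructions
  u <- c(1, -1, 1, -1); v <- c(1, 1, -1, -1)
  mk <- function(p) p * u + sqrt(1 - p^2) * v
  expect_equal(as.numeric(snr_split(u, mk(0.5))), 0)
  expect_equal(as.numeric(snr_split(u, mk(0.9))), 10 * log10(9),
               tolerance = 1e-9)            # 9.542 dB
  expect_equal(attr(snr_split(u, mk(0.9)), "ccc"), 0.9)
  expect_identical(as.numeric(snr_split(u, u)), Inf)
  expect_warning(db <- snr_split(u, mk(-0.4)), "non-positive")
  expect_identical(as.numeric(db), -Inf)
  # strictly increasing in p
  ps <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  dbs <- vapply(ps, function(p) as.numeric(snr_split(u, mk(p))), numeric(1))
  expect_true(all(diff(dbs) > 0))
})

region_fixture <- function() {
  img <- matrix(0, 2, 4)
  img[, 1:2] <- 3                 # signal region: all 3s
  img[, 3:4] <- c(0, 2, 0, 2)     # background: mean 1, population variance 1
  regions <- data.frame(
    image_name = "img", role = c("signal", "background"), pair_id = 1L,
    x0 = c(0L, 2L), y0 = 0L, x1 = c(2L, 4L), y1 = 2L)
  list(img = img, regions = regions)
}

test_that("snr_regions reproduces the hand-computed fixture", {
  f <- region_fixture()
  rep <- snr_regions(list(img = f$img), f$regions)
  expect_equal(rep$mean_db, 10 * log10(4), tolerance = 1e-12)  # 6.021 dB
  # two identical pairs -> mean equals the single-pair value
  r2 <- rbind(f$regions, transform(f$regions, pair_id = 2L))
  expect_equal(snr_regions(list(img = f$img), r2)$mean_db, rep$mean_db)
  # gain invariance under affine intensity rescaling
  rep2 <- snr_regions(list(img = 17.3 * f$img), f$regions)
  expect_equal(rep2$mean_db, rep$mean_db, tolerance = 1e-9)
})

test_that("snr_regions flags degenerate regions", {
  f <- region_fixture()
  img <- f$img; img[, 3:4] <- 5  # zero background variance
  expect_error(snr_regions(list(img = img), f$regions), "variance")
  bad <- f$regions; bad$x1 <- c(2L, 40L)
  expect_error(snr_regions(list(img = f$img), bad), "bounds")
  img2 <- f$img; img2[, 1:2] <- 1  # signal mean == background mean
  expect_warning(rep <- snr_regions(list(img = img2), f$regions), "equals")
  expect_identical(rep$items, -Inf)
})

test_that("region TSV files round trip through read_regions", {
  f <- region_fixture()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write.table(f$regions, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_regions(tmp), f$regions, ignore_attr = TRUE)
  bad <- f$regions; bad$role <- "blob"
  write.table(bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_regions(tmp), "signal")
})

test_that("lowpass_bin band-limits at Nyquist / factor", {
  x <- matrix(rnorm(64 * 64), 64, 64)
  expect_equal(lowpass_bin(x, 1L), x, tolerance = 1e-10)
  expect_equal(lowpass_bin(matrix(3, 32, 32), 16L), matrix(3, 32, 32),
               tolerance = 1e-12)
  grid <- outer(rep(1, 64), 0:63)
  hi <- sin(2 * pi * 20 * grid / 64)   # |f| = 20/64 of axis, cutoff 2/64
  lo <- sin(2 * pi * 1 * grid / 64)
  expect_lt(mean(lowpass_bin(hi, 16L)^2), 1e-6 * mean(hi^2))
  expect_equal(lowpass_bin(lo, 16L), lo, tolerance = 1e-6)
  expect_error(lowpass_bin(x, 100L), "exceeds")
  expect_error(lowpass_bin(x, 2.5), "integer")
})

test_that("lowpass_gaussian halves amplitude at the cutoff", {
  x <- matrix(rnorm(48 * 48), 48, 48)
  expect_equal(lowpass_gaussian(matrix(2, 24, 24), 0.125),
               matrix(2, 24, 24), tolerance = 1e-12)
  grid <- outer(rep(1, 64), 0:63)
  s <- sin(2 * pi * 4 * grid / 64)     # f = 4/32 Nyquist = 0.125
  out <- lowpass_gaussian(s, 0.125)
  expect_equal(max(abs(out)) / max(abs(s)), 0.5, tolerance = 0.02)
  expect_equal(lowpass_gaussian(x, 100), x, tolerance = 1e-3)
  expect_error(lowpass_gaussian(x, 0), "cutoff")
})

test_that("scale_display buckets standardized intensities into 0..255", {
  ref <- matrix(rnorm(32 * 32, 10, 2), 32, 32)
  img <- matrix(mean(ref), 32, 32); img[1, 1] <- 100; img[1, 2] <- -100
  b <- scale_display(img, reference = ref)
  expect_equal(b[2, 2], 128L)     # pixel at the reference mean
  expect_equal(b[1, 1], 255L)     # z >= 4 clamps high
  expect_equal(b[1, 2], 0L)       # z <= -4 clamps low
  z <- seq(-5, 5, length.out = 101)
  bz <- scale_display(matrix(mean(ref) + z * sd(ref), 1), reference = ref)
  expect_true(all(diff(as.vector(bz)) >= 0))  # monotone
  expect_error(scale_display(img, reference = matrix(1, 2, 2)), "constant")
})

test_that("dose_titration validates fractions and reports per method", {
  stk <- tiny_stack(n_frames = 20L, h = 24L, w = 24L)
  expect_error(dose_titration(stk, c(1.0)), "0.5")
  expect_warning(tab <- dose_titration(stk, c(0.01, 0.5)), "skipped")
  expect_equal(nrow(tab), 1L)
  tab <- dose_titration(stk, c(0.25, 0.5),
                        methods = list(raw = identity,
                                       lp = function(x) lowpass_bin(x, 4L)))
  expect_equal(tab$frames, c(5L, 10L))
  expect_true(all(c("raw", "lp") %in% names(tab)))
})
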