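# Scene generation, movie rendering, and the analytic SNR oracle.

test_that("scenes are reproducible and analytically calibrated", {
  sc0 <- make_scene_2d(64, 64, n_particles = 0L)
  expect_true(all(sc0$signal$data == 1))
  s1 <- make_scene_2d(96, 96, n_particles = 5L, seed = 4L)
  s2 <- make_scene_2d(96, 96, n_particles = 5L, seed = 4L)
  expect_identical(s1$signal$data, s2$signal$data)
  expect_false(identical(s1$signal$data,
                         make_scene_2d(96, 96, n_particles = 5L,
                                       seed = 5L)$signal$data))
  # integrated deficit below background = n * contrast * 2*pi*sigma^2
  sc <- make_scene_2d(128, 128, n_particles = 6L, radius_px = 6,
                      contrast = 0.8, seed = 2L)
  deficit <- sum(sc$background - sc$signal$data)
  expect_equal(deficit, 6 * 0.8 * 2 * pi * 3^2, tolerance = 1e-6)
  # particles darker than background (phase-contrast convention)
  expect_lt(min(sc$signal$data), sc$background)
  expect_lte(max(sc$signal$data), sc$background)
})

test_that("3D scenes mirror the 2D contract with spherical blobs", {
  sc0 <- make_scene_3d(32, 32, 32, n_particles = 0L)
  expect_true(all(sc0$signal$data == 1))
  sc <- make_scene_3d(56, 56, 56, n_particles = 3L, radius_px = 4,
                      contrast = 1, seed = 3L)
  expect_identical(sc$signal$data,
                   make_scene_3d(56, 56, 56, n_particles = 3L, radius_px = 4,
                                 contrast = 1, seed = 3L)$signal$data)
  deficit <- sum(sc$background - sc$signal$data)
  expect_equal(deficit, 3 * (2 * pi)^1.5 * 2^3, tolerance = 1e-6)
})

test_that("render_movie draws independent frames, bitwise reproducibly", {
  sc <- make_scene_2d(64, 64, n_particles = 3L, seed = 1L)
  s1 <- render_movie(sc, 6L, noise_model("gaussian", read_std = 2), seed = 9L)
  s2 <- render_movie(sc, 6L, noise_model("gaussian", read_std = 2), seed = 9L)
  for (i in 1:6) expect_identical(s1$frames[[i]], s2$frames[[i]])
  # noiseless limit: high-count Poisson, no readout noise
  clean <- render_movie(sc, 4L,
                        noise_model("poisson_gaussian", read_std = 0,
                                    counts_per_frame = 1e9), seed = 2L)
  pair <- split_even_odd(clean)
  expect_gt(ccc(pair$even, pair$odd), 0.999)
  # negative signal under Poisson is refused
  dark <- make_scene_2d(64, 64, n_particles = 1L, contrast = 2, seed = 1L,
                        background = 0.5)
  expect_error(render_movie(dark, 2L, noise_model("poisson_gaussian")),
               "offset")
})

test_that("noise in the two halves is independent", {
  sc <- make_scene_2d(128, 128, n_particles = 4L, seed = 6L)
  stk <- render_movie(sc, 20L, noise_model("gaussian", read_std = 3),
                      seed = 12L)
  pair <- split_even_odd(stk)
  ne <- 10; no <- 10
  resid_e <- pair$even$data - ne * sc$signal$data
  resid_o <- pair$odd$data - no * sc$signal$data
  expect_lt(abs(ccc(resid_e, resid_o)), 3 / sqrt(128 * 128))
})

test_that("expected_pair_snr follows the variance algebra", {
  sc <- make_scene_2d(96, 96, n_particles = 4L, seed = 2L)
  V <- mean((sc$signal$data - mean(sc$signal$data))^2)
  nm0 <- noise_model("gaussian", read_std = sqrt(10 * V))  # ne*s2 == ne^2*V
  expect_equal(expected_pair_snr(sc, nm0, 20L), 0, tolerance = 1e-10)
  # doubling the frame count adds 10*log10(2) dB
  nm <- noise_model("gaussian", read_std = 4)
  expect_equal(expected_pair_snr(sc, nm, 40L) - expected_pair_snr(sc, nm, 20L),
               10 * log10(2), tolerance = 0.02)
  expect_identical(expected_pair_snr(sc, noise_model("gaussian",
                                                     read_std = 0), 10L), Inf)
  flat <- make_scene_2d(64, 64, n_particles = 0L)
  expect_identical(expected_pair_snr(flat, nm, 10L), -Inf)
  # noise_std_for_snr inverts the relationship
  sdf <- noise_std_for_snr(sc, 40L, 0.1)
  expect_equal(expected_pair_snr(sc, noise_model("gaussian", read_std = sdf),
                                 40L), 10 * log10(0.1), tolerance = 1e-9)
})

test_that("simulate_pairs produces shape-consistent independent pairs", {
  sim <- simulate_pairs(3L, h = 48L, w = 40L, n_frames = 6L, snr = 0.5,
                        n_particles = 2L, radius_px = 4, seed = 5L)
  expect_length(sim$pairs, 3L)
  for (p in sim$pairs) expect_identical(dim(p$even$data), c(48L, 40L))
  expect_false(identical(sim$pairs[[1]]$even$data, sim$pairs[[2]]$even$data))
})
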