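# Synthetic scenes, movie stacks and noise pairs with known ground truth and
# known SNR, so that training, inference and both SNR estimators can be
# validated end to end without any external data.
#
# A scene is a smooth particle-like signal: Gaussian blobs of amplitude
# `contrast` *below* a constant background (phase-contrast convention:
# particles are darker). Each movie frame is an independent noisy draw of the
# same scene; frames sum to a full-dose micrograph.

#' Gaussian blob kernel scale used by the scene generators
#' @noRd
blob_sigma <- function(radius_px) radius_px / 2

#' Noise model for synthetic movie frames
#'
#' `gaussian`: frame = signal + N(0, read_std^2) per pixel.
#' `poisson_gaussian`: frame = Pois(counts_per_frame * signal) /
#' counts_per_frame + N(0, read_std^2) -- low-count shot noise plus readout
#' noise.
#'
#' @param kind `"gaussian"` or `"poisson_gaussian"`.
#' @param read_std additive readout noise sd (>= 0).
#' @param counts_per_frame mean electron count scale (> 0, Poisson only).
#' @return a `cdn_noise_model`.
#' @export
noise_model <- function(kind = c("gaussian", "poisson_gaussian"),
                        read_std = 1, counts_per_frame = 10) {
  kind <- match.arg(kind)
  stopifnot(read_std >= 0, counts_per_frame > 0)
  structure(list(kind = kind, read_std = read_std,
                 counts_per_frame = counts_per_frame),
            class = "cdn_noise_model")
}

place_centers <- function(extents, n, min_dist, margin, ndim) {
  centers <- matrix(numeric(0), ncol = ndim)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(50L)) {
      cand <- vapply(extents, function(e) runif(1, margin, e - 1 - margin),
                     numeric(1))
      if (nrow(centers) == 0L ||
          min(sqrt(rowSums((centers - matrix(cand, nrow(centers), ndim,
                                             byrow = TRUE))^2))) >= min_dist) {
        placed <- TRUE
        break
      }
    }
    if (!placed)
      warning("could not separate all particles; placing with overlap")
    centers <- rbind(centers, cand)
  }
  centers
}

#' Generate a 2D scene of particle-like blobs
#'
#' Particles are isotropic Gaussian blobs (sd = `radius_px / 2`) of amplitude
#' `contrast` below a constant background, placed uniformly with a 3-radius
#' margin so each blob fits in the frame. The integrated signal deficit is
#' `n_particles * contrast * 2 * pi * sigma^2` to high accuracy.
#'
#' @param h,w frame extents in pixels.
#' @param n_particles number of blobs (0 gives a constant background).
#' @param radius_px particle radius; blob sd is half of it.
#' @param contrast blob depth below background.
#' @param seed RNG seed.
#' @param background background level (kept positive so Poisson noise is
#'   well defined).
#' @return a `cdn_scene` with fields `signal` ([image_plane()]), `centers`
#'   (0-based), `radius_px`, `contrast`, `background`.
#' @export
make_scene_2d <- function(h, w, n_particles = 8L, radius_px = 6,
                          contrast = 1, seed = 0L, background = 1) {
  margin <- 3 * radius_px
  if (n_particles > 0L && (h <= 2 * margin || w <= 2 * margin))
    stop("make_scene_2d: frame too small for the particle margin")
  sig <- matrix(background, h, w)
  centers <- with_seed(seed,
    place_centers(c(h, w), n_particles, 2 * radius_px, margin, 2L))
  s2 <- 2 * blob_sigma(radius_px)^2
  ys <- seq_len(h) - 1; xs <- seq_len(w) - 1
  for (i in seq_len(nrow(centers))) {
    g <- outer((ys - centers[i, 1])^2, (xs - centers[i, 2])^2, "+")
    sig <- sig - contrast * exp(-g / s2)
  }
  structure(list(signal = image_plane(sig), centers = centers,
                 radius_px = radius_px, contrast = contrast,
                 background = background),
            class = "cdn_scene")
}

#' Generate a 3D scene of spherical blobs
#'
#' 3D analogue of [make_scene_2d()]; blob mass is
#' `contrast * (2*pi)^(3/2) * sigma^3`.
#'
#' @param d,h,w volume extents in voxels.
#' @inheritParams make_scene_2d
#' @return a `cdn_scene` whose `signal` is a [volume()].
#' @export
make_scene_3d <- function(d, h, w, n_particles = 8L, radius_px = 4,
                          contrast = 1, seed = 0L, background = 1) {
  margin <- 3 * radius_px
  if (n_particles > 0L && any(c(d, h, w) <= 2 * margin))
    stop("make_scene_3d: volume too small for the particle margin")
  sig <- array(background, c(d, h, w))
  centers <- with_seed(seed,
    place_centers(c(d, h, w), n_particles, 2 * radius_px, margin, 3L))
  s2 <- 2 * blob_sigma(radius_px)^2
  zs <- seq_len(d) - 1; ys <- seq_len(h) - 1; xs <- seq_len(w) - 1
  for (i in seq_len(nrow(centers))) {
    r2 <- outer(outer((zs - centers[i, 1])^2, (ys - centers[i, 2])^2, "+"),
                (xs - centers[i, 3])^2, "+")
    sig <- sig - contrast * exp(-r2 / s2)
  }
  structure(list(signal = volume(sig), centers = centers,
                 radius_px = radius_px, contrast = contrast,
                 background = background),
            class = "cdn_scene")
}

scene_signal_data <- function(scene) {
  if (inherits(scene$signal, "image_plane") || inherits(scene$signal, "volume"))
    scene$signal$data else scene$signal
}

#' Render a movie stack from a scene
#'
#' Each frame is an independent noisy observation of the same signal; frames
#' are mutually independent given the scene, so even/odd sums form a valid
#' Noise2Noise pair.
#'
#' @param scene a 2D `cdn_scene` from [make_scene_2d()].
#' @param n_frames number of frames (>= 2 for pairing use).
#' @param noise a [noise_model()].
#' @param seed RNG seed (bitwise reproducible).
#' @return a [movie_stack()].
#' @export
render_movie <- function(scene, n_frames, noise = noise_model(), seed = 0L) {
  y <- scene_signal_data(scene)
  stopifnot(n_frames >= 1L)
  if (noise$kind == "poisson_gaussian" && any(y < 0))
    stop("render_movie: negative signal under Poisson noise; raise the background offset")
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(i) {
    f <- if (noise$kind == "gaussian") y
    else rpois(length(y), noise$counts_per_frame * y) / noise$counts_per_frame
    f <- f + if (noise$read_std > 0) rnorm(length(y), 0, noise$read_std) else 0
    matrix(f, nrow(y), ncol(y))
  }))
  movie_stack(frames, origin_name = sprintf("synthetic(seed=%d)", seed))
}

#' Analytic split-frame SNR for a synthetic stack
#'
#' Closed form for the Gaussian noise model (Poisson approximated by its
#' variance): with per-half frame counts ne, no, per-frame noise variance
#' s2 and population signal variance V, the expected cross-correlation is
#' `p = ne*no*V / sqrt((ne^2 V + ne s2)(no^2 V + no s2))` and the SNR is
#' `10*log10(p / (1 - p))`. This is the oracle [snr_split()] is tested
#' against.
#'
#' @param scene a `cdn_scene`.
#' @param noise a [noise_model()].
#' @param n_frames total frames in the stack.
#' @return expected SNR in dB (`-Inf` for zero signal variance, `Inf` for
#'   zero noise).
#' @export
expected_pair_snr <- function(scene, noise, n_frames) {
  y <- scene_signal_data(scene)
  V <- mean((y - mean(y))^2)
  if (V == 0) return(-Inf)
  s2 <- noise$read_std^2 +
    if (noise$kind == "poisson_gaussian") mean(y) / noise$counts_per_frame else 0
  if (s2 == 0) return(Inf)
  ne <- ceiling(n_frames / 2); no <- floor(n_frames / 2)
  p <- ne * no * V / sqrt((ne^2 * V + ne * s2) * (no^2 * V + no * s2))
  10 * log10(p / (1 - p))
}

#' Per-frame noise sd achieving a target split-pair SNR
#'
#' For the Gaussian model with an even number of frames, the even/odd pair
#' SNR is `(F/2) * V / sigma^2`; inverting gives the per-frame sd for a
#' requested regime (e.g. the typical cryoEM value 0.1, i.e. -10 dB).
#'
#' @param scene a `cdn_scene`.
#' @param n_frames total frames.
#' @param snr target linear pair SNR (default 0.1).
#' @return per-frame Gaussian noise sd.
#' @export
noise_std_for_snr <- function(scene, n_frames, snr = 0.1) {
  y <- scene_signal_data(scene)
  V <- mean((y - mean(y))^2)
  sqrt((n_frames / 2) * V / snr)
}

#' Generate a list of synthetic noise pairs
#'
#' Desk-scale fixture generator: one scene per pair (fresh particle layout),
#' rendered as an `n_frames` movie under per-frame Gaussian noise calibrated
#' so each even/odd pair has split SNR `snr`, then split even/odd.
#'
#' @param n number of pairs.
#' @param h,w frame extents (default 128).
#' @param n_frames frames per movie (default 40).
#' @param snr target linear pair SNR (default 0.1).
#' @param n_particles,radius_px,contrast scene parameters.
#' @param seed base RNG seed; pair i uses seeds derived from it.
#' @return list with `pairs` (list of [noise_pair()]) and `scenes`.
#' @export
simulate_pairs <- function(n, h = 128L, w = 128L, n_frames = 40L, snr = 0.1,
                           n_particles = 8L, radius_px = 6, contrast = 1,
                           seed = 0L) {
  pairs <- vector("list", n); scenes <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- make_scene_2d(h, w, n_particles, radius_px, contrast,
                        seed = seed + 1000L * i)
    sd_f <- noise_std_for_snr(sc, n_frames, snr)
    stk <- render_movie(sc, n_frames, noise_model("gaussian", read_std = sd_f),
                        seed = seed + 1000L * i + 1L)
    pairs[[i]] <- split_even_odd(stk)
    pairs[[i]]$source <- sprintf("sim%03d", i)
    scenes[[i]] <- sc
  }
  list(pairs = pairs, scenes = scenes)
}
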