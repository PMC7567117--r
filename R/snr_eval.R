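# Signal-to-noise quantification.
#
# Two estimators:
#  * region SNR: mean over labeled signal/background region pairs of
#    10 * (log10(s_i) - log10(v_i)) with s_i = (mu_signal - mu_background)^2
#    and v_i the background (population) variance;
#  * split-frame SNR (Frank/Al-Ali): from two independent observations of the
#    same signal, SNR = p / (1 - p) with p their cross-correlation
#    coefficient, reported as 10*log10(p / (1 - p)) dB.
# Plus the low-pass baselines, dose-titration curves and display scaling.

#' Cross-correlation (Pearson) coefficient between two images
#' @param a,b equal-shape images (planes/volumes/arrays), both non-constant.
#' @return correlation in `[-1, 1]`.
#' @export
ccc <- function(a, b) {
  av <- as.vector(if (inherits(a, "image_plane") || inherits(a, "volume"))
    a$data else a)
  bv <- as.vector(if (inherits(b, "image_plane") || inherits(b, "volume"))
    b$data else b)
  if (length(av) != length(bv)) stop("ccc: shape mismatch")
  if (sd(av) == 0 || sd(bv) == 0) stop("ccc: constant input")
  cor(av, bv)
}

#' Split-frame SNR estimate in dB
#'
#' `10 * log10(p / (1 - p))` with `p = ccc(x, y)`; requires p in (0, 1) for a
#' finite value. `p <= 0` yields `-Inf` (with a warning), `p == 1` yields
#' `Inf`. The estimated `p` is attached as attribute `"ccc"`.
#'
#' @param x,y two independent observations of the same signal (e.g. denoised
#'   odd-frame and raw even-frame micrographs).
#' @return SNR in dB.
#' @export
snr_split <- function(x, y) {
  p <- ccc(x, y)
  db <- if (p <= 0) {
    warning(sprintf("snr_split: non-positive correlation (p = %.4g)", p))
    -Inf
  } else if (p >= 1) Inf else 10 * log10(p / (1 - p))
  structure(db, ccc = p)
}

#' Read a region-annotation table for the region SNR estimator
#'
#' Tab-separated columns: `image_name`, `role` (`signal` | `background`),
#' `pair_id`, `x0`, `y0`, `x1`, `y1` (0-based, half-open rectangles).
#'
#' @param path TSV file.
#' @return validated data.frame of regions.
#' @export
read_regions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("image_name", "role", "pair_id", "x0", "y0", "x1", "y1")
  if (!all(need %in% names(df)))
    stop(sprintf("region table must have columns: %s",
                 paste(need, collapse = ", ")))
  if (!all(df$role %in% c("signal", "background")))
    stop("region roles must be 'signal' or 'background'")
  df
}

region_pixels <- function(img, r) {
  m <- plane_data(img)
  if (r$x1 > ncol(m) || r$y1 > nrow(m) || r$x0 < 0 || r$y0 < 0 ||
      r$x1 <= r$x0 || r$y1 <= r$y0)
    stop(sprintf("region (pair %s) outside image bounds", r$pair_id))
  px <- m[(r$y0 + 1L):r$y1, (r$x0 + 1L):r$x1]
  if (length(px) < 4L)
    stop(sprintf("region (pair %s) has fewer than 4 pixels", r$pair_id))
  px
}

#' Region-based SNR estimate in dB
#'
#' For each signal/background pair i: signal power
#' `s_i = (mean(signal_i) - mean(background_i))^2`, noise power `v_i` the
#' population variance of the background region; the report averages
#' `10*(log10(s_i) - log10(v_i))` over pairs. Invariant to affine intensity
#' rescaling of the micrograph.
#'
#' @param images named list of [image_plane()]s or matrices.
#' @param regions data.frame as returned by [read_regions()].
#' @param method label recorded in the report.
#' @return a `cdn_snr_report` with per-pair and mean dB.
#' @export
snr_regions <- function(images, regions, method = "raw") {
  if (inherits(images, "image_plane") || is.matrix(images))
    images <- list(image = images)
  keys <- unique(regions[, c("image_name", "pair_id")])
  db <- numeric(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- regions$image_name == keys$image_name[i] &
      regions$pair_id == keys$pair_id[i]
    rs <- regions[sel & regions$role == "signal", ]
    rb <- regions[sel & regions$role == "background", ]
    if (nrow(rs) != 1L || nrow(rb) != 1L)
      stop(sprintf("pair %s of '%s' needs exactly one signal and one background region",
                   keys$pair_id[i], keys$image_name[i]))
    img <- images[[keys$image_name[i]]]
    if (is.null(img))
      stop(sprintf("image '%s' not supplied", keys$image_name[i]))
    ps <- region_pixels(img, rs[1, ])
    pb <- region_pixels(img, rb[1, ])
    vb <- mean((pb - mean(pb))^2)
    if (vb == 0)
      stop(sprintf("zero background variance in pair %s of '%s'",
                   keys$pair_id[i], keys$image_name[i]))
    s <- (mean(ps) - mean(pb))^2
    if (s == 0) {
      warning(sprintf("pair %s: signal mean equals background mean",
                      keys$pair_id[i]))
      db[i] <- -Inf
    } else {
      db[i] <- 10 * (log10(s) - log10(vb))
    }
  }
  structure(list(method = method, items = db, mean_db = mean(db)),
            class = "cdn_snr_report")
}

#' @export
print.cdn_snr_report <- function(x, ...) {
  cat(sprintf("<snr_report '%s': mean %.3f dB over %d region pairs>\n",
              x$method, x$mean_db, length(x$items)))
  invisible(x)
}

# Signed frequency index per axis: 0, 1, ..., -1 in FFT bin order.
fft_freqs <- function(n) {
  i <- seq_len(n) - 1L
  ifelse(i <= n / 2, i, i - n)
}

apply_spectral_filter <- function(x, mask_fun) {
  data <- if (inherits(x, "image_plane") || inherits(x, "volume")) x$data else x
  d <- dim(data)
  freqs <- lapply(d, fft_freqs)
  mask <- mask_fun(freqs, d)
  sp <- fft(data) * mask
  res <- Re(fft(sp, inverse = TRUE)) / length(data)
  out <- x
  if (inherits(x, "image_plane") || inherits(x, "volume")) out$data <- res
  else out <- res
  out
}

#' Low-pass filter by a binning factor (band-limit at Nyquist / factor)
#'
#' Equivalent to Fourier-cropping each axis to `1/factor` of its length and
#' padding back: all axis frequencies above `Nyquist / factor` are zeroed
#' (the band edge itself is kept, so `factor = 1` is the identity). Output is
#' real and has the input's shape, making pixelwise SNR comparison against
#' the raw image possible.
#'
#' @param image [image_plane()], [volume()], matrix or 3D array.
#' @param factor integer binning factor >= 1.
#' @return filtered image, same type and shape.
#' @export
lowpass_bin <- function(image, factor) {
  data <- if (inherits(image, "image_plane") || inherits(image, "volume"))
    image$data else image
  if (factor < 1 || factor != round(factor))
    stop("lowpass_bin: factor must be a positive integer")
  if (factor > min(dim(data)))
    stop("lowpass_bin: factor exceeds the smallest image dimension")
  apply_spectral_filter(image, function(freqs, d) {
    keep <- mapply(function(f, n) abs(f) <= (n / factor) / 2, freqs, d,
                   SIMPLIFY = FALSE)
    Reduce(function(a, b) outer(a, b, "&"),
           lapply(seq_along(keep), function(i) keep[[i]])) * 1
  })
}

#' Gaussian low-pass filter
#'
#' Multiplies the spectrum by a radial Gaussian whose attenuation is 0.5 at
#' the cutoff frequency (`cutoff` as a fraction of Nyquist, e.g. `1/8`).
#'
#' @param image [image_plane()], [volume()], matrix or 3D array.
#' @param cutoff positive fraction of Nyquist at which amplitude is halved.
#' @return filtered image, same type and shape.
#' @export
lowpass_gaussian <- function(image, cutoff) {
  if (!is.finite(cutoff) || cutoff <= 0)
    stop("lowpass_gaussian: cutoff must be > 0")
  apply_spectral_filter(image, function(freqs, d) {
    # radial frequency as fraction of Nyquist (0.5 cycles/pixel)
    r2 <- Reduce(function(a, b) outer(a, b, "+"),
                 lapply(seq_along(freqs),
                        function(i) ((freqs[[i]] / d[i]) / 0.5)^2))
    exp(-log(2) * r2 / cutoff^2)
  })
}

#' Dose-titration SNR table
#'
#' Splits the stack into even/odd halves, keeps the leading
#' `floor(fraction * n_frames)` frames of the odd half for each fraction
#' (fractions are of the full-stack dose, so at most 0.5), applies each
#' method to the fractionated odd sum and reports
#' `snr_split(method(odd_f), even_full)` in dB.
#'
#' @param stack a [movie_stack()] (>= 2 frames).
#' @param fractions dose fractions in (0, 0.5].
#' @param methods named list of callables mapping an [image_plane()] to a
#'   denoised plane (e.g. `list(raw = identity, unet = \(x)
#'   denoise_image(model, x))`).
#' @return data.frame with columns `fraction`, `frames`, one dB column per
#'   method.
#' @export
dose_titration <- function(stack, fractions,
                           methods = list(raw = identity)) {
  stopifnot(inherits(stack, "movie_stack"), n_frames(stack) >= 2L)
  if (any(fractions <= 0 | fractions > 0.5))
    stop("dose_titration: fractions must lie in (0, 0.5] of the total dose (the odd half holds at most half)")
  if (is.null(names(methods)) || any(names(methods) == ""))
    stop("dose_titration: methods must be a named list")
  pair <- split_even_odd(stack)
  even_full <- pair$even
  nf <- n_frames(stack)
  odd_frames <- stack$frames[seq(2L, nf, by = 2L)]
  res <- list()
  for (f in fractions) {
    k <- floor(f * nf)
    if (k < 1L) {
      warning(sprintf("fraction %.4g rounds down to 0 frames; skipped", f))
      next
    }
    k <- min(k, length(odd_frames))
    odd_f <- image_plane(sum_frames_list(odd_frames[seq_len(k)]))
    row <- list(fraction = f, frames = k)
    for (nm in names(methods)) {
      den <- methods[[nm]](odd_f)
      row[[nm]] <- as.numeric(snr_split(den, even_full))
    }
    res[[length(res) + 1L]] <- as.data.frame(row)
  }
  if (length(res) == 0L) stop("dose_titration: no usable fractions")
  do.call(rbind, res)
}

#' Scale a micrograph to 8-bit display values
#'
#' Intensities are standardized against a 16x low-passed reference (so raw
#' and denoised versions share one scale), clamped to z in [-4, 4] and
#' binned into 256 uniform buckets (`z = 0` falls in bucket 128).
#'
#' @param image [image_plane()] or matrix.
#' @param reference low-passed reference; default `lowpass_bin(image, 16)`.
#' @return integer matrix of bucket indices 0..255.
#' @export
scale_display <- function(image, reference = NULL) {
  data <- plane_data(image)
  if (is.null(reference)) reference <- lowpass_bin(data, 16L)
  ref <- plane_data(reference)
  m <- mean(ref)
  s <- sqrt(mean((ref - m)^2))
  if (s == 0) stop("scale_display: constant reference")
  z <- pmin(4, pmax(-4, (data - m) / s))
  b <- floor((z + 4) / 8 * 256)
  b[b > 255] <- 255L
  mode(b) <- "integer"
  matrix(b, nrow(data), ncol(data))
}
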