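# Shared fixture builders. Everything is generated in code; no binary files.

# Small movie stack with float32-representable values (so MRC round trips
# are bitwise).
tiny_stack <- function(n_frames = 4L, h = 8L, w = 6L, seed = 1L) {
  frames <- cryodenoise:::with_seed(seed, lapply(seq_len(n_frames), function(i)
    matrix(as.numeric(sample.int(512L, h * w, replace = TRUE)), h, w)))
  movie_stack(frames, dose_per_frame = 1.5, pixel_size = 1.1)
}

# Noise pairs from independently-seeded synthetic scenes (fast sizes).
tiny_pairs <- function(n = 4L, h = 48L, w = 48L, n_frames = 8L, snr = 0.5,
                       seed = 1L) {
  simulate_pairs(n, h = h, w = w, n_frames = n_frames, snr = snr,
                 n_particles = 1L, radius_px = 3, seed = seed)$pairs
}

# A model with non-zero weights for inference tests (affine init is zero).
seeded_model <- function(arch, base_width = 8L, depth = NULL, seed = 11L) {
  m <- build_model(model_spec(arch, base_width = base_width, depth = depth,
                              seed = seed))
  if (arch == "affine") {
    m$params$out$w[] <- cryodenoise:::with_seed(seed,
      rnorm(length(m$params$out$w), 0, 0.02))
    m$params$out$b <- 0.05
  }
  m
}

# Minimal baseline TIFF writer (test oracle for the package's reader):
# uncompressed single-strip grayscale, little-endian.
write_tiff_gray <- function(mats, path, sample_format = 3L, bps = 32L,
                            compression = 1L) {
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L)
  # layout: header(8) | per page: pixel data then IFD
  offs <- 8L
  n <- length(mats)
  meta <- list()
  for (i in seq_len(n)) {
    m <- mats[[i]]
    nbytes <- length(m) * (bps %/% 8L)
    meta[[i]] <- list(data_off = offs, ifd_off = offs + nbytes)
    offs <- offs + nbytes + 2L + 10L * 12L + 4L
  }
  w4(meta[[1]]$ifd_off)
  for (i in seq_len(n)) {
    m <- mats[[i]]
    vals <- as.vector(t(m))  # row-major
    if (sample_format == 3L)
      writeBin(as.double(vals), con, size = 4L, endian = "little")
    else writeBin(as.integer(vals), con, size = bps %/% 8L, endian = "little")
    entry <- function(tag, type, count, value) {
      w2(tag); w2(type); w4(count)
      if (type == 3L) { w2(value); w2(0L) } else w4(value)
    }
    w2(10L)  # entries
    entry(256L, 4L, 1L, ncol(m))
    entry(257L, 4L, 1L, nrow(m))
    entry(258L, 3L, 1L, bps)
    entry(259L, 3L, 1L, compression)
    entry(262L, 3L, 1L, 1L)
    entry(273L, 4L, 1L, meta[[i]]$data_off)
    entry(277L, 3L, 1L, 1L)
    entry(278L, 4L, 1L, nrow(m))
    entry(279L, 4L, 1L, length(m) * (bps %/% 8L))
    entry(339L, 3L, 1L, sample_format)
    w4(if (i < n) meta[[i + 1L]]$ifd_off else 0L)
  }
  invisible(path)
}

# Round any matrix/array to float32 representable values.
as_float32 <- function(x) {
  con <- rawConnection(raw(0), "wb")
  writeBin(as.double(x), con, size = 4L)
  v <- readBin(rawConnectionValue(con), "numeric", n = length(x), size = 4L)
  close(con)
  if (!is.null(dim(x))) dim(v) <- dim(x)
  v
}
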