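# MRC2014 and baseline-TIFF input/output.
#
# MRC data order on disk is x fastest, then y, then z; in memory this package
# indexes [y, x] (2D) and [z, y, x] (3D). Files are always written as mode 2
# (float32) little-endian; modes 0 (int8), 1 (int16), 2 (float32) and
# 6 (uint16) are accepted on read and promoted to float.

MRC_HEADER_BYTES <- 1024L

# Parse the fixed 1024-byte MRC header from a raw vector.
parse_mrc_header <- function(raw, path) {
  if (length(raw) < MRC_HEADER_BYTES)
    stop(sprintf("MRC format error in '%s': header truncated at byte %d (need %d)",
                 path, length(raw), MRC_HEADER_BYTES))
  map_tag <- rawToChar(raw[209:212])
  machst <- raw[213:214]
  endian <- "little"
  if (identical(machst[1], as.raw(0x11))) endian <- "big"
  ints <- readBin(raw, "integer", n = 56L, size = 4L, endian = endian)
  flts <- readBin(raw, "numeric", n = 56L, size = 4L, endian = endian)
  if (!identical(map_tag, "MAP ") && !(ints[1] > 0 && ints[2] > 0 && ints[3] >= 0))
    stop(sprintf("MRC format error in '%s': bad magic at byte offset 208", path))
  list(nx = ints[1], ny = ints[2], nz = ints[3], mode = ints[4],
       mx = ints[8], my = ints[9], mz = ints[10],
       cella = flts[11:13], ispg = ints[23], nsymbt = ints[24],
       endian = endian)
}

mrc_mode_info <- function(mode, path) {
  switch(as.character(mode),
         "0" = list(what = "integer", size = 1L, signed = TRUE),
         "1" = list(what = "integer", size = 2L, signed = TRUE),
         "2" = list(what = "numeric", size = 4L, signed = TRUE),
         "6" = list(what = "integer", size = 2L, signed = FALSE),
         stop(sprintf("MRC '%s': mode %d unsupported (modes 0/1/2/6 only)",
                      path, mode)))
}

read_mrc_raw <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = sz)
  hdr <- parse_mrc_header(raw, path)
  info <- mrc_mode_info(hdr$mode, path)
  npix <- as.numeric(hdr$nx) * hdr$ny * hdr$nz
  data_off <- MRC_HEADER_BYTES + hdr$nsymbt
  need <- data_off + npix * info$size
  if (sz < need)
    stop(sprintf("MRC format error in '%s': file ends at byte %d, need %d",
                 path, sz, need))
  vals <- readBin(raw[(data_off + 1L):(data_off + npix * info$size)],
                  info$what, n = npix, size = info$size,
                  signed = info$signed, endian = hdr$endian)
  vals <- as.double(vals)
  px <- NULL
  if (hdr$mx > 0 && is.finite(hdr$cella[1]) && hdr$cella[1] > 0)
    px <- hdr$cella[1] / hdr$mx
  list(hdr = hdr, data = vals, pixel_size = px)
}

#' Read an MRC2014 or TIFF file
#'
#' Dimensionality is inferred from the header: a single section becomes an
#' [image_plane()], a multi-section file becomes a [movie_stack()] when
#' `as_stack = TRUE` (MRC headers do not reliably distinguish stacks from
#' volumes, so the caller decides) and a [volume()] otherwise.
#'
#' @param path file path; format chosen by extension (`.tif`/`.tiff` vs MRC).
#' @param as_stack interpret a 3D MRC as a movie stack rather than a volume.
#' @return an `image_plane`, `volume` or `movie_stack`.
#' @export
read_image <- function(path, as_stack = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- read_tiff(path)
    if (length(pages) == 1L)
      return(image_plane(pages[[1]], origin_name = path))
    return(movie_stack(pages, origin_name = path))
  }
  r <- read_mrc_raw(path)
  h <- r$hdr
  if (h$nz <= 1L) {
    m <- t(matrix(r$data, nrow = h$nx, ncol = h$ny)) # -> rows = Y
    return(image_plane(m, pixel_size = r$pixel_size, origin_name = path))
  }
  arr <- array(r$data, dim = c(h$nx, h$ny, h$nz))
  if (as_stack) {
    frames <- lapply(seq_len(h$nz), function(z) t(arr[, , z]))
    return(movie_stack(frames, pixel_size = r$pixel_size, origin_name = path))
  }
  volume(aperm(arr, c(3L, 2L, 1L)), voxel_size = r$pixel_size,
         origin_name = path)
}

mrc_header_raw <- function(nx, ny, nz, pixel_size, ispg, dmin, dmax, dmean, rms) {
  if (is.null(pixel_size)) pixel_size <- 0
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  wf <- function(v) writeBin(as.double(v), con, size = 4L, endian = "little")
  wi(c(nx, ny, nz, 2L))                      # NX NY NZ MODE
  wi(c(0L, 0L, 0L))                          # N*START
  wi(c(nx, ny, nz))                          # MX MY MZ
  wf(c(nx, ny, nz) * pixel_size)             # CELLA
  wf(c(90, 90, 90))                          # CELLB
  wi(c(1L, 2L, 3L))                          # MAPC MAPR MAPS
  wf(c(dmin, dmax, dmean))                   # DMIN DMAX DMEAN
  wi(c(ispg, 0L))                            # ISPG NSYMBT
  wi(rep(0L, 2))                             # EXTRA 25-26
  writeBin(charToRaw("MRCO"), con)           # EXTTYP
  wi(20140L)                                 # NVERSION
  wi(rep(0L, 21))                            # EXTRA 29-49
  wf(c(0, 0, 0))                             # ORIGIN
  writeBin(charToRaw("MAP "), con)           # MAP
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # MACHST little-endian
  wf(rms)                                    # RMS
  wi(1L)                                     # NLABL
  lab <- sprintf("%-80s", "cryodenoise")
  writeBin(charToRaw(lab), con)
  writeBin(raw(9L * 80L), con)
  rawConnectionValue(con)
}

#' Write an image, volume or movie stack as MRC2014 (mode 2, float32)
#'
#' Round-trip contract: `read_image(write_image(x))` reproduces `x` bitwise
#' when the payload is float32-representable.
#'
#' @param obj an [image_plane()], [volume()] or [movie_stack()] (bare matrices
#'   and 3D arrays are coerced to plane / volume).
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
write_image <- function(obj, path) {
  if (is.matrix(obj)) obj <- image_plane(obj)
  if (is.array(obj) && length(dim(obj)) == 3L) obj <- volume(obj)
  if (inherits(obj, "image_plane")) {
    vals <- as.vector(t(obj$data))  # x fastest
    dims <- c(ncol(obj$data), nrow(obj$data), 1L)
    px <- obj$pixel_size; ispg <- 0L
  } else if (inherits(obj, "volume")) {
    d <- dim(obj$data)
    vals <- as.vector(aperm(obj$data, c(3L, 2L, 1L)))
    dims <- c(d[3], d[2], d[1])
    px <- obj$voxel_size; ispg <- 1L
  } else if (inherits(obj, "movie_stack")) {
    vals <- unlist(lapply(obj$frames, function(f) as.vector(t(f))),
                   use.names = FALSE)
    d <- dim(obj$frames[[1]])
    dims <- c(d[2], d[1], length(obj$frames))
    px <- obj$pixel_size; ispg <- 0L
  } else stop("write_image: unsupported object type")
  if (!all(is.finite(vals)))
    stop("write_image: refusing to write non-finite pixel values")
  m <- mean(vals)
  hdr <- mrc_header_raw(dims[1], dims[2], dims[3], px, ispg,
                        min(vals), max(vals), m, sqrt(mean((vals - m)^2)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(as.double(vals), con, size = 4L, endian = "little")
  invisible(path)
}

# ---------------------------------------------------------------------- TIFF
# Minimal baseline TIFF reader: uncompressed, single-sample (grayscale),
# 8/16/32-bit integer or 32-bit float, multi-page. Read-only convenience.

read_tiff <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = sz)
  if (length(raw) < 8L)
    stop(sprintf("TIFF format error in '%s': truncated at byte %d", path,
                 length(raw)))
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop(sprintf("TIFF format error in '%s': bad byte-order mark", path))
  rd_int <- function(off, size, n = 1L, signed = TRUE) {
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = signed, endian = endian)
  }
  if (rd_int(2L, 2L, signed = FALSE) != 42L)
    stop(sprintf("TIFF format error in '%s': magic != 42", path))
  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `6` = 1L, `8` = 2L,
                 `9` = 4L, `11` = 4L)
  read_entry_values <- function(off) {
    typ <- rd_int(off + 2L, 2L, signed = FALSE)
    cnt <- rd_int(off + 4L, 4L)
    tsz <- type_size[as.character(typ)]
    if (is.na(tsz)) return(NULL)
    total <- tsz * cnt
    voff <- if (total <= 4L) off + 8L else rd_int(off + 8L, 4L)
    if (typ %in% c(3L, 8L)) rd_int(voff, 2L, cnt, signed = typ == 8L)
    else if (typ %in% c(4L, 9L)) rd_int(voff, 4L, cnt)
    else if (typ %in% c(1L, 6L)) rd_int(voff, 1L, cnt, signed = typ == 6L)
    else if (typ == 11L) readBin(raw[(voff + 1L):(voff + 4L * cnt)], "numeric",
                                 n = cnt, size = 4L, endian = endian)
    else NULL
  }
  pages <- list()
  ifd_off <- rd_int(4L, 4L)
  while (ifd_off != 0L) {
    n_ent <- rd_int(ifd_off, 2L, signed = FALSE)
    tags <- list()
    for (i in seq_len(n_ent)) {
      eoff <- ifd_off + 2L + (i - 1L) * 12L
      tag <- rd_int(eoff, 2L, signed = FALSE)
      tags[[as.character(tag)]] <- read_entry_values(eoff)
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    w <- g(256); h <- g(257)
    if (is.null(w) || is.null(h))
      stop(sprintf("TIFF '%s': missing ImageWidth/ImageLength", path))
    bps <- g(258, 1L)[1]
    if (g(259, 1L) != 1L)
      stop(sprintf("TIFF '%s': compressed TIFF unsupported", path))
    if (g(277, 1L) != 1L)
      stop(sprintf("TIFF '%s': only single-sample (grayscale) supported", path))
    fmt <- g(339, 1L)[1]
    offs <- g(273); cnts <- g(279)
    rps <- g(278, h)
    if (is.null(offs))
      stop(sprintf("TIFF '%s': missing StripOffsets", path))
    bytes_px <- bps %/% 8L
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      nb <- if (!is.null(cnts)) cnts[s] else
        min(rps, h - (s - 1L) * rps) * w * bytes_px
      chunk <- raw[(offs[s] + 1L):(offs[s] + nb)]
      v <- if (fmt == 3L) {
        if (bps != 32L) stop(sprintf("TIFF '%s': float bps %d unsupported",
                                     path, bps))
        readBin(chunk, "numeric", n = nb %/% 4L, size = 4L, endian = endian)
      } else {
        readBin(chunk, "integer", n = nb %/% bytes_px, size = bytes_px,
                signed = (fmt == 2L) || bytes_px > 2L, endian = endian)
      }
      vals <- c(vals, as.double(v))
    }
    if (length(vals) < w * h)
      stop(sprintf("TIFF format error in '%s': pixel data truncated", path))
    pages[[length(pages) + 1L]] <- t(matrix(vals[seq_len(w * h)],
                                            nrow = w, ncol = h))
    ifd_off <- rd_int(ifd_off + 2L + n_ent * 12L, 4L)
  }
  if (length(pages) == 0L)
    stop(sprintf("TIFF format error in '%s': no IFDs", path))
  pages
}
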