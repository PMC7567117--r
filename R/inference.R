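# Tiled inference. Large inputs are normalized once, cut into core tiles that
# partition the image, each core is denoised with `pad` pixels of real
# context on every side (clipped at the image border), and the cores are
# stitched back. When pad >= ceiling(receptive_field / 2) the stitched result
# equals the whole-image forward pass, so patching introduces no seams.
#
# For pooled (U-net) models, patch and pad are additionally rounded to
# multiples of 2^depth so that every tile sees the same pooling grid as the
# whole image; without that alignment max-pooling breaks the translation
# equivariance the guarantee relies on.

axis_tiles <- function(size, patch, pad) {
  starts <- seq(0L, size - 1L, by = patch)
  data.frame(core0 = starts,
             core1 = pmin(size, starts + patch),
             pad0 = pmax(0L, starts - pad),
             pad1 = pmin(size, pmin(size, starts + patch) + pad))
}

#' Plan a tiling of an image or volume
#'
#' Core intervals are disjoint, half-open, 0-based and tile the full extent;
#' padded intervals add `pad` pixels of context, clipped at the borders.
#'
#' @param shape integer extents (length 2 or 3).
#' @param patch core tile side.
#' @param pad context width on each side (>= 0).
#' @param align round `patch` (down) and `pad` (up) to multiples of this
#'   (use `2^depth` for pooled models; default 1).
#' @return a `cdn_patch_plan`: list with `patch`, `pad` and one tile table
#'   per axis.
#' @export
plan_tiles <- function(shape, patch, pad, align = 1L) {
  stopifnot(all(shape >= 1L), patch >= 1L, pad >= 0L, align >= 1L)
  patch <- max(align, (patch %/% align) * align)
  pad <- as.integer(ceiling(pad / align) * align)
  structure(list(patch = as.integer(patch), pad = pad,
                 axes = lapply(as.integer(shape), axis_tiles,
                               patch = patch, pad = pad)),
            class = "cdn_patch_plan")
}

#' Denoise a full-size micrograph by padded patch stitching
#'
#' The image is normalized once at the whole-micrograph level, denoised in
#' padded tiles, stitched, and restored with the same statistics
#' (`out * std + mean`). With `pad >= ceiling(receptive_field / 2)` the
#' result equals denoising the whole image in one pass.
#'
#' @param model a 2D `cdn_denoiser`.
#' @param image [image_plane()] or matrix (non-constant).
#' @param patch tile side in pixels (default 4000).
#' @param pad context width in pixels (default 500).
#' @return denoised image of the same type and shape.
#' @export
denoise_image <- function(model, image, patch = 4000L, pad = 500L) {
  stopifnot(inherits(model, "cdn_denoiser"))
  if (model$ndim != 2L)
    stop("denoise_image: model is 3D; use denoise_volume()")
  data <- plane_data(image)
  nz <- normalize_image(data)
  h <- nrow(data); w <- ncol(data)
  if (patch >= h && patch >= w) {
    out <- forward(model, nz$data)
  } else {
    plan <- plan_tiles(c(h, w), patch, pad, align = model$align)
    out <- matrix(0, h, w)
    for (ty in seq_len(nrow(plan$axes[[1]]))) {
      ry <- plan$axes[[1]][ty, ]
      for (tx in seq_len(nrow(plan$axes[[2]]))) {
        rx <- plan$axes[[2]][tx, ]
        sub <- nz$data[(ry$pad0 + 1L):ry$pad1, (rx$pad0 + 1L):rx$pad1,
                       drop = FALSE]
        ysub <- forward(model, sub)
        out[(ry$core0 + 1L):ry$core1, (rx$core0 + 1L):rx$core1] <-
          ysub[(ry$core0 - ry$pad0 + 1L):(ry$core1 - ry$pad0),
               (rx$core0 - rx$pad0 + 1L):(rx$core1 - rx$pad0), drop = FALSE]
      }
    }
  }
  out <- denormalize_image(out, nz$stats)
  if (inherits(image, "image_plane")) {
    res <- image; res$data <- out; res
  } else out
}

#' Denoise a tomogram by padded cubic patch stitching
#'
#' As [denoise_image()] with cubic tiles; the default padding is
#' `ceiling(receptive_field / 2)` computed from the model.
#'
#' @param model a 3D `cdn_denoiser` (arch `unet3d`).
#' @param vol [volume()] or 3D array.
#' @param patch cubic tile side in voxels (default 96).
#' @param pad context width in voxels; default `ceiling(rf / 2)`.
#' @return denoised volume of the same type and shape.
#' @export
denoise_volume <- function(model, vol, patch = 96L, pad = NULL) {
  stopifnot(inherits(model, "cdn_denoiser"))
  if (model$ndim != 3L)
    stop("denoise_volume: model is 2D; use denoise_image()")
  data <- volume_data(vol)
  if (length(dim(data)) != 3L) stop("denoise_volume: need a 3D volume")
  if (is.null(pad)) pad <- ceiling(model$receptive_field / 2)
  nz <- normalize_image(data)
  d <- dim(data)
  if (all(patch >= d)) {
    out <- forward(model, nz$data)
  } else {
    plan <- plan_tiles(d, patch, pad, align = model$align)
    out <- array(0, d)
    ax <- plan$axes
    for (tz in seq_len(nrow(ax[[1]]))) {
      rz <- ax[[1]][tz, ]
      for (ty in seq_len(nrow(ax[[2]]))) {
        ry <- ax[[2]][ty, ]
        for (tx in seq_len(nrow(ax[[3]]))) {
          rx <- ax[[3]][tx, ]
          sub <- nz$data[(rz$pad0 + 1L):rz$pad1, (ry$pad0 + 1L):ry$pad1,
                         (rx$pad0 + 1L):rx$pad1, drop = FALSE]
          ysub <- forward(model, sub)
          out[(rz$core0 + 1L):rz$core1, (ry$core0 + 1L):ry$core1,
              (rx$core0 + 1L):rx$core1] <-
            ysub[(rz$core0 - rz$pad0 + 1L):(rz$core1 - rz$pad0),
                 (ry$core0 - ry$pad0 + 1L):(ry$core1 - ry$pad0),
                 (rx$core0 - rx$pad0 + 1L):(rx$core1 - rx$pad0), drop = FALSE]
        }
      }
    }
  }
  out <- denormalize_image(out, nz$stats)
  if (inherits(vol, "volume")) {
    res <- vol; res$data <- out; res
  } else out
}
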