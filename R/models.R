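# Denoiser architectures and receptive-field accounting.
#
# Five architectures:
#   affine     - one 31x31 convolution (linear; the L2-trained affine model is
#                the Wiener filter solution), weights start at zero
#   fcnn       - three 11x11 conv layers, 64 filters, leaky-ReLU
#   unet_small - U-net with 3 pooling levels
#   unet       - U-net with 5 pooling levels, first conv 11x11
#   unet3d     - 3D U-net, first conv kernel 7, default 3 pooling levels
#   constant   - bias-only predictor f(x) = b (diagnostic model: its L2/L1
#                minimizers are the target mean/median)
#
# Internal tensor layout: (H, W, C, N) for 2D, (D, H, W, C, N) for 3D.
# All convolutions use "same" zero padding; every forward preserves spatial
# shape exactly (sides not divisible by 2^depth are reflect-padded up and
# cropped back).

VALID_ARCHS <- c("affine", "fcnn", "unet_small", "unet", "unet3d", "constant")

#' Describe a denoiser architecture
#'
#' @param arch one of `"affine"`, `"fcnn"`, `"unet_small"`, `"unet"`,
#'   `"unet3d"`, `"constant"`.
#' @param base_width filters in the first U-net block (default 48; ignored by
#'   affine/constant; fcnn fixes 64).
#' @param depth number of pooling levels for the U-nets (defaults: 5 for
#'   `unet`, 3 for `unet_small` and `unet3d`).
#' @param activation_slope negative slope of the leaky rectifier (default 0.1).
#' @param seed integer seed for weight initialization.
#' @return a `cdn_model_spec`.
#' @export
model_spec <- function(arch, base_width = 48L, depth = NULL,
                       activation_slope = 0.1, seed = 0L) {
  if (!arch %in% VALID_ARCHS)
    stop(sprintf("unknown arch '%s'; valid: %s", arch,
                 paste(VALID_ARCHS, collapse = ", ")))
  if (base_width < 1L) stop("base_width must be >= 1")
  if (is.null(depth))
    depth <- switch(arch, unet = 5L, unet_small = 3L, unet3d = 3L, 0L)
  structure(list(arch = arch, in_channels = 1L,
                 base_width = as.integer(base_width),
                 depth = as.integer(depth),
                 activation_slope = activation_slope,
                 seed = as.integer(seed)),
            class = "cdn_model_spec")
}

spec_kernel0 <- function(spec) {
  switch(spec$arch, unet3d = 7L, affine = 31L, 11L)
}

spec_ndim <- function(spec) if (spec$arch == "unet3d") 3L else 2L

# Fan-in-scaled uniform initialization (the standard conv-layer default:
# U(-1/sqrt(fan_in), 1/sqrt(fan_in)) for both weights and bias).
init_conv <- function(k, cin, cout, ndim = 2L, zero = FALSE) {
  kd <- rep(k, ndim)
  nw <- prod(kd) * cin * cout
  if (zero) {
    w <- array(0, dim = c(kd, cin, cout)); b <- numeric(cout)
  } else {
    bound <- 1 / sqrt(prod(kd) * cin)
    w <- array(runif(nw, -bound, bound), dim = c(kd, cin, cout))
    b <- runif(cout, -bound, bound)
  }
  list(w = w, b = b)
}

#' Instantiate a denoiser from its spec
#'
#' Affine weights start at zero; network weights use a seeded
#' fan-in-scaled uniform scheme.
#'
#' @param spec a [model_spec()].
#' @return a `cdn_denoiser` with fields `spec`, `params`, `receptive_field`.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "cdn_model_spec"))
  nd <- spec_ndim(spec)
  w <- spec$base_width
  params <- with_seed(spec$seed, {
    switch(spec$arch,
      constant = list(bias = list(b = 0)),
      affine = list(out = init_conv(31L, 1L, 1L, zero = TRUE)),
      fcnn = list(conv1 = init_conv(11L, 1L, 64L),
                  conv2 = init_conv(11L, 64L, 64L),
                  out = init_conv(11L, 64L, 1L)),
      { # unet family
        p <- list(enc0 = init_conv(spec_kernel0(spec), 1L, w, ndim = nd))
        for (i in seq_len(spec$depth))
          p[[paste0("enc", i)]] <- init_conv(3L, w, w, ndim = nd)
        for (j in rev(seq_len(spec$depth)) - 1L)
          p[[paste0("dec", j)]] <- init_conv(3L, 2L * w, w, ndim = nd)
        p$out <- init_conv(3L, w, 1L, ndim = nd)
        p
      })
  })
  structure(list(spec = spec, params = params,
                 receptive_field = receptive_field(spec),
                 ndim = nd, align = 2L^spec$depth),
            class = "cdn_denoiser")
}

#' @export
print.cdn_denoiser <- function(x, ...) {
  np <- sum(vapply(x$params, function(p)
    sum(vapply(p, length, integer(1))), numeric(1)))
  cat(sprintf("<denoiser %s: %d parameters, receptive field %d, %dD>\n",
              x$spec$arch, np, x$receptive_field, x$ndim))
  invisible(x)
}

#' Count of learnable scalars in a denoiser
#' @param model a `cdn_denoiser`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(p)
    sum(vapply(p, length, integer(1))), numeric(1)))
}

# Dilate a boolean influence vector by a width-k "same" convolution.
dilate1d <- function(v, k) {
  p <- (k - 1L) %/% 2L
  n <- length(v)
  out <- v
  for (o in seq_len(p)) {
    out <- out | c(v[-seq_len(o)], rep(FALSE, o)) |
      c(rep(FALSE, o), v[seq_len(n - o)])
  }
  out
}

# Exact 1D influence footprint of the U-net layer graph: propagate which
# positions depend on a single perturbed input pixel through conv dilations,
# 2x pooling (or of pairs) and nearest upsampling (duplication). Pooling is
# not a centered operator, so the footprint depends on the pixel's alignment
# modulo 2^depth; the receptive field is the maximum span over alignments.
unet_rf_1d <- function(k0, d) {
  n <- 64L
  repeat {
    n <- n * 2L
    spans <- vapply(seq_len(2L^d), function(off) {
      v <- logical(n)
      v[n %/% 2L + off] <- TRUE
      e <- vector("list", d + 1L)
      e[[1]] <- dilate1d(v, k0)
      cur <- e[[1]]
      for (i in seq_len(d)) {
        odd <- cur[seq(1L, length(cur), 2L)]
        evn <- cur[seq(2L, length(cur), 2L)]
        e[[i + 1L]] <- dilate1d(odd | evn, 3L)
        cur <- e[[i + 1L]]
      }
      u <- e[[d + 1L]]
      for (j in rev(seq_len(d))) {
        up <- rep(u, each = 2L)
        u <- dilate1d(up | e[[j]], 3L)
      }
      y <- dilate1d(u, 3L)
      idx <- which(y)
      max(idx) - min(idx) + 1L
    }, integer(1))
    if (max(spans) < n %/% 2L) return(max(spans))
  }
}

#' Receptive field of an architecture
#'
#' Side length of the square (cube) of input pixels that can influence one
#' output pixel. Pure convolution stacks use the recurrence
#' rf <- rf + (k - 1); the pooled U-nets use an exact 1D influence
#' propagation through the layer graph (max pooling is not centered, so the
#' plain recurrence undercounts). Always returned odd (rounded up) so that
#' `ceiling(rf / 2)` padding is a safe stitching bound.
#'
#' @param spec a [model_spec()] (or a `cdn_denoiser`).
#' @return odd integer, pixels (2D) or voxels (3D).
#' @export
receptive_field <- function(spec) {
  if (inherits(spec, "cdn_denoiser")) spec <- spec$spec
  stopifnot(inherits(spec, "cdn_model_spec"))
  rf <- switch(spec$arch,
    constant = 1L,
    affine = 31L,
    fcnn = 31L,  # 11 + 10 + 10
    unet_rf_1d(spec_kernel0(spec), spec$depth))
  rf <- as.integer(rf)
  if (rf %% 2L == 0L) rf <- rf + 1L
  rf
}

# ------------------------------------------------------------------- layers

conv_fw <- function(x, p) {
  if (length(dim(x)) == 4L) cpp_conv2d_fw(x, p$w, p$b)
  else cpp_conv3d_fw(x, p$w, p$b)
}

conv_bw <- function(x, p, dy, need_dx = TRUE) {
  if (length(dim(x)) == 4L) cpp_conv2d_bw(x, p$w, dy, need_dx)
  else cpp_conv3d_bw(x, p$w, dy, need_dx)
}

lrelu_fw <- function(x, slope) cpp_lrelu_fw(x, slope)

lrelu_bw <- function(x, dy, slope) cpp_lrelu_bw(x, dy, slope)

# 2x max pooling over each spatial dim (even extents assumed).
pool_fw <- function(x) {
  d <- dim(x); nd <- length(d) - 2L
  if (nd == 2L) {
    o1 <- seq(1L, d[1], 2L); o2 <- seq(1L, d[2], 2L)
    pmax(x[o1, o2, , , drop = FALSE],       x[o1 + 1L, o2, , , drop = FALSE],
         x[o1, o2 + 1L, , , drop = FALSE],  x[o1 + 1L, o2 + 1L, , , drop = FALSE])
  } else {
    o1 <- seq(1L, d[1], 2L); o2 <- seq(1L, d[2], 2L); o3 <- seq(1L, d[3], 2L)
    m <- x[o1, o2, o3, , , drop = FALSE]
    for (dz in 0:1) for (dy_ in 0:1) for (dx_ in 0:1) {
      if (dz + dy_ + dx_ == 0) next
      m <- pmax(m, x[o1 + dz, o2 + dy_, o3 + dx_, , , drop = FALSE])
    }
    m
  }
}

# Route gradients to the argmax (first-index tie break).
pool_bw <- function(x, m, dm) {
  d <- dim(x); nd <- length(d) - 2L
  dx <- array(0, d)
  taken <- array(FALSE, dim(m))
  if (nd == 2L) {
    o1 <- seq(1L, d[1], 2L); o2 <- seq(1L, d[2], 2L)
    for (dy_ in 0:1) for (dx_ in 0:1) {
      sl <- x[o1 + dy_, o2 + dx_, , , drop = FALSE]
      hit <- (sl == m) & !taken
      taken <- taken | hit
      dx[o1 + dy_, o2 + dx_, , ] <- dx[o1 + dy_, o2 + dx_, , , drop = FALSE] +
        dm * hit
    }
  } else {
    o1 <- seq(1L, d[1], 2L); o2 <- seq(1L, d[2], 2L); o3 <- seq(1L, d[3], 2L)
    for (dz in 0:1) for (dy_ in 0:1) for (dx_ in 0:1) {
      sl <- x[o1 + dz, o2 + dy_, o3 + dx_, , , drop = FALSE]
      hit <- (sl == m) & !taken
      taken <- taken | hit
      dx[o1 + dz, o2 + dy_, o3 + dx_, , ] <-
        dx[o1 + dz, o2 + dy_, o3 + dx_, , , drop = FALSE] + dm * hit
    }
  }
  dx
}

# 2x nearest-neighbor upsampling.
up_fw <- function(x) {
  d <- dim(x); nd <- length(d) - 2L
  if (nd == 2L)
    x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
      drop = FALSE]
  else
    x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L),
      rep(seq_len(d[3]), each = 2L), , , drop = FALSE]
}

up_bw <- function(dy) {
  d <- dim(dy); nd <- length(d) - 2L
  if (nd == 2L) {
    o1 <- seq(1L, d[1], 2L); o2 <- seq(1L, d[2], 2L)
    dy[o1, o2, , , drop = FALSE] + dy[o1 + 1L, o2, , , drop = FALSE] +
      dy[o1, o2 + 1L, , , drop = FALSE] + dy[o1 + 1L, o2 + 1L, , , drop = FALSE]
  } else {
    o1 <- seq(1L, d[1], 2L); o2 <- seq(1L, d[2], 2L); o3 <- seq(1L, d[3], 2L)
    acc <- NULL
    for (dz in 0:1) for (dy_ in 0:1) for (dx_ in 0:1) {
      sl <- dy[o1 + dz, o2 + dy_, o3 + dx_, , , drop = FALSE]
      acc <- if (is.null(acc)) sl else acc + sl
    }
    acc
  }
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b); nd <- length(da)
  out <- array(0, c(da[seq_len(nd - 2L)], da[nd - 1L] + db[nd - 1L], da[nd]))
  if (nd == 4L) {
    out[, , seq_len(da[3]), ] <- a
    out[, , da[3] + seq_len(db[3]), ] <- b
  } else {
    out[, , , seq_len(da[4]), ] <- a
    out[, , , da[4] + seq_len(db[4]), ] <- b
  }
  out
}

split_channels <- function(x, c1) {
  nd <- length(dim(x))
  if (nd == 4L)
    list(x[, , seq_len(c1), , drop = FALSE],
         x[, , -seq_len(c1), , drop = FALSE])
  else
    list(x[, , , seq_len(c1), , drop = FALSE],
         x[, , , -seq_len(c1), , drop = FALSE])
}

# ------------------------------------------------------ network forward/back

# x: (H, W, 1, N) or (D, H, W, 1, N), spatial extents divisible by 2^depth.
net_forward <- function(model, x, want_cache = FALSE) {
  sl <- model$spec$activation_slope
  p <- model$params
  switch(model$spec$arch,
    constant = {
      y <- array(p$bias$b, dim(x))
      list(y = y, cache = if (want_cache) list(dims = dim(x)))
    },
    affine = {
      y <- conv_fw(x, p$out)
      list(y = y, cache = if (want_cache) list(x = x))
    },
    fcnn = {
      h1 <- conv_fw(x, p$conv1); a1 <- lrelu_fw(h1, sl)
      h2 <- conv_fw(a1, p$conv2); a2 <- lrelu_fw(h2, sl)
      y <- conv_fw(a2, p$out)
      list(y = y,
           cache = if (want_cache) list(x = x, h1 = h1, a1 = a1, h2 = h2,
                                        a2 = a2))
    },
    { # unet family
      d <- model$spec$depth
      h_enc <- vector("list", d + 1L); e <- vector("list", d + 1L)
      h_enc[[1]] <- conv_fw(x, p$enc0)
      e[[1]] <- lrelu_fw(h_enc[[1]], sl)
      pooled <- vector("list", d)
      for (i in seq_len(d)) {
        pooled[[i]] <- pool_fw(e[[i]])
        h_enc[[i + 1L]] <- conv_fw(pooled[[i]], p[[paste0("enc", i)]])
        e[[i + 1L]] <- lrelu_fw(h_enc[[i + 1L]], sl)
      }
      u <- e[[d + 1L]]
      cc <- vector("list", d); h_dec <- vector("list", d)
      for (j in rev(seq_len(d)) - 1L) {       # j = d-1 .. 0
        cc[[j + 1L]] <- cat_channels(up_fw(u), e[[j + 1L]])
        h_dec[[j + 1L]] <- conv_fw(cc[[j + 1L]], p[[paste0("dec", j)]])
        u <- lrelu_fw(h_dec[[j + 1L]], sl)
        if (j == 0L) u0 <- u
      }
      y <- conv_fw(u0, p$out)
      list(y = y,
           cache = if (want_cache) list(x = x, h_enc = h_enc, e = e,
                                        pooled = pooled, cc = cc,
                                        h_dec = h_dec, u0 = u0))
    })
}

# Returns gradients w.r.t. every parameter, shaped like model$params.
net_backward <- function(model, cache, dy) {
  sl <- model$spec$activation_slope
  p <- model$params
  g <- list()
  switch(model$spec$arch,
    constant = {
      g$bias <- list(b = sum(dy))
    },
    affine = {
      r <- conv_bw(cache$x, p$out, dy, need_dx = FALSE)
      g$out <- list(w = r$dw, b = r$db)
    },
    fcnn = {
      r3 <- conv_bw(cache$a2, p$out, dy)
      g$out <- list(w = r3$dw, b = r3$db)
      da2 <- lrelu_bw(cache$h2, r3$dx, sl)
      r2 <- conv_bw(cache$a1, p$conv2, da2)
      g$conv2 <- list(w = r2$dw, b = r2$db)
      da1 <- lrelu_bw(cache$h1, r2$dx, sl)
      r1 <- conv_bw(cache$x, p$conv1, da1, need_dx = FALSE)
      g$conv1 <- list(w = r1$dw, b = r1$db)
    },
    { # unet family
      d <- model$spec$depth
      w <- model$spec$base_width
      r_out <- conv_bw(cache$u0, p$out, dy)
      g$out <- list(w = r_out$dw, b = r_out$db)
      dU <- vector("list", d + 1L)  # dU[[j+1]] = grad wrt u_j
      dE <- vector("list", d + 1L)  # accumulated grads wrt e[[i]]
      dU[[1]] <- r_out$dx
      for (j in seq_len(d) - 1L) {  # j = 0 .. d-1 (reverse of decoder)
        dh <- lrelu_bw(cache$h_dec[[j + 1L]], dU[[j + 1L]], sl)
        r <- conv_bw(cache$cc[[j + 1L]], p[[paste0("dec", j)]], dh)
        g[[paste0("dec", j)]] <- list(w = r$dw, b = r$db)
        sp <- split_channels(r$dx, w)
        dE[[j + 1L]] <- if (is.null(dE[[j + 1L]])) sp[[2]] else
          dE[[j + 1L]] + sp[[2]]
        dU[[j + 2L]] <- up_bw(sp[[1]])
      }
      dE[[d + 1L]] <- if (is.null(dE[[d + 1L]])) dU[[d + 1L]] else
        dE[[d + 1L]] + dU[[d + 1L]]
      for (i in rev(seq_len(d))) {
        dh <- lrelu_bw(cache$h_enc[[i + 1L]], dE[[i + 1L]], sl)
        r <- conv_bw(cache$pooled[[i]], p[[paste0("enc", i)]], dh)
        g[[paste0("enc", i)]] <- list(w = r$dw, b = r$db)
        dpool <- pool_bw(cache$e[[i]], cache$pooled[[i]], r$dx)
        dE[[i]] <- if (is.null(dE[[i]])) dpool else dE[[i]] + dpool
      }
      dh0 <- lrelu_bw(cache$h_enc[[1]], dE[[1]], sl)
      r0 <- conv_bw(cache$x, p$enc0, dh0, need_dx = FALSE)
      g$enc0 <- list(w = r0$dw, b = r0$db)
    })
  g
}

# ----------------------------------------------------------- public forward

# Symmetric (edge-duplicating) padding of the trailing spatial sides up to a
# multiple of `align`; returns padded array and the original extents.
pad_to_multiple <- function(arr, align) {
  d <- dim(arr); nd <- length(d) - 2L
  sp <- d[seq_len(nd)]
  target <- as.integer(ceiling(sp / align) * align)
  if (all(target == sp)) return(list(arr = arr, orig = sp))
  idx <- lapply(seq_len(nd), function(i) {
    extra <- target[i] - sp[i]
    if (extra > sp[i])
      stop("image too small to pad to the pooling alignment; use a shallower model")
    c(seq_len(sp[i]), rev(seq_len(sp[i]))[seq_len(extra)])
  })
  arr2 <- if (nd == 2L) arr[idx[[1]], idx[[2]], , , drop = FALSE]
          else arr[idx[[1]], idx[[2]], idx[[3]], , , drop = FALSE]
  list(arr = arr2, orig = sp)
}

#' Apply a denoiser to a normalized image or volume
#'
#' The input is expected to be normalized (see [normalize_image()]); the
#' output has identical shape. Sides not divisible by `2^depth` are
#' reflect-padded internally and cropped back.
#'
#' @param model a `cdn_denoiser`.
#' @param x an [image_plane()] / [volume()] / matrix / 3D array.
#' @return denoised object of the same type and shape.
#' @export
forward <- function(model, x) {
  stopifnot(inherits(model, "cdn_denoiser"))
  is2 <- model$ndim == 2L
  wrap <- NULL
  if (inherits(x, "image_plane")) { wrap <- x; data <- x$data }
  else if (inherits(x, "volume")) { wrap <- x; data <- x$data }
  else data <- x
  nd <- length(dim(data))
  if (is.null(dim(data)) || any(dim(data) == 0L))
    stop("forward: zero-extent input")
  if (is2 && nd != 2L) stop("forward: 2D model applied to non-2D input")
  if (!is2 && nd != 3L) stop("forward: 3D model applied to non-3D input")
  arr <- array(data, c(dim(data), 1L, 1L))
  pp <- pad_to_multiple(arr, model$align)
  y <- net_forward(model, pp$arr)$y
  out <- if (is2) y[seq_len(pp$orig[1]), seq_len(pp$orig[2]), 1L, 1L]
         else y[seq_len(pp$orig[1]), seq_len(pp$orig[2]), seq_len(pp$orig[3]),
                1L, 1L]
  if (!all(is.finite(out))) stop("forward: non-finite output")
  if (is.null(wrap)) return(out)
  wrap[["data"]] <- out
  wrap
}

# ------------------------------------------------------------- checkpoints

#' Save a trained denoiser to a single-file checkpoint
#' @param model a `cdn_denoiser`.
#' @param path destination file.
#' @return `invisible(path)`.
#' @export
save_denoiser <- function(model, path) {
  stopifnot(inherits(model, "cdn_denoiser"))
  obj <- list(format = "cryodenoise-checkpoint", version = 1L,
              spec = unclass(model$spec), params = model$params)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a denoiser checkpoint written by [save_denoiser()]
#' @param path checkpoint file.
#' @return a `cdn_denoiser`.
#' @export
load_denoiser <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "cryodenoise-checkpoint"))
    stop(sprintf("'%s' is not a cryodenoise checkpoint", path))
  spec <- do.call(model_spec, obj$spec[c("arch", "base_width", "depth",
                                         "activation_slope", "seed")])
  model <- build_model(spec)
  model$params <- obj$params
  model
}
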