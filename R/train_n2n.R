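# Noise2Noise training: whole-image normalization, aligned patch sampling,
# dihedral augmentation, the L1/L2/smoothed-L0 objectives and a deterministic
# Adagrad loop that trains in both directions (denoise even -> match odd and
# vice versa).

#' Normalize an image to zero mean, unit (population) standard deviation
#'
#' Normalization is at the whole micrograph/volume level; the returned stats
#' invert it exactly: `x == normalized * std + mean`.
#'
#' @param image [image_plane()], [volume()], matrix or array with at least
#'   two distinct values.
#' @return list with `data` (same type as input, normalized) and `stats`
#'   (list with `mean`, `std`).
#' @export
normalize_image <- function(image) {
  raw <- if (inherits(image, "image_plane") || inherits(image, "volume"))
    image$data else image
  m <- mean(raw)
  s <- sqrt(mean((raw - m)^2))
  if (!is.finite(s) || s == 0)
    stop("normalize_image: degenerate micrograph (zero standard deviation)")
  norm <- (raw - m) / s
  out <- image
  if (inherits(image, "image_plane") || inherits(image, "volume"))
    out$data <- norm else out <- norm
  list(data = out, stats = list(mean = m, std = s))
}

#' Invert [normalize_image()]
#' @param image normalized image (same types as [normalize_image()]).
#' @param stats the `stats` element returned by [normalize_image()].
#' @return image restored to the original intensity scale.
#' @export
denormalize_image <- function(image, stats) {
  raw <- if (inherits(image, "image_plane") || inherits(image, "volume"))
    image$data else image
  res <- raw * stats$std + stats$mean
  out <- image
  if (inherits(image, "image_plane") || inherits(image, "volume"))
    out$data <- res else out <- res
  out
}

#' Sample aligned patch pairs from a noise pair
#'
#' Top-left corners are uniform over all valid positions; `patch_a` and
#' `patch_b` are cut at identical coordinates from the even and odd planes.
#' Patches larger than the image are shrunk to fit (with a warning). Uses the
#' current R RNG stream, so seeding makes the coordinate sequence
#' reproducible.
#'
#' @param pair a [noise_pair()].
#' @param patch square patch side in pixels.
#' @param n number of pairs to draw.
#' @return list of `n` lists with elements `a`, `b` (matrices) and `y0`,
#'   `x0` (0-based top-left coordinates).
#' @export
sample_patch_pairs <- function(pair, patch, n) {
  stopifnot(inherits(pair, "noise_pair"))
  ev <- pair$even$data; od <- pair$odd$data
  h <- nrow(ev); w <- ncol(ev)
  eff <- min(patch, h, w)
  if (eff < patch)
    warning(sprintf("patch %d shrunk to %d to fit a %d x %d micrograph",
                    patch, eff, h, w))
  lapply(seq_len(n), function(i) {
    y0 <- sample.int(h - eff + 1L, 1L) - 1L
    x0 <- sample.int(w - eff + 1L, 1L) - 1L
    list(a = ev[y0 + seq_len(eff), x0 + seq_len(eff), drop = FALSE],
         b = od[y0 + seq_len(eff), x0 + seq_len(eff), drop = FALSE],
         y0 = y0, x0 = x0)
  })
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

# Apply dihedral-group element t (0..7): rotation by 90*(t %% 4) degrees,
# then mirror when t >= 4. Pure pixel permutation, no interpolation.
apply_dihedral <- function(m, transform) {
  r <- transform %% 4L
  if (r %in% c(1L, 3L) && nrow(m) != ncol(m))
    stop("augment_pair: rotation of a non-square patch")
  for (i in seq_len(r)) m <- rot90cw(m)
  if (transform >= 4L) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  m
}

#' Augment a patch pair with a random rotation/mirror
#'
#' The same element of the 8-element dihedral group (rotations by 0/90/180/270
#' degrees, optionally mirrored) is applied to both patches; only right-angle
#' rotations are used so no interpolation ever occurs.
#'
#' @param pa,pb square patches (matrices).
#' @param transform optional element 0..7; drawn uniformly from the current
#'   RNG stream when `NULL`.
#' @return list with `a`, `b` and the `transform` applied.
#' @export
augment_pair <- function(pa, pb, transform = NULL) {
  if (is.null(transform)) transform <- sample.int(8L, 1L) - 1L
  if (!transform %in% 0:7) stop("augment_pair: transform must be in 0..7")
  list(a = apply_dihedral(pa, transform), b = apply_dihedral(pb, transform),
       transform = transform)
}

#' Noise2Noise patch loss
#'
#' `l2` is the mean squared difference (mean-seeking), `l1` the mean absolute
#' difference (median-seeking), `l0` the smoothed mode-seeking objective
#' `mean((|d| + eps)^gamma)` with `gamma` annealed during training.
#'
#' @param pred,target equal-shape numeric arrays.
#' @param mode `"l2"`, `"l1"` or `"l0"`.
#' @param gamma exponent for `l0` smoothing.
#' @param eps stabilizer for `l0`.
#' @return scalar loss >= 0.
#' @export
pair_loss <- function(pred, target, mode = c("l2", "l1", "l0"), gamma = 2,
                      eps = 1e-8) {
  mode <- match.arg(mode)
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target))
    stop("pair_loss: shape mismatch")
  d <- pred - target
  switch(mode,
         l2 = mean(d * d),
         l1 = mean(abs(d)),
         l0 = mean((abs(d) + eps)^gamma))
}

loss_grad <- function(pred, target, mode, gamma = 2, eps = 1e-8) {
  d <- pred - target
  n <- length(d)
  switch(mode,
         l2 = 2 * d / n,
         l1 = sign(d) / n,
         l0 = gamma * (abs(d) + eps)^(gamma - 1) * sign(d) / n)
}

#' Training configuration
#'
#' Defaults follow the published recipe: Adagrad, learning rate 0.001 for 100
#' epochs, 800x800 patches, minibatch 4, right-angle rotation + mirror
#' augmentation.
#'
#' @param loss_mode `"l2"`, `"l1"` or `"l0"`.
#' @param lr Adagrad learning rate.
#' @param epochs training epochs (one sampled patch per pair per epoch).
#' @param batch minibatch size.
#' @param patch square patch side in pixels.
#' @param augment apply random dihedral augmentation.
#' @param seed RNG seed controlling sampling (weight init is governed by the
#'   model spec's own seed).
#' @param l0_gamma_start,l0_gamma_end linear annealing schedule for the `l0`
#'   exponent.
#' @param l0_eps stabilizer for the `l0` objective.
#' @return a `cdn_train_config`.
#' @export
train_config <- function(loss_mode = "l2", lr = 0.001, epochs = 100L,
                         batch = 4L, patch = 800L, augment = TRUE, seed = 0L,
                         l0_gamma_start = 2, l0_gamma_end = 0.01,
                         l0_eps = 1e-8) {
  stopifnot(loss_mode %in% c("l1", "l2", "l0"), epochs >= 1L, batch >= 1L,
            patch >= 1L, lr > 0)
  structure(list(loss_mode = loss_mode, lr = lr, epochs = as.integer(epochs),
                 batch = as.integer(batch), patch = as.integer(patch),
                 augment = isTRUE(augment), seed = as.integer(seed),
                 l0_gamma_start = l0_gamma_start, l0_gamma_end = l0_gamma_end,
                 l0_eps = l0_eps),
            class = "cdn_train_config")
}

# Stack square patches into an (eff, eff, 1, N) batch array.
stack_patches <- function(patches) {
  eff <- nrow(patches[[1]])
  array(unlist(patches, use.names = FALSE), dim = c(eff, eff, 1L,
                                                    length(patches)))
}

#' Train a denoiser on even/odd noise pairs
#'
#' Each half of every pair is normalized independently at the whole-image
#' level. Every epoch samples one augmented patch per pair; each minibatch
#' trains in both directions, with total loss
#' `0.5 * (loss(f(a), b) + loss(f(b), a))`, optimized by Adagrad. Fully
#' deterministic given `cfg$seed` and `spec$seed`.
#'
#' @param pairs list of [noise_pair()] objects (at least one).
#' @param spec a [model_spec()] for a 2D architecture.
#' @param cfg a [train_config()].
#' @param val_pairs optional held-out pairs; when given, the symmetric
#'   whole-image loss is recorded per epoch.
#' @param verbose log per-epoch loss to stderr.
#' @return list with `model` (trained `cdn_denoiser`) and `history`
#'   (numeric per-epoch training loss; held-out loss in
#'   `attr(history, "val")`).
#' @export
train_denoiser <- function(pairs, spec, cfg = train_config(),
                           val_pairs = NULL, verbose = FALSE) {
  stopifnot(length(pairs) >= 1L, inherits(spec, "cdn_model_spec"),
            inherits(cfg, "cdn_train_config"))
  if (spec_ndim(spec) != 2L)
    stop("train_denoiser: 2D pairs require a 2D architecture")
  rf <- receptive_field(spec)
  if (cfg$patch < rf)
    stop(sprintf("patch %d is smaller than the model receptive field %d",
                 cfg$patch, rf))
  model <- build_model(spec)
  align <- model$align

  norm_half <- function(p) normalize_image(p$data)$data
  evs <- lapply(pairs, function(p) norm_half(p$even))
  ods <- lapply(pairs, function(p) norm_half(p$odd))
  norm_pairs <- mapply(function(e, o) noise_pair(e, o), evs, ods,
                       SIMPLIFY = FALSE)
  if (!is.null(val_pairs)) {
    val_norm <- lapply(val_pairs, function(p)
      list(a = norm_half(p$even), b = norm_half(p$odd)))
  }

  # effective patch: shrink to smallest image, then to pooling alignment
  min_side <- min(vapply(norm_pairs, function(p)
    min(dim(p$even$data)), numeric(1)))
  eff <- min(cfg$patch, min_side)
  eff <- (eff %/% align) * align
  if (eff < 1L)
    stop("train_denoiser: images too small for the pooling depth")
  if (eff < min(cfg$patch, min_side))
    warning(sprintf("patch cropped to %d for pooling alignment", eff))

  params <- model$params
  acc <- rapply(params, function(v) v * 0, how = "replace")
  history <- numeric(cfg$epochs)
  val_hist <- if (is.null(val_pairs)) NULL else numeric(cfg$epochs)
  npairs <- length(norm_pairs)
  set.seed(cfg$seed)

  for (epoch in seq_len(cfg$epochs)) {
    gamma <- cfg$l0_gamma_start +
      (cfg$l0_gamma_end - cfg$l0_gamma_start) *
      (if (cfg$epochs > 1L) (epoch - 1) / (cfg$epochs - 1) else 0)
    drawn <- lapply(norm_pairs, function(p) {
      pp <- sample_patch_pairs(p, eff, 1L)[[1]]
      if (cfg$augment) augment_pair(pp$a, pp$b) else pp
    })
    order_idx <- sample.int(npairs)
    epoch_loss <- 0; nb <- 0L
    for (start in seq(1L, npairs, by = cfg$batch)) {
      idx <- order_idx[start:min(npairs, start + cfg$batch - 1L)]
      a <- stack_patches(lapply(drawn[idx], `[[`, "a"))
      b <- stack_patches(lapply(drawn[idx], `[[`, "b"))
      xb <- array(c(a, b), dim = c(dim(a)[1:3], 2L * length(idx)))
      tb <- array(c(b, a), dim = dim(xb))
      model$params <- params
      fw <- net_forward(model, xb, want_cache = TRUE)
      loss <- pair_loss(fw$y, tb, cfg$loss_mode, gamma = gamma,
                        eps = cfg$l0_eps)
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d, minibatch %d", epoch,
                     nb + 1L))
      dy <- loss_grad(fw$y, tb, cfg$loss_mode, gamma = gamma,
                      eps = cfg$l0_eps)
      dim(dy) <- dim(fw$y)
      g <- net_backward(model, fw$cache, dy)
      for (nm in names(g)) {
        for (f in names(g[[nm]])) {
          gv <- g[[nm]][[f]]
          acc[[nm]][[f]] <- acc[[nm]][[f]] + gv * gv
          params[[nm]][[f]] <- params[[nm]][[f]] -
            cfg$lr * gv / (sqrt(acc[[nm]][[f]]) + 1e-10)
        }
      }
      epoch_loss <- epoch_loss + loss; nb <- nb + 1L
    }
    history[epoch] <- epoch_loss / nb
    model$params <- params
    if (!is.null(val_pairs)) {
      vl <- vapply(val_norm, function(v) {
        0.5 * (pair_loss(forward(model, v$a), v$b, cfg$loss_mode,
                         gamma = gamma, eps = cfg$l0_eps) +
               pair_loss(forward(model, v$b), v$a, cfg$loss_mode,
                         gamma = gamma, eps = cfg$l0_eps))
      }, numeric(1))
      val_hist[epoch] <- mean(vl)
    }
    if (verbose)
      message(sprintf("[epoch %d/%d] loss %.6f%s", epoch, cfg$epochs,
                      history[epoch],
                      if (is.null(val_hist)) "" else
                        sprintf(" val %.6f", val_hist[epoch])))
  }
  model$params <- params
  if (!is.null(val_hist)) attr(history, "val") <- val_hist
  list(model = model, history = history)
}
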