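# Even/odd frame pairing and dose fractionation.
#
# "Even" frames are 0-based indices 0, 2, 4, ... so an odd-length stack gives
# its extra frame to the even half. Frames are assumed gain-corrected; frame
# alignment is out of scope (pre-aligned per-half stacks can be paired with
# noise_pair() directly).

#' Paired independent observations of one signal
#'
#' @param even,odd [image_plane()]s (or matrices) of identical shape, summed
#'   from disjoint frame subsets of one exposure.
#' @param source identifier of the originating stack.
#' @param dose_even,dose_odd optional e-/A^2 accumulated in each half.
#' @return a `noise_pair` object.
#' @export
noise_pair <- function(even, odd, source = "memory", dose_even = NULL,
                       dose_odd = NULL) {
  even <- as_image_plane(even); odd <- as_image_plane(odd)
  if (!identical(dim(even$data), dim(odd$data)))
    stop("noise_pair: even and odd shapes differ")
  structure(list(even = even, odd = odd, source = source,
                 dose_even = dose_even, dose_odd = dose_odd),
            class = "noise_pair")
}

#' @export
print.noise_pair <- function(x, ...) {
  cat(sprintf("<noise_pair %d x %d> %s\n", nrow(x$even$data),
              ncol(x$even$data), x$source))
  invisible(x)
}

# Pairwise (tree) summation of a list of matrices: associativity-stable and
# more accurate than left-to-right accumulation for many frames.
sum_frames_list <- function(frames) {
  while (length(frames) > 1L) {
    n <- length(frames)
    out <- vector("list", ceiling(n / 2))
    for (i in seq_along(out)) {
      a <- 2L * i - 1L
      out[[i]] <- if (a + 1L <= n) frames[[a]] + frames[[a + 1L]] else frames[[a]]
    }
    frames <- out
  }
  frames[[1]]
}

#' Split a movie stack into an even/odd Noise2Noise pair
#'
#' Frames at 0-based indices 0, 2, 4, ... are summed into the even half and
#' 1, 3, 5, ... into the odd half; the two halves are independent
#' observations of the same specimen signal and
#' `even + odd == sum_frames(stack)` exactly.
#'
#' @param stack a [movie_stack()] with at least 2 frames.
#' @return a [noise_pair()].
#' @export
split_even_odd <- function(stack) {
  stopifnot(inherits(stack, "movie_stack"))
  nf <- n_frames(stack)
  if (nf < 2L)
    stop("split_even_odd: cannot form independent pair from a single frame")
  ie <- seq(1L, nf, by = 2L)  # 0-based 0,2,4,...
  io <- seq(2L, nf, by = 2L)
  dose <- stack$dose_per_frame
  noise_pair(even = image_plane(sum_frames_list(stack$frames[ie]),
                                pixel_size = stack$pixel_size),
             odd = image_plane(sum_frames_list(stack$frames[io]),
                               pixel_size = stack$pixel_size),
             source = stack$origin_name,
             dose_even = if (is.null(dose)) NULL else dose * length(ie),
             dose_odd = if (is.null(dose)) NULL else dose * length(io))
}

#' Keep the leading fraction of an exposure
#'
#' Returns the first `k = floor(fraction * n_frames)` frames, i.e. the dose
#' fraction is rounded down to the nearest whole frame. A prefix operation:
#' `fractionate_frames(s, 0.25)` frames are a prefix of
#' `fractionate_frames(s, 0.5)` frames.
#'
#' @param stack a [movie_stack()].
#' @param fraction dose fraction in (0, 1].
#' @return a [movie_stack()] with the first `k` frames; per-frame dose kept.
#' @export
fractionate_frames <- function(stack, fraction) {
  stopifnot(inherits(stack, "movie_stack"))
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("fractionate_frames: fraction must lie in (0, 1]")
  k <- floor(fraction * n_frames(stack))
  if (k < 1L)
    stop(sprintf(
      "fractionate_frames: fraction %.4g of %d frames rounds down to 0 frames",
      fraction, n_frames(stack)))
  movie_stack(stack$frames[seq_len(k)], dose_per_frame = stack$dose_per_frame,
              pixel_size = stack$pixel_size, origin_name = stack$origin_name)
}

#' Sum all frames of a stack into one full-dose micrograph
#'
#' @param stack a [movie_stack()].
#' @return an [image_plane()].
#' @export
sum_frames <- function(stack) {
  stopifnot(inherits(stack, "movie_stack"))
  image_plane(sum_frames_list(stack$frames), pixel_size = stack$pixel_size,
              origin_name = stack$origin_name)
}

#' Cap the number of micrographs contributed per source dataset
#'
#' Dataset balancing for aggregate training sets: each named group keeps at
#' most `max_per_dataset` entries, sampled with a fixed seed.
#'
#' @param items list of pairable items (paths or objects).
#' @param groups character vector, one dataset label per item.
#' @param max_per_dataset cap (default 200).
#' @param seed RNG seed for the subsample.
#' @return indices (into `items`) of the balanced selection, in input order.
#' @export
balance_datasets <- function(items, groups, max_per_dataset = 200L, seed = 0L) {
  stopifnot(length(items) == length(groups))
  keep <- integer(0)
  with_seed(seed, {
    for (g in unique(groups)) {
      idx <- which(groups == g)
      if (length(idx) > max_per_dataset)
        idx <- sort(sample(idx, max_per_dataset))
      keep <- c(keep, idx)
    }
  })
  sort(keep)
}

# Evaluate an expression under a local, restored RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}
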