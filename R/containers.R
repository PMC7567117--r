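# Core data containers. All are light S3 wrappers over plain arrays so that
# every numerical routine can also be called on bare matrices/arrays.
#
# Conventions (used throughout the package):
#   * 2D data are matrices indexed [y, x]; 3D data are arrays indexed [z, y, x]
#   * coordinates are 0-based in all interval/region arguments,
#     intervals are half-open [start, end)

#' Single 2D image (micrograph)
#'
#' @param data numeric matrix, rows = Y, cols = X; must be finite.
#' @param pixel_size optional pixel size in Angstrom/pixel (> 0).
#' @param origin_name source identifier (e.g. file path).
#' @return an `image_plane` object.
#' @export
image_plane <- function(data, pixel_size = NULL, origin_name = "memory") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop("image_plane: shape must be at least 1x1")
  if (!all(is.finite(data)))
    stop("image_plane: data contains non-finite values")
  if (!is.null(pixel_size)) {
    pixel_size <- as.numeric(pixel_size)
    if (!is.finite(pixel_size) || pixel_size <= 0)
      stop("image_plane: pixel_size must be > 0")
  }
  structure(list(data = data, pixel_size = pixel_size,
                 origin_name = origin_name),
            class = "image_plane")
}

#' 3D volume (tomogram)
#'
#' @param data numeric 3D array indexed `[z, y, x]`; must be finite.
#' @param voxel_size optional voxel size in Angstrom/voxel (> 0).
#' @param origin_name source identifier.
#' @return a `volume` object.
#' @export
volume <- function(data, voxel_size = NULL, origin_name = "memory") {
  if (length(dim(data)) != 3L)
    stop("volume: data must be a 3D array (Z, Y, X)")
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("volume: data contains non-finite values")
  if (!is.null(voxel_size)) {
    voxel_size <- as.numeric(voxel_size)
    if (!is.finite(voxel_size) || voxel_size <= 0)
      stop("volume: voxel_size must be > 0")
  }
  structure(list(data = data, voxel_size = voxel_size,
                 origin_name = origin_name),
            class = "volume")
}

#' Movie stack: ordered raw detector frames of one exposure
#'
#' @param frames list of numeric matrices, all the same shape (or a 3D array
#'   indexed `[frame, y, x]`).
#' @param dose_per_frame optional electron dose per frame in e-/A^2 (>= 0).
#' @param pixel_size optional pixel size in Angstrom/pixel.
#' @param origin_name source identifier.
#' @return a `movie_stack` object.
#' @export
movie_stack <- function(frames, dose_per_frame = NULL, pixel_size = NULL,
                        origin_name = "memory") {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[1]), function(i) frames[i, , ])
  }
  if (!is.list(frames) || length(frames) < 1L)
    stop("movie_stack: need at least one frame")
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f); storage.mode(f) <- "double"; f
  })
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(ok)) stop("movie_stack: all frames must share one shape")
  if (!all(vapply(frames, function(f) all(is.finite(f)), logical(1))))
    stop("movie_stack: frames contain non-finite values")
  if (!is.null(dose_per_frame)) {
    dose_per_frame <- as.numeric(dose_per_frame)
    if (!is.finite(dose_per_frame) || dose_per_frame < 0)
      stop("movie_stack: dose_per_frame must be >= 0")
  }
  structure(list(frames = frames, dose_per_frame = dose_per_frame,
                 pixel_size = pixel_size, origin_name = origin_name),
            class = "movie_stack")
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane %d x %d%s> %s\n", nrow(x$data), ncol(x$data),
              if (is.null(x$pixel_size)) "" else
                sprintf(" @ %.3f A/px", x$pixel_size), x$origin_name))
  invisible(x)
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume %d x %d x %d (Z,Y,X)%s> %s\n", d[1], d[2], d[3],
              if (is.null(x$voxel_size)) "" else
                sprintf(" @ %.3f A/vox", x$voxel_size), x$origin_name))
  invisible(x)
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<movie_stack %d frames of %d x %d%s> %s\n", length(x$frames),
              d[1], d[2],
              if (is.null(x$dose_per_frame)) "" else
                sprintf(", %.3g e-/A^2 per frame", x$dose_per_frame),
              x$origin_name))
  invisible(x)
}

#' Number of frames in a movie stack
#' @param stack a `movie_stack`.
#' @return integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "movie_stack"))
  length(stack$frames)
}

#' Total electron dose of a movie stack
#' @param stack a `movie_stack`.
#' @return total dose in e-/A^2, or `NULL` when the per-frame dose is unknown.
#' @export
total_dose <- function(stack) {
  stopifnot(inherits(stack, "movie_stack"))
  if (is.null(stack$dose_per_frame)) return(NULL)
  stack$dose_per_frame * n_frames(stack)
}

# Coerce plain matrices / arrays to the container types where convenient.
as_image_plane <- function(x) {
  if (inherits(x, "image_plane")) return(x)
  image_plane(x)
}

as_volume <- function(x) {
  if (inherits(x, "volume")) return(x)
  volume(x)
}

# Extract the raw array from a container or pass a bare array through.
plane_data <- function(x) if (inherits(x, "image_plane")) x$data else as.matrix(x)
volume_data <- function(x) if (inherits(x, "volume")) x$data else x
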