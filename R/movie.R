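#' Movie containers
#'
#' Time-lapse movies are stored as plain 3-D numeric arrays indexed
#' `[row, col, frame]` with two calibration attributes: `pixel_size`
#' (micrometres per pixel) and `frame_interval` (seconds between frames).
#' `intensity_movie()` wraps a fluorescence channel; `label_movie()` wraps
#' integer label images in which `0` marks membrane ridges / background and
#' positive integers identify cells.
#'
#' @param data 3-D numeric array `[row, col, frame]`, or a list of equally
#'   sized matrices (one per frame).
#' @param pixel_size Pixel size in micrometres per pixel. Must be positive.
#' @param frame_interval Time between consecutive frames, in seconds.
#'   Must be positive.
#' @return An array of class `intensity_movie` or `label_movie` (both also
#'   class `epimovie`).
#' @examples
#' m <- intensity_movie(array(runif(4 * 4 * 3), c(4, 4, 3)),
#'                      pixel_size = 0.3, frame_interval = 5)
#' n_frames(m)
#' @export
intensity_movie <- function(data, pixel_size, frame_interval) {
  new_movie(data, pixel_size, frame_interval, "intensity_movie")
}

#' @rdname intensity_movie
#' @export
label_movie <- function(data, pixel_size, frame_interval) {
  m <- new_movie(data, pixel_size, frame_interval, "label_movie")
  if (any(m < 0) || any(m != floor(m))) {
    abort("label_movie frames must contain non-negative integers")
  }
  m
}

new_movie <- function(data, pixel_size, frame_interval, class) {
  if (is.list(data)) {
    stopifnot(length(data) >= 1)
    data <- array(unlist(data, use.names = FALSE),
                  dim = c(dim(data[[1]]), length(data)))
  }
  if (length(dim(data)) == 2) data <- array(data, c(dim(data), 1))
  if (length(dim(data)) != 3) abort("movie data must be [row, col, frame]")
  check_positive(pixel_size, "pixel_size")
  check_positive(frame_interval, "frame_interval")
  structure(data,
            pixel_size = pixel_size,
            frame_interval = frame_interval,
            class = c(class, "epimovie"))
}

#' @rdname intensity_movie
#' @param x A movie object.
#' @export
n_frames <- function(x) dim(x)[3]

#' @rdname intensity_movie
#' @export
pixel_size <- function(x) attr(x, "pixel_size")

#' @rdname intensity_movie
#' @export
frame_interval <- function(x) attr(x, "frame_interval")

#' Extract a single frame as a matrix
#'
#' @param x A movie object.
#' @param i Frame index (1-based).
#' @return A matrix.
#' @export
movie_frame <- function(x, i) {
  stopifnot(i >= 1, i <= n_frames(x))
  x[, , i, drop = TRUE]
}

#' @export
print.epimovie <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<%s> %d x %d px, %d frames, %.3g um/px, dt = %.3g s\n",
              class(x)[1], d[1], d[2], d[3],
              pixel_size(x), frame_interval(x)))
  invisible(x)
}

#' Read and write movies as multi-page TIFF
#'
#' Movies are written as 16-bit multi-page TIFF files, the standard
#' interchange format of time-lapse microscopy. Intensity movies are
#' scaled to the full 16-bit range on write; label movies are written
#' verbatim (label values must stay below 65536).
#'
#' @param movie A movie object.
#' @param path Path to a `.tif` file.
#' @param pixel_size,frame_interval Calibration to attach on read
#'   (TIFF files do not carry the frame interval).
#' @param labels If `TRUE` the pages are interpreted as integer labels.
#' @return `write_movie_tiff()` returns `path` invisibly;
#'   `read_movie_tiff()` returns a movie object.
#' @export
write_movie_tiff <- function(movie, path) {
  frames <- lapply(seq_len(n_frames(movie)), function(i) movie_frame(movie, i))
  if (inherits(movie, "label_movie")) {
    if (max(vapply(frames, max, 0)) > 65535) abort("labels exceed 16-bit range")
    frames <- lapply(frames, function(f) f / 65535)
  } else {
    hi <- max(vapply(frames, max, 0), 1e-12)
    frames <- lapply(frames, function(f) pmax(f, 0) / hi)
  }
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, pixel_size, frame_interval, labels = FALSE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (labels) {
    pages <- lapply(pages, function(p) round(p * 65535))
    label_movie(pages, pixel_size, frame_interval)
  } else {
    intensity_movie(pages, pixel_size, frame_interval)
  }
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive finite number", name))
  }
  invisible(x)
}
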