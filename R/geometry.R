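#' Opening angle at a vertex
#'
#' The angle, in degrees, between the rays from `vertex` to the two rim
#' points — the standard measure of organ folding (smaller angle = more
#' folded). Invariant under rotation, translation and uniform scaling.
#'
#' @param vertex,rim1,rim2 Numeric length-2 vectors (x, y); the three
#'   points must be distinct.
#' @return Angle in degrees, in `(0, 180]`, reported to 1 decimal.
#' @examples
#' opening_angle(c(0, 0), c(1, 0), c(0, 1))  # 90
#' @export
opening_angle <- function(vertex, rim1, rim2) {
  u <- rim1 - vertex
  v <- rim2 - vertex
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu <= .Machine$double.eps || nv <= .Machine$double.eps) {
    abort("rim points must be distinct from the vertex")
  }
  ca <- sum(u * v) / (nu * nv)
  round(acos(pmin(pmax(ca, -1), 1)) * 180 / pi, 1)
}

polyline_length <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2) abort("polyline needs at least 2 points")
  if (any(rowSums(abs(diff(pts))) == 0)) {
    abort("polyline has repeated consecutive points")
  }
  sum(sqrt(rowSums(diff(pts)^2)))
}

# shortest distance from point p to segment (a, b)
point_segment_dist <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  l2 <- vx^2 + vy^2
  t <- ifelse(l2 > 0, ((px - ax) * vx + (py - ay) * vy) / l2, 0)
  t <- pmin(pmax(t, 0), 1)
  sqrt((ax + t * vx - px)^2 + (ay + t * vy - py)^2)
}

point_polyline_dist <- function(p, pts) {
  a <- pts[-nrow(pts), , drop = FALSE]
  b <- pts[-1, , drop = FALSE]
  min(point_segment_dist(p[1], p[2], a[, 1], a[, 2], b[, 1], b[, 2]))
}

#' Apical/basal contour lengths and tissue width
#'
#' Arc lengths of the two contours (polyline length times `pixel_size`)
#' and the mean tissue width: the average, over apical vertices, of the
#' nearest distance to the basal polyline (nearest-distance rather than
#' normal projection, for robustness on curved contours).
#'
#' @param apical,basal Two-column matrices of polyline points, px.
#' @param pixel_size Micrometres per pixel.
#' @return A one-row tibble: `apical_len_um`, `basal_len_um`,
#'   `mean_width_um`.
#' @export
contour_metrics <- function(apical, basal, pixel_size = 1) {
  check_positive(pixel_size, "pixel_size")
  apical <- as.matrix(apical); basal <- as.matrix(basal)
  la <- polyline_length(apical) * pixel_size
  lb <- polyline_length(basal) * pixel_size
  w <- mean(vapply(seq_len(nrow(apical)), function(i) {
    point_polyline_dist(apical[i, ], basal)
  }, numeric(1))) * pixel_size
  tibble::tibble(apical_len_um = la, basal_len_um = lb, mean_width_um = w)
}

#' Read point/polyline annotations from JSON
#'
#' Annotation files carry a list of records
#' `{frame, surface, points: [[x, y], ...]}`, replacing interactive
#' contour tracing with coordinate files.
#'
#' @param path JSON file.
#' @return A tibble with `frame`, `surface` and a list-column `points`
#'   of two-column matrices.
#' @export
read_annotations <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw)) {
    tibble::tibble(frame = raw$frame, surface = raw$surface,
                   points = lapply(raw$points, function(p) {
                     m <- as.matrix(p); colnames(m) <- c("x", "y"); m
                   }))
  } else {
    dplyr::bind_rows(lapply(raw, function(r) {
      m <- do.call(rbind, lapply(r$points, unlist))
      colnames(m) <- c("x", "y")
      tibble::tibble(frame = r$frame, surface = r$surface,
                     points = list(m))
    }))
  }
}

#' Write tidy tracks to CSV
#'
#' @param tracks A tracks tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  readr::write_csv(tracks, path)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
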