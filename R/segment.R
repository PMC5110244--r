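#' Watershed segmentation of a membrane image
#'
#' Smooths the membrane channel with a Gaussian, inverts it and floods the
#' resulting topography with a seeded watershed (h-minima style basin
#' merging via the flooding tolerance). Pixels on the watershed ridge are
#' labelled 0; every other pixel belongs to exactly one region.
#'
#' @param img 2-D numeric matrix (membrane intensity), or a movie frame.
#' @param smoothing_sigma Gaussian pre-smoothing sigma in px.
#' @param h_min Basin-merging depth as a fraction of the smoothed image's
#'   dynamic range (the watershed flooding tolerance).
#' @param ridge_frac Membrane-ridge threshold as a fraction of the
#'   smoothed image's dynamic range; pixels at least this bright are
#'   labelled 0 (membrane).
#' @return An integer label matrix; 0 on membrane ridges / background.
#' @export
segment_frame <- function(img, smoothing_sigma = 1, h_min = 0.1,
                          ridge_frac = 0.5) {
  img <- as.matrix(img)
  if (diff(range(img)) <= .Machine$double.eps) {
    abort("constant image: no membrane signal to segment")
  }
  s <- as.matrix(EBImage::gblur(img, sigma = smoothing_sigma))
  inv <- max(s) - s
  lab <- EBImage::watershed(inv, tolerance = h_min * diff(range(s)),
                            ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(img))
  lab <- drop_background_regions(lab)
  # membrane pixels are ridge, not cell; classify on the unsmoothed image
  # so pre-smoothing does not widen the excluded band
  lab[img >= min(img) + ridge_frac * diff(range(img))] <- 0L
  lab
}

# Non-tissue basins: regions touching the image border that are much
# larger than the typical region are background, not cells, and get
# label 0. A tessellation that fills the frame (all regions of similar
# size) is left untouched. Remaining labels are compacted to 1..K.
drop_background_regions <- function(lab, factor = 3) {
  n <- max(lab)
  if (n == 0) return(lab)
  areas <- tabulate(lab[lab > 0], n)
  edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  edge <- edge[edge > 0]
  bg <- intersect(edge, which(areas > factor * median(areas[areas > 0])))
  if (length(bg)) lab[lab %in% bg] <- 0L
  keep <- which(tabulate(lab[lab > 0], n) > 0)
  map <- integer(n)
  map[keep] <- seq_along(keep)
  ifelse(lab > 0, map[pmax(lab, 1L)], 0L)
}

#' @rdname segment_frame
#' @param movie An [intensity_movie()].
#' @param ... Passed to [segment_frame()].
#' @return `segment_movie()` returns a [label_movie()] whose per-frame
#'   labels are *not* yet temporally consistent (see [track_labels()]).
#' @export
segment_movie <- function(movie, ...) {
  frames <- lapply(seq_len(n_frames(movie)),
                   function(i) segment_frame(movie_frame(movie, i), ...))
  label_movie(frames, pixel_size(movie), frame_interval(movie))
}

#' Track segmented cells through time by mask overlap
#'
#' Establishes frame-to-frame correspondence by maximal intersection-over-
#' union of region masks, relabels the movie so a given ID denotes the same
#' cell in every frame, and classifies each track as `complete` or
#' `ambiguous`. A track is ambiguous if the cell touches the image border
#' in any frame, is absent in some frame, or is involved in a weak
#' (`IoU < min_iou`), split or merged match. Only complete tracks should
#' enter downstream statistics.
#'
#' Overlap ties are broken by larger intersection area, then by lower
#' candidate label, so the result is deterministic and invariant to
#' per-frame label permutations.
#'
#' @param labels A [label_movie()] (>= 2 frames) with per-frame labels,
#'   e.g. from [segment_movie()].
#' @param min_iou Minimum IoU for an unambiguous match.
#' @return A list with `labels` (relabelled, consistent [label_movie()])
#'   and `cells` (tibble: `cell_id`, `status`, `n_frames_present`,
#'   `first_frame`, `last_frame`).
#' @export
track_labels <- function(labels, min_iou = 0.5) {
  stopifnot(inherits(labels, "label_movie"))
  nfr <- n_frames(labels)
  if (nfr < 2) abort("tracking needs at least 2 frames")
  for (t in seq_len(nfr)) {
    if (all(labels[, , t] == 0)) abort(sprintf("frame %d is empty", t))
  }
  out <- array(0L, dim(labels))
  f1 <- labels[, , 1]
  n1 <- max(f1)
  ids1 <- seq_len(n1)[tabulate(f1[f1 > 0], n1) > 0]
  map <- integer(n1); map[ids1] <- seq_along(ids1)
  out[, , 1] <- ifelse(f1 > 0, map[pmax(f1, 1)], 0L)
  next_id <- length(ids1)
  flags <- new.env()
  mark <- function(id, why) assign(as.character(id), why, envir = flags)

  for (t in 2:nfr) {
    prev <- out[, , t - 1]
    cur <- labels[, , t]
    np <- max(prev); ncur <- max(cur)
    sel <- prev > 0 & cur > 0
    if (any(sel)) {
      code <- (as.integer(prev[sel]) - 1L) * ncur + as.integer(cur[sel])
      inter <- tabulate(code, np * ncur)
      nz <- which(inter > 0)
      pi_ <- (nz - 1L) %/% ncur + 1L
      ci_ <- (nz - 1L) %% ncur + 1L
      ai <- tabulate(prev[prev > 0], np)[pi_]
      aj <- tabulate(cur[cur > 0], ncur)[ci_]
      iou <- inter[nz] / (ai + aj - inter[nz])
      ord <- order(-iou, -inter[nz], ci_)
      matched_p <- logical(np); matched_c <- logical(ncur)
      assign_c <- integer(ncur)
      for (k in ord) {
        p <- pi_[k]; cc <- ci_[k]
        if (matched_p[p] || matched_c[cc]) next
        if (iou[k] < min_iou) {
          # overlapping but weak: both parties become ambiguous
          mark(p, "weak_match")
          next
        }
        matched_p[p] <- TRUE; matched_c[cc] <- TRUE
        assign_c[cc] <- p
      }
      # previous cells that vanished
      present_p <- tabulate(prev[prev > 0], np) > 0
      for (p in which(present_p & !matched_p)) mark(p, "lost")
    } else {
      assign_c <- integer(ncur)
      matched_c <- logical(ncur)
    }
    present_c <- tabulate(cur[cur > 0], ncur) > 0
    lut <- integer(ncur)
    for (cc in which(present_c)) {
      id <- assign_c[cc]
      if (id == 0L) {
        next_id <- next_id + 1L
        id <- next_id
        mark(id, "appeared")
      }
      lut[cc] <- id
    }
    out[, , t] <- ifelse(cur > 0, lut[pmax(cur, 1L)], 0L)
  }

  n_total <- next_id
  pres <- matrix(FALSE, n_total, nfr)
  border <- logical(n_total)
  d <- dim(out)
  for (t in seq_len(nfr)) {
    f <- out[, , t]
    pres[, t] <- tabulate(f[f > 0], n_total) > 0
    edge <- unique(c(f[1, ], f[d[1], ], f[, 1], f[, d[2]]))
    border[edge[edge > 0]] <- TRUE
  }
  flagged <- as.integer(ls(envir = flags))
  status <- ifelse(rowSums(pres) == nfr & !border &
                     !(seq_len(n_total) %in% flagged),
                   "complete", "ambiguous")
  cells <- tibble::tibble(
    cell_id = seq_len(n_total),
    status = status,
    n_frames_present = rowSums(pres),
    first_frame = apply(pres, 1, function(p) which(p)[1]) - 1L,
    last_frame = apply(pres, 1, function(p) max(which(p))) - 1L
  )
  list(labels = label_movie(out, pixel_size(labels),
                            frame_interval(labels)),
       cells = cells)
}

#' Measure per-cell areas, centroids and the neighbour graph
#'
#' Area is the membrane-excluded pixel count times `pixel_size^2`
#' (reported to 3 decimals); two cells are neighbours in a frame when at
#' least `min_contact` ridge pixels separate them (or they touch
#' directly).
#'
#' @param tracked Result of [track_labels()] (or a consistent
#'   [label_movie()] plus a `cells` tibble).
#' @param pixel_size Micrometres per pixel; defaults to the movie's
#'   calibration.
#' @param min_contact Minimum shared boundary length in px.
#' @return A list with `tracks` (tibble: `cell_id`, `frame` 0-based,
#'   `time_s`, `area_um2`, `cx_um`, `cy_um`, `status`) and `neighbors`
#'   (tibble: `frame`, `cell_a`, `cell_b`, `contact_px`).
#' @export
measure_areas <- function(tracked, pixel_size = NULL, min_contact = 3) {
  labels <- tracked$labels
  cells <- tracked$cells
  if (is.null(pixel_size)) pixel_size <- pixel_size(labels)
  check_positive(pixel_size, "pixel_size")
  dt <- frame_interval(labels)
  nfr <- n_frames(labels)
  n <- max(cells$cell_id)
  rows <- vector("list", nfr)
  nbrs <- vector("list", nfr)
  for (t in seq_len(nfr)) {
    f <- labels[, , t]
    cnt <- tabulate(f[f > 0], n)
    present <- which(cnt > 0)
    sx <- rowsum(as.numeric(row(f)[f > 0]), f[f > 0])
    sy <- rowsum(as.numeric(col(f)[f > 0]), f[f > 0])
    rows[[t]] <- tibble::tibble(
      cell_id = present,
      frame = t - 1L,
      time_s = (t - 1) * dt,
      area_um2 = round(cnt[present] * pixel_size^2, 3),
      cx_um = as.numeric(sx) / cnt[present] * pixel_size,
      cy_um = as.numeric(sy) / cnt[present] * pixel_size
    )
    nbrs[[t]] <- frame_neighbors(f, n, min_contact, t - 1L)
  }
  tracks <- dplyr::bind_rows(rows)
  tracks <- dplyr::left_join(tracks,
                             cells[, c("cell_id", "status")],
                             by = "cell_id")
  list(tracks = tracks, neighbors = dplyr::bind_rows(nbrs))
}

# Neighbour pairs within one frame: direct label adjacency plus pairs
# separated by a 1-px ridge (look 2 px across in each direction).
frame_neighbors <- function(f, n, min_contact, frame0) {
  nr <- nrow(f); nc <- ncol(f)
  pair <- function(a, b) {
    sel <- a > 0 & b > 0 & a != b
    if (!any(sel)) return(NULL)
    cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel]))
  }
  p <- rbind(
    pair(f[-nr, ], f[-1, ]), pair(f[, -nc], f[, -1]),
    pair(f[1:(nr - 2), ], f[3:nr, ]), pair(f[, 1:(nc - 2)], f[, 3:nc]),
    pair(f[1:(nr - 3), ], f[4:nr, ]), pair(f[, 1:(nc - 3)], f[, 4:nc])
  )
  if (is.null(p) || !nrow(p)) {
    return(tibble::tibble(frame = integer(), cell_a = integer(),
                          cell_b = integer(), contact_px = integer()))
  }
  code <- (p[, 1] - 1) * n + p[, 2]
  cnt <- tabulate(code, n * n)
  nz <- which(cnt >= min_contact)
  tibble::tibble(frame = frame0,
                 cell_a = as.integer((nz - 1) %/% n + 1),
                 cell_b = as.integer((nz - 1) %% n + 1),
                 contact_px = cnt[nz])
}

#' Mean intensity per tracked cell (mask overlap)
#'
#' Overlays the tracked cell masks onto an intensity channel and reports
#' the mean intensity per cell and frame.
#'
#' @param movie An [intensity_movie()].
#' @param labels A temporally consistent [label_movie()].
#' @return A tibble with `cell_id`, `frame` (0-based), `mean_intensity`.
#' @export
measure_intensity <- function(movie, labels) {
  stopifnot(all(dim(movie) == dim(labels)))
  nfr <- n_frames(labels)
  n <- max(labels)
  rows <- vector("list", nfr)
  for (t in seq_len(nfr)) {
    f <- labels[, , t]
    img <- movie[, , t]
    cnt <- tabulate(f[f > 0], n)
    s <- rowsum(as.numeric(img[f > 0]), f[f > 0])
    present <- which(cnt > 0)
    rows[[t]] <- tibble::tibble(cell_id = present, frame = t - 1L,
                                mean_intensity =
                                  as.numeric(s) / cnt[present])
  }
  dplyr::bind_rows(rows)
}
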