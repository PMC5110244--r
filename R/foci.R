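#' Detect and link transient cortical intensity foci
#'
#' Per frame, focus pixels are connected components of the cortical band
#' (a 3-px-wide band inside each cell mask) brighter than
#' `median + k_sigma * MAD` of the band intensity, with at least
#' `min_area_px` pixels. Detections are linked across frames by nearest
#' centroid within `r_max_px`, tolerating `gap` missing frames; an event
#' ends when its host cell changes. Each event is assigned to the cell
#' containing its mean centroid.
#'
#' @param movie An [intensity_movie()] (focus channel).
#' @param labels A temporally consistent [label_movie()] of cell masks.
#' @param k_sigma Robust threshold in MAD units.
#' @param min_area_px Minimum component area.
#' @param r_max_px Maximum centroid displacement per frame for linking.
#' @param gap Missing frames tolerated inside one event.
#' @param band_width Cortical band width, px.
#' @return A tibble of focus events: `focus_id`, `cell_id`,
#'   `start_frame`, `end_frame` (0-based), `lifetime_min`, `x_px`,
#'   `y_px`, `peak_intensity`, with the per-frame detections in
#'   `attr(, "detections")`.
#' @export
detect_and_link_foci <- function(movie, labels, k_sigma = 3,
                                 min_area_px = 4, r_max_px = 6,
                                 gap = 1, band_width = 3) {
  stopifnot(all(dim(movie) == dim(labels)))
  nfr <- n_frames(movie)
  dt <- frame_interval(movie)
  det <- vector("list", nfr)
  for (t in seq_len(nfr)) {
    L <- labels[, , t]
    if (all(L == 0)) abort(sprintf("empty cell mask in frame %d", t))
    band <- cortical_band_mask(L, band_width)
    img <- movie[, , t]
    v <- img[band]
    thr <- median(v) + k_sigma * stats::mad(v)
    hot <- band & img > thr
    if (!any(hot)) { det[[t]] <- NULL; next }
    comp <- EBImage::bwlabel(hot)
    comp <- matrix(as.integer(EBImage::imageData(comp)), nrow(img))
    sizes <- tabulate(comp[comp > 0])
    keep <- which(sizes >= min_area_px)
    if (!length(keep)) { det[[t]] <- NULL; next }
    rows <- lapply(keep, function(k) {
      w <- which(comp == k)
      x <- (w - 1) %% nrow(img) + 1
      y <- (w - 1) %/% nrow(img) + 1
      cx <- mean(x); cy <- mean(y)
      host <- L[round(cx), round(cy)]
      if (host == 0) {   # centroid on a ridge: majority label of the blob
        lv <- L[w]; lv <- lv[lv > 0]
        host <- if (length(lv)) as.integer(names(which.max(table(lv)))) else 0L
      }
      tibble::tibble(frame = t - 1L, x_px = cx, y_px = cy,
                     area_px = sizes[k],
                     peak = max(movie[, , t][w]), cell_id = host)
    })
    cur <- dplyr::bind_rows(rows)
    # non-maximum suppression: a focus bleeding over a ridge can light up
    # the neighbouring cell's band; keep only the brightest component
    # within r_max
    if (nrow(cur) > 1) {
      cur <- cur[order(-cur$peak), ]
      keep <- rep(TRUE, nrow(cur))
      for (k in 2:nrow(cur)) {
        d2 <- (cur$x_px[seq_len(k - 1)] - cur$x_px[k])^2 +
          (cur$y_px[seq_len(k - 1)] - cur$y_px[k])^2
        if (any(keep[seq_len(k - 1)] & d2 <= r_max_px^2)) keep[k] <- FALSE
      }
      cur <- cur[keep, ]
    }
    det[[t]] <- cur
  }
  dets <- dplyr::bind_rows(det)
  events <- link_detections(dets, r_max_px, gap, dt)
  attr(events, "detections") <- dets
  events
}

link_detections <- function(dets, r_max_px, gap, dt) {
  empty <- tibble::tibble(focus_id = integer(), cell_id = integer(),
                          start_frame = integer(), end_frame = integer(),
                          lifetime_min = numeric(), x_px = numeric(),
                          y_px = numeric(), peak_intensity = numeric())
  if (is.null(dets) || !nrow(dets)) return(empty)
  open <- list()   # active tracks: list(rows = df, last_frame)
  done <- list()
  for (fr in sort(unique(dets$frame))) {
    cur <- dets[dets$frame == fr, ]
    # close stale tracks
    stale <- vapply(open, function(tr) fr - tr$last > gap + 1L, TRUE)
    done <- c(done, open[stale])
    open <- open[!stale]
    used <- logical(nrow(cur))
    if (length(open)) {
      px <- vapply(open, function(tr) tail(tr$rows$x_px, 1), 0)
      py <- vapply(open, function(tr) tail(tr$rows$y_px, 1), 0)
      dmat <- sqrt(outer(px, cur$x_px, "-")^2 +
                     outer(py, cur$y_px, "-")^2)
      repeat {
        k <- which.min(dmat)
        if (!length(k) || !is.finite(dmat[k]) || dmat[k] > r_max_px) break
        i <- (k - 1) %% length(open) + 1
        j <- (k - 1) %/% length(open) + 1
        if (cur$cell_id[j] == tail(open[[i]]$rows$cell_id, 1)) {
          open[[i]]$rows <- rbind(open[[i]]$rows, cur[j, ])
          open[[i]]$last <- fr
          used[j] <- TRUE
        }
        dmat[i, ] <- Inf; dmat[, j] <- Inf
      }
    }
    for (j in which(!used)) {
      open[[length(open) + 1]] <- list(rows = cur[j, ], last = fr)
    }
  }
  done <- c(done, open)
  if (!length(done)) return(empty)
  rows <- lapply(seq_along(done), function(i) {
    r <- done[[i]]$rows
    tibble::tibble(
      focus_id = i,
      cell_id = as.integer(names(which.max(table(r$cell_id)))),
      start_frame = min(r$frame), end_frame = max(r$frame),
      lifetime_min = (max(r$frame) - min(r$frame) + 1L) * dt / 60,
      x_px = mean(r$x_px), y_px = mean(r$y_px),
      peak_intensity = max(r$peak))
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$start_frame, out$cell_id), ]
}

#' Focus lifetime statistics and condition comparison
#'
#' Lifetimes are `(end - start + 1) * frame_interval / 60` minutes. With a
#' `condition` column (two levels), the summary is computed per condition
#' and a Welch t-test compares them.
#'
#' @param events Focus-event tibble (from [detect_and_link_foci()] or the
#'   generator), optionally with a `condition` column.
#' @return A tibble (`condition`, `n`, `mean_min`, `sem_min`, `sd_min`)
#'   with attribute `test` (the t-test, or `NULL`).
#' @export
focus_stability <- function(events) {
  if (!nrow(events)) abort("no focus events")
  if (!"condition" %in% names(events)) events$condition <- "all"
  out <- events |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_min = mean(.data$lifetime_min),
                     sem_min = sd(.data$lifetime_min) / sqrt(dplyr::n()),
                     sd_min = sd(.data$lifetime_min), .groups = "drop")
  tt <- NULL
  if (length(unique(events$condition)) == 2) {
    tt <- t.test(lifetime_min ~ condition, data = events)
  }
  attr(out, "test") <- tt
  out
}

#' Apico-basal shortening at a focus from an edge-profile movie
#'
#' Samples a line perpendicular to the basal edge (an image column) in
#' every frame, locates the membrane edge as the first suprathreshold
#' crossing (sub-pixel, by linear interpolation) and reports the
#' shortening relative to a pre-event baseline. The measure is flagged
#' unreliable when the edge is undetectable in more than 20% of frames.
#'
#' @param movie An [intensity_movie()] viewing the apico-basal axis.
#' @param column Image column along which to sample (the line through the
#'   focus, perpendicular to the edge).
#' @param start_frame,end_frame Event span, 0-based.
#' @param baseline_frames Pre-onset frames averaged for the baseline.
#' @param halfwidth Columns averaged on each side of `column`.
#' @param threshold_frac Edge threshold as a fraction of the profile's
#'   dynamic range.
#' @return A tibble (`frame`, `edge_um`, `shortening_um`) with attributes
#'   `max_shortening_um`, `baseline_um`, `reliable`.
#' @export
ab_shortening <- function(movie, column, start_frame, end_frame,
                          baseline_frames = 5, halfwidth = 2,
                          threshold_frac = 0.5) {
  ps <- pixel_size(movie)
  nfr <- n_frames(movie)
  cols <- max(1, column - halfwidth):min(dim(movie)[2], column + halfwidth)
  pos <- rep(NA_real_, nfr)
  for (t in seq_len(nfr)) {
    prof <- rowMeans(movie[, cols, t, drop = FALSE])
    thr <- min(prof) + threshold_frac * diff(range(prof))
    above <- which(prof >= thr)
    if (!length(above)) next
    i <- above[1]
    if (i == 1) { pos[t] <- 1 } else {
      pos[t] <- (i - 1) + (thr - prof[i - 1]) / (prof[i] - prof[i - 1])
    }
  }
  reliable <- mean(is.na(pos)) <= 0.2
  if (!reliable) warn("edge undetectable in > 20% of frames")
  base_idx <- max(1L, start_frame + 1L - baseline_frames):
    max(1L, start_frame)
  baseline <- mean(pos[base_idx], na.rm = TRUE)
  short_um <- (baseline - pos) * ps
  ev <- (start_frame:end_frame) + 1L
  out <- tibble::tibble(frame = seq_len(nfr) - 1L, edge_um = pos * ps,
                        shortening_um = short_um)
  structure(out,
            max_shortening_um = max(short_um[ev], na.rm = TRUE),
            baseline_um = baseline * ps,
            reliable = reliable)
}

#' Focus-coupled contraction: host versus neighbour area change
#'
#' For each focus event, the host cell's area change at the intensity peak
#' (event midpoint when no intensity is available) relative to a
#' pre-event baseline, compared with the mean change of its neighbours
#' over the same frames. Events hosted by untracked or ambiguous cells
#' are skipped with a warning.
#'
#' @param events Focus events (`focus_id`, `cell_id`, `start_frame`,
#'   `end_frame`).
#' @param tracks Tidy tracks (`cell_id`, `frame`, `area_um2`, optional
#'   `status`).
#' @param neighbors Neighbour edge list (`frame`, `cell_a`, `cell_b`).
#' @param baseline_frames Pre-onset frames for the baseline mean.
#' @return A tibble (`focus_id`, `cell_id`, `host_dA_um2`,
#'   `neighbor_dA_um2`, `n_neighbors`) with attributes `test` (paired
#'   t-test host vs neighbour) and `n_excluded`.
#' @export
focus_area_coupling <- function(events, tracks, neighbors,
                                baseline_frames = 5) {
  has_status <- "status" %in% names(tracks)
  excluded <- 0L
  rows <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    tr <- tracks[tracks$cell_id == e$cell_id, ]
    tr <- tr[order(tr$frame), ]
    if (!nrow(tr) ||
        (has_status && tr$status[1] != "complete")) {
      excluded <- excluded + 1L
      next
    }
    peak_fr <- round((e$start_frame + e$end_frame) / 2)
    base_fr <- (e$start_frame - baseline_frames):(e$start_frame - 1)
    base_fr <- base_fr[base_fr >= 0]
    if (!length(base_fr) || !peak_fr %in% tr$frame) {
      excluded <- excluded + 1L
      next
    }
    baseA <- mean(tr$area_um2[tr$frame %in% base_fr])
    dA <- tr$area_um2[tr$frame == peak_fr] - baseA
    nb <- neighbors[neighbors$frame == e$start_frame &
                      (neighbors$cell_a == e$cell_id |
                         neighbors$cell_b == e$cell_id), ]
    nb_ids <- setdiff(unique(c(nb$cell_a, nb$cell_b)), e$cell_id)
    if (has_status) {
      ok <- tracks$cell_id %in% nb_ids & tracks$status == "complete"
      nb_ids <- unique(tracks$cell_id[ok])
    }
    nb_dA <- vapply(nb_ids, function(id) {
      trn <- tracks[tracks$cell_id == id, ]
      b <- mean(trn$area_um2[trn$frame %in% base_fr])
      p <- trn$area_um2[trn$frame == peak_fr]
      if (length(p)) p - b else NA_real_
    }, numeric(1))
    rows[[i]] <- tibble::tibble(
      focus_id = e$focus_id, cell_id = e$cell_id, host_dA_um2 = dA,
      neighbor_dA_um2 = mean(nb_dA, na.rm = TRUE),
      n_neighbors = sum(is.finite(nb_dA)))
  }
  if (excluded > 0) {
    warn(sprintf("%d event(s) on untracked/ambiguous cells excluded",
                 excluded))
  }
  out <- dplyr::bind_rows(rows)
  tt <- NULL
  ok <- is.finite(out$host_dA_um2) & is.finite(out$neighbor_dA_um2)
  if (sum(ok) >= 3) {
    tt <- t.test(out$host_dA_um2[ok], out$neighbor_dA_um2[ok],
                 paired = TRUE)
  }
  structure(out, test = tt, n_excluded = excluded)
}
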