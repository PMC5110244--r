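#' Synthetic cortical-intensity channel coupled to area dynamics
#'
#' Generates a per-cell cortical intensity series whose frame-to-frame rate
#' is coupled to the cell's standardized area-change rate with target
#' coupling `rho`:
#' `rate_I = rho * z_area + sqrt(1 - rho^2) * noise * eps`, `eps ~ N(0,1)`.
#' With `noise = 1` the true rate-rate correlation equals `rho`. The
#' intensity itself is the cumulated rate around a positive baseline and is
#' clipped at zero. If a rendered label movie is supplied, the channel is
#' also rendered as an image stack with the intensity concentrated in a
#' cortical edge band, plus photon noise.
#'
#' @param truth A `sheet_truth` manifest (see [build_sheet_truth()]).
#' @param rho Target rate coupling in `[-1, 1]`.
#' @param noise Standard deviation of the unit-variance noise term
#'   (1 preserves `rho` exactly; other values rescale the effective
#'   coupling).
#' @param labels Optional [label_movie()] matching `truth`; when given an
#'   intensity movie is rendered.
#' @param noise_level Photon-noise scale of the rendered movie.
#' @param seed Integer seed.
#' @return A list with `intensity_um` (cells x frames matrix of true mean
#'   intensities, a.u.), `movie` (an [intensity_movie()] or `NULL`), and
#'   `rho`.
#' @export
generate_actin_channel <- function(truth, rho = 0.4, noise = 1,
                                   labels = NULL, noise_level = 0.1,
                                   seed = 1L) {
  stopifnot(inherits(truth, "sheet_truth"))
  if (!is.numeric(rho) || abs(rho) > 1) abort("`rho` must lie in [-1, 1]")
  if (noise < 0) abort("`noise` must be >= 0")
  A <- truth$area_um2
  n <- nrow(A); nfr <- ncol(A)
  if (nfr < 3) abort("need at least 3 frames to couple rates")
  withr::with_seed(as.integer(seed), {
    dA <- t(apply(A, 1, diff))
    z <- t(scale(t(dA)))           # standardize per cell
    z[!is.finite(z)] <- 0
    eps <- matrix(rnorm(n * (nfr - 1)), n)
    g <- rho * z + sqrt(1 - rho^2) * noise * eps
    I <- 150 + 2 * t(apply(cbind(0, g), 1, cumsum))
    I <- pmax(I, 0)
    movie <- NULL
    if (!is.null(labels)) {
      movie <- render_band_intensity(labels, I / 150, noise_level)
    }
    list(intensity_au = I, movie = movie, rho = rho)
  })
}

# Paint per-cell values into a cortical band (3 px inside each cell mask),
# dim interior, blur + photon noise. `values` is cells x frames in ~[0, 2].
render_band_intensity <- function(labels, values, noise_level) {
  side <- dim(labels)[1]
  nfr <- dim(labels)[3]
  n <- nrow(values)
  out <- array(0, dim(labels))
  for (t in seq_len(nfr)) {
    L <- labels[, , t]
    band <- cortical_band_mask(L, width = 3)
    img <- matrix(0.05, side, dim(labels)[2])
    cells <- L > 0
    img[cells] <- 0.2 * values[L[cells], min(t, ncol(values))]
    img[band] <- values[L[band], min(t, ncol(values))]
    img <- as.matrix(EBImage::gblur(img, sigma = 1))
    if (noise_level > 0) {
      peak <- max(4, round(1 / noise_level^2))
      img <- matrix(pmax(rpois(length(img), pmax(img, 0) * peak) / peak +
                           rnorm(length(img), 0, 0.25 * noise_level), 0),
                    side)
    }
    out[, , t] <- img
  }
  intensity_movie(out, pixel_size(labels), frame_interval(labels))
}

# Band of `width` px just inside each cell mask (cells are separated by
# 0-valued ridges, so binary erosion shrinks each cell individually).
cortical_band_mask <- function(lab, width = 3) {
  bin <- lab > 0
  er <- bin
  brush <- EBImage::makeBrush(3, "box")
  for (i in seq_len(width)) er <- EBImage::erode(er, brush) > 0
  bin & !er
}

#' Specification of synthetic cortical focus events
#'
#' Transient cortical intensity condensations ("foci") appear in randomly
#' chosen cells; during an event the host cell's area ratchets down by
#' `contraction_step` and its basal edge indents by `indentation_depth`,
#' neighbours unchanged. Defaults emulate the measured myosin-focus regime:
#' mean lifetime 4 min (a myosin-stabilized condition corresponds to
#' `lifetime_mean = 21.5`), apico-basal indentation of 2.3 um.
#'
#' @param event_rate Expected events per cell per hour (>= 0).
#' @param lifetime_mean Mean event lifetime in minutes (> 0). Lifetimes are
#'   drawn from a truncated normal (sd = 25% of mean, floor 2 frames).
#' @param contraction_step Area lost by the host cell per event, um^2.
#' @param indentation_depth Basal-edge indentation per event, um (>= 0).
#' @param intensity_gain Peak focus intensity above background, a.u.
#' @param seed Integer seed.
#' @return A list of class `foci_spec`.
#' @export
foci_spec <- function(event_rate = 2, lifetime_mean = 4,
                      contraction_step = 3, indentation_depth = 2.3,
                      intensity_gain = 1, seed = 1L) {
  if (event_rate < 0) abort("`event_rate` must be >= 0")
  check_positive(lifetime_mean, "lifetime_mean")
  if (indentation_depth < 0) abort("`indentation_depth` must be >= 0")
  structure(list(event_rate = event_rate, lifetime_mean = lifetime_mean,
                 contraction_step = contraction_step,
                 indentation_depth = indentation_depth,
                 intensity_gain = intensity_gain, seed = as.integer(seed)),
            class = "foci_spec")
}

#' Synthetic focus-event channel
#'
#' Draws focus events (Poisson count per cell, uniform onsets,
#' truncated-normal lifetimes), updates the ground-truth area series so the
#' host cell ratchets down by `contraction_step` across each event
#' (neighbours untouched), and — when a label movie is supplied — renders
#' the foci as Gaussian intensity blobs on the host cell's cortex with a
#' raised-cosine temporal profile.
#'
#' @param truth A `sheet_truth` manifest.
#' @param spec A [foci_spec()].
#' @param labels Optional [label_movie()] for rendering.
#' @param noise_level Photon-noise scale of the rendered movie.
#' @return A list with `events` (tibble: `focus_id`, `cell_id`,
#'   `start_frame`, `end_frame` 0-based, `lifetime_min`, `x_px`, `y_px`),
#'   `truth` (updated manifest), and `movie` (or `NULL`).
#' @export
generate_foci_channel <- function(truth, spec = foci_spec(), labels = NULL,
                                  noise_level = 0.1) {
  stopifnot(inherits(truth, "sheet_truth"), inherits(spec, "foci_spec"))
  sp <- truth$spec
  dt <- sp$frame_interval
  nfr <- sp$n_frames
  n <- sp$n_cells
  dur_h <- (nfr * dt) / 3600
  withr::with_seed(spec$seed + 7919L, {
    ev <- list()
    for (cell in seq_len(n)) {
      k <- rpois(1, spec$event_rate * dur_h)
      if (k == 0) next
      taken <- rep(FALSE, nfr)
      for (j in seq_len(k)) {
        life_min <- max(rnorm(1, spec$lifetime_mean,
                              0.25 * spec$lifetime_mean),
                        2 * dt / 60)
        len <- max(2L, round(life_min * 60 / dt))
        if (len >= nfr) next       # event would not fit the movie
        o <- sample.int(nfr - len + 1L, 1)
        end <- o + len - 1L
        if (any(taken[o:end])) next   # no overlapping events in one cell
        taken[o:end] <- TRUE
        ev[[length(ev) + 1L]] <- list(cell_id = cell, start = o, end = end)
      }
    }
    A <- truth$area_um2
    events <- tibble::tibble(focus_id = integer(), cell_id = integer(),
                             start_frame = integer(), end_frame = integer(),
                             lifetime_min = numeric(),
                             x_px = numeric(), y_px = numeric())
    if (length(ev)) {
      for (i in seq_along(ev)) {
        e <- ev[[i]]
        len <- e$end - e$start + 1L
        # the contraction completes by mid-event and holds (ratchet), so
        # the area deficit at the intensity peak equals the full step
        ramp <- pmin(seq(0, 2, length.out = len), 1)
        idx <- e$start:e$end
        A[e$cell_id, idx] <- A[e$cell_id, idx] - spec$contraction_step * ramp
        if (e$end < nfr) {       # ratcheted: the step persists
          A[e$cell_id, (e$end + 1L):nfr] <-
            A[e$cell_id, (e$end + 1L):nfr] - spec$contraction_step
        }
        pos <- focus_position(truth, labels, e$cell_id, e$start)
        events <- dplyr::bind_rows(events, tibble::tibble(
          focus_id = i, cell_id = e$cell_id,
          start_frame = e$start - 1L, end_frame = e$end - 1L,
          lifetime_min = len * dt / 60,
          x_px = pos[1], y_px = pos[2]))
      }
      A <- pmax(A, 1)
    }
    truth$area_um2 <- A
    truth$focus_events <- events
    movie <- NULL
    if (!is.null(labels)) {
      movie <- render_foci_movie(labels, events, spec, noise_level)
    }
    list(events = events, truth = truth, movie = movie)
  })
}

# A cortical point of the host cell: a random band pixel if labels are
# available, else a point offset from the seed.
focus_position <- function(truth, labels, cell, frame) {
  if (!is.null(labels)) {
    L <- labels[, , min(frame, dim(labels)[3])]
    band <- cortical_band_mask(L, 2) & (L == cell)
    w <- which(band)
    if (length(w)) {
      k <- w[sample.int(length(w), 1)]
      return(c((k - 1) %% nrow(L) + 1, (k - 1) %/% nrow(L) + 1))
    }
  }
  r <- sqrt(truth$cells$base_area_um2[cell] / pi) / truth$spec$pixel_size
  th <- runif(1, 0, 2 * pi)
  c(truth$cells$seed_x[cell] + 0.8 * r * cos(th),
    truth$cells$seed_y[cell] + 0.8 * r * sin(th))
}

render_foci_movie <- function(labels, events, spec, noise_level) {
  d <- dim(labels)
  out <- array(0.05, d)
  sigma <- 1.5
  half <- 5L
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    frames <- (e$start_frame:e$end_frame) + 1L
    len <- length(frames)
    # trapezoid: condensation and dispersal take about one frame each,
    # with a bright plateau in between, so the visible span tracks the
    # true lifetime to within a frame
    prof <- rep(1, len)
    prof[1] <- 0.7
    prof[len] <- 0.7
    x0 <- round(e$x_px); y0 <- round(e$y_px)
    xs <- max(1, x0 - half):min(d[1], x0 + half)
    ys <- max(1, y0 - half):min(d[2], y0 + half)
    blob <- exp(-(outer((xs - e$x_px)^2, (ys - e$y_px)^2, "+")) /
                  (2 * sigma^2))
    for (k in seq_len(len)) {
      out[xs, ys, frames[k]] <- out[xs, ys, frames[k]] +
        spec$intensity_gain * prof[k] * blob
    }
  }
  if (noise_level > 0) {
    withr::with_seed(spec$seed + 15013L, {
      peak <- max(4, round(1 / noise_level^2))
      out <- array(pmax(rpois(length(out), out * peak) / peak +
                          rnorm(length(out), 0, 0.25 * noise_level), 0), d)
    })
  }
  intensity_movie(out, pixel_size(labels), frame_interval(labels))
}

#' Synthetic apico-basal edge-profile movie
#'
#' Renders a bright, roughly horizontal membrane edge whose position
#' indents transiently (raised-cosine time course) by `indentation_depth`
#' during a focus event, emulating a kymograph-style view of the basal
#' surface along the apico-basal axis. Used to validate edge-indentation
#' recovery.
#'
#' @param spec A [foci_spec()] (uses `indentation_depth`, `lifetime_mean`,
#'   `seed`).
#' @param n_frames,frame_interval,pixel_size Movie geometry/calibration.
#' @param onset_frame First frame of the event (1-based).
#' @param width_px,height_px Frame size.
#' @param noise_level Photon-noise scale.
#' @return A list with `movie`, `edge_row_px` (true edge row per frame),
#'   `event` (tibble with `start_frame`, `end_frame`, 0-based).
#' @export
generate_edge_movie <- function(spec = foci_spec(), n_frames = 60,
                                frame_interval = 10, pixel_size = 0.3,
                                onset_frame = 15, width_px = 40,
                                height_px = 60, noise_level = 0.05) {
  stopifnot(inherits(spec, "foci_spec"))
  len <- max(2L, round(spec$lifetime_mean * 60 / frame_interval))
  end <- min(onset_frame + len - 1L, n_frames)
  prof <- rep(0, n_frames)
  prof[onset_frame:end] <-
    0.5 * (1 - cos(2 * pi * seq(0, 1,
                                length.out = end - onset_frame + 1L)))
  y0 <- 0.7 * height_px
  rows <- y0 - (spec$indentation_depth / pixel_size) * prof
  out <- array(0, c(height_px, width_px, n_frames))
  withr::with_seed(spec$seed + 27011L, {
    for (t in seq_len(n_frames)) {
      img <- matrix(0.1, height_px, width_px)
      # 1-px edge with sub-pixel position split across two rows
      r <- rows[t]
      r0 <- floor(r); fr <- r - r0
      img[r0, ] <- img[r0, ] + (1 - fr)
      img[r0 + 1, ] <- img[r0 + 1, ] + fr
      img <- as.matrix(EBImage::gblur(img, sigma = 1.2))
      if (noise_level > 0) {
        peak <- max(4, round(1 / noise_level^2))
        img <- matrix(pmax(rpois(length(img), img * peak) / peak +
                             rnorm(length(img), 0, 0.25 * noise_level), 0),
                      height_px)
      }
      out[, , t] <- img
    }
  })
  list(movie = intensity_movie(out, pixel_size, frame_interval),
       edge_row_px = rows,
       event = tibble::tibble(start_frame = onset_frame - 1L,
                              end_frame = end - 1L))
}
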