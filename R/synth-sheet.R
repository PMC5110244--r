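#' Specification of a synthetic oscillating cell sheet
#'
#' Defines the statistical regime of a ground-truthed synthetic epithelium:
#' a packed polygonal sheet whose per-cell areas oscillate asynchronously
#' around a slowly declining ("ratcheted") mean. Defaults emulate the basal
#' surface of the folding zebrafish retinal neuroepithelium between 19 and
#' 21 hpf: a mean-area decline from 25.4 to 15.3 um^2 across the movie,
#' oscillation at 50 mHz with a rate amplitude near 11 um^2/min, frames
#' every 5 s for 25 min.
#'
#' @param n_cells Number of cells (>= 4).
#' @param mean_area Mean cell area in um^2. Defaults to the midpoint of the
#'   ratchet window; used directly when the ratchet endpoints are equal.
#' @param osc_amplitude Oscillation amplitude as a fraction of cell area.
#'   The default 0.023 yields a measured peak-to-peak area-rate amplitude
#'   of about 11 um^2/min at 50 mHz for a 20 um^2 cell sampled every 5 s
#'   (finite differencing at 4 samples per cycle attenuates the true
#'   derivative by sin(w dt)/(w dt) ~ 0.64, as in the reference imaging
#'   regime).
#' @param osc_freq Oscillation frequency in mHz.
#' @param phase_mode `"independent"` (each cell gets an independent uniform
#'   phase) or `"shared"` (all cells in phase).
#' @param ratchet_from,ratchet_to Mean cell area (um^2) at the first and
#'   last frame; the decline is linear in time. `ratchet_from >= ratchet_to
#'   >= 0` is required.
#' @param frame_interval Seconds between frames.
#' @param n_frames Number of frames.
#' @param pixel_size Micrometres per pixel.
#' @param noise_level Relative photon-noise scale of the rendered membrane
#'   channel (standard deviation at peak membrane intensity); 0 disables
#'   noise.
#' @param area_cv Coefficient of variation of per-cell base areas.
#' @param psf_sigma Gaussian point-spread sigma of the rendered membrane
#'   channel, px (0.8 px ~ a confocal lateral PSF at 0.3 um/px).
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return A list of class `sheet_spec`.
#' @seealso [generate_sheet_movie()]
#' @export
sheet_spec <- function(n_cells = 100,
                       mean_area = NULL,
                       osc_amplitude = 0.023,
                       osc_freq = 50,
                       phase_mode = c("independent", "shared"),
                       ratchet_from = 25.4,
                       ratchet_to = 15.3,
                       frame_interval = 5,
                       n_frames = 300,
                       pixel_size = 0.3,
                       noise_level = 0.1,
                       area_cv = 0.07,
                       psf_sigma = 0.8,
                       seed = 1L) {
  phase_mode <- match.arg(phase_mode)
  if (n_cells < 4) abort("`n_cells` must be >= 4")
  check_positive(frame_interval, "frame_interval")
  check_positive(pixel_size, "pixel_size")
  if (n_frames < 1) abort("`n_frames` must be >= 1")
  if (!is.numeric(ratchet_from) || !is.numeric(ratchet_to) ||
      ratchet_from < ratchet_to || ratchet_to < 0) {
    abort("require `ratchet_from` >= `ratchet_to` >= 0")
  }
  if (osc_amplitude < 0 || osc_freq < 0) {
    abort("`osc_amplitude` and `osc_freq` must be non-negative")
  }
  if (noise_level < 0) abort("`noise_level` must be >= 0")
  if (is.null(mean_area)) mean_area <- (ratchet_from + ratchet_to) / 2
  check_positive(mean_area, "mean_area")
  structure(list(n_cells = as.integer(n_cells), mean_area = mean_area,
                 osc_amplitude = osc_amplitude, osc_freq = osc_freq,
                 phase_mode = phase_mode, ratchet_from = ratchet_from,
                 ratchet_to = ratchet_to, frame_interval = frame_interval,
                 n_frames = as.integer(n_frames), pixel_size = pixel_size,
                 noise_level = noise_level, area_cv = area_cv,
                 psf_sigma = psf_sigma, seed = as.integer(seed)),
            class = "sheet_spec")
}

#' Build the ground-truth record of a synthetic sheet
#'
#' Lays out the cells (Lloyd-relaxed random seed points in a disk) and
#' evaluates the true per-cell area series
#' `A_i(t) = B_i * rho(t) * (1 + a * sin(2 pi f t + phi_i))`,
#' where `rho(t)` interpolates the ratchet window linearly and `B_i` are
#' per-cell base areas with mean `ratchet_from`. No pixels are rendered;
#' use [render_sheet_movie()] for that.
#'
#' @param spec A [sheet_spec()].
#' @return A list of class `sheet_truth` with elements `cells` (tibble:
#'   `cell_id`, seed coordinates in px, base area, phase, frequency),
#'   `area_um2` (matrix cells x frames of true areas), `time_s`, the frame
#'   geometry, and an echo of `spec`.
#' @export
build_sheet_truth <- function(spec) {
  stopifnot(inherits(spec, "sheet_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_cells
    ps <- spec$pixel_size
    total0 <- n * spec$ratchet_from
    r0_px <- sqrt(total0 / pi) / ps
    side <- ceiling(2 * r0_px * 1.28)
    cx <- (side + 1) / 2
    cy <- (side + 1) / 2

    # seed points in the tissue disk, Lloyd-relaxed for even packing
    th <- runif(n, 0, 2 * pi)
    rr <- r0_px * 0.97 * sqrt(runif(n))
    sx <- cx + rr * cos(th)
    sy <- cy + rr * sin(th)
    gx <- rep(seq_len(side), times = side)
    gy <- rep(seq_len(side), each = side)
    inside <- (gx - cx)^2 + (gy - cy)^2 <= r0_px^2
    gxi <- gx[inside]; gyi <- gy[inside]
    for (i in seq_len(6)) {
      lab <- max.col(-(outer(gxi, sx, "-")^2 + outer(gyi, sy, "-")^2),
                     ties.method = "first")
      sx <- as.numeric(tapply(gxi, factor(lab, seq_len(n)), mean))
      sy <- as.numeric(tapply(gyi, factor(lab, seq_len(n)), mean))
      miss <- !is.finite(sx)
      if (any(miss)) { # re-seed any starved site
        sx[miss] <- cx + r0_px * 0.5 * cos(runif(sum(miss), 0, 2 * pi))
        sy[miss] <- cy + r0_px * 0.5 * sin(runif(sum(miss), 0, 2 * pi))
      }
    }

    base <- spec$ratchet_from * pmax(rnorm(n, 1, spec$area_cv), 0.4)
    base <- base * spec$ratchet_from / mean(base)
    phi <- switch(spec$phase_mode,
                  independent = runif(n, 0, 2 * pi),
                  shared = rep(runif(1, 0, 2 * pi), n))
    tt <- (seq_len(spec$n_frames) - 1) * spec$frame_interval
    rho <- if (spec$n_frames == 1) 1 else {
      (spec$ratchet_from + (spec$ratchet_to - spec$ratchet_from) *
         tt / tt[length(tt)]) / spec$ratchet_from
    }
    f_hz <- spec$osc_freq / 1000
    osc <- 1 + spec$osc_amplitude *
      sin(outer(phi, 2 * pi * f_hz * tt, "+"))
    area <- base * osc * rep(rho, each = n)

    cells <- tibble::tibble(cell_id = seq_len(n), seed_x = sx, seed_y = sy,
                            base_area_um2 = base, phase = phi,
                            freq_mHz = spec$osc_freq)
    structure(list(cells = cells, area_um2 = area, time_s = tt,
                   side_px = side, centre_px = c(cx, cy), r0_px = r0_px,
                   spec = spec),
              class = "sheet_truth")
  })
}

#' Per-cell ground-truth area series as a tidy table
#'
#' @param truth A `sheet_truth` object.
#' @return A tibble with `cell_id`, `frame` (0-based), `time_s`,
#'   `area_um2`.
#' @export
truth_tracks <- function(truth) {
  stopifnot(inherits(truth, "sheet_truth"))
  nfr <- ncol(truth$area_um2)
  tibble::tibble(
    cell_id = rep(truth$cells$cell_id, times = nfr),
    frame = rep(seq_len(nfr) - 1L, each = nrow(truth$area_um2)),
    time_s = rep(truth$time_s, each = nrow(truth$area_um2)),
    area_um2 = as.vector(truth$area_um2)
  )
}

# ---- power-diagram rendering -------------------------------------------

# Squared pixel-site distances, computed once per frame.
pd_dist2 <- function(gx, gy, sx, sy) {
  outer(gx, sx, "-")^2 + outer(gy, sy, "-")^2
}

# Assign each candidate pixel to a weighted site (or background beyond
# `tau`). A running-minimum loop over the (few) sites avoids the large
# temporaries of a whole-matrix argmin. Returns the dense label matrix.
pd_assign <- function(D2, w, tau, side, idx) {
  P <- nrow(D2)
  bestv <- w[1] - D2[, 1]
  best <- rep(1L, P)
  for (i in 2:ncol(D2)) {
    v <- w[i] - D2[, i]
    upd <- v > bestv
    if (any(upd)) {
      bestv[upd] <- v[upd]
      best[upd] <- i
    }
  }
  best[bestv < -tau] <- 0L
  M <- matrix(0L, side, side)
  M[idx] <- best
  M
}

# Membrane convention: every positive pixel flanking a label change (on
# either side, including the tissue rim) is membrane and set to 0. The
# same pixels are rendered bright in the membrane channel, so generated
# truth areas and intensity-thresholded segmentation areas share one
# definition of "cell area" (membrane-excluded interior).
ridge_zero <- function(lab) {
  out <- lab
  out[membrane_mask(lab)] <- 0L
  out
}

# Closed membrane outline (both sides of every boundary) for rendering.
membrane_mask <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  m <- matrix(FALSE, nr, nc)
  d1 <- lab[-nr, ] != lab[-1, ]
  d2 <- lab[, -nc] != lab[, -1]
  m[-nr, ] <- m[-nr, ] | d1
  m[-1, ] <- m[-1, ] | d1
  m[, -nc] <- m[, -nc] | d2
  m[, -1] <- m[, -1] | d2
  m & (lab > 0)
}

# Count ridge-excluded pixels per cell.
pd_areas <- function(lab_z, n) tabulate(lab_z[lab_z > 0], n)

# Cell-cell shared boundary counts and cell-background boundary counts.
pd_adjacency <- function(lab, n) {
  nr <- nrow(lab); nc <- ncol(lab)
  a <- c(lab[-nr, ], lab[, -nc])
  b <- c(lab[-1, ], lab[, -1])
  sel <- a != b & a > 0 & b > 0
  i <- pmin(a[sel], b[sel]); j <- pmax(a[sel], b[sel])
  cnt <- tabulate((i - 1L) * n + j, n * n)
  A <- matrix(cnt, n, n, byrow = TRUE)
  A <- A + t(A)
  selbg <- (a == 0) != (b == 0)
  cellbg <- pmax(a[selbg], b[selbg])
  list(cc = A, bg = tabulate(cellbg, n))
}

# Newton solve of site weights so that ridge-excluded pixel counts match
# `target`. The Jacobian of areas wrt weights is a boundary-length-weighted
# graph Laplacian plus a diagonal background term.
pd_solve_weights <- function(gx, gy, sx, sy, w, tau, side, target, idx,
                             tol = 3, maxit = 14, step0 = 0.9) {
  n <- length(sx)
  D2 <- pd_dist2(gx, gy, sx, sy)
  dmat <- as.matrix(dist(cbind(sx, sy)))
  best <- NULL; best_err <- Inf
  for (it in seq_len(maxit)) {
    lab <- pd_assign(D2, w, tau, side, idx)
    labz <- ridge_zero(lab)
    cur <- pd_areas(labz, n)
    err <- target - cur
    m <- max(abs(err))
    if (m < best_err) { best_err <- m; best <- list(lab = lab, w = w) }
    if (m <= tol) break
    adj <- pd_adjacency(lab, n)
    Wt <- adj$cc / (2 * pmax(dmat, 1e-6)); diag(Wt) <- 0
    L <- diag(rowSums(Wt) + adj$bg / (2 * sqrt(pmax(tau + w, 1)))) - Wt
    dw <- tryCatch(solve(L + diag(1e-6, n), err),
                   error = function(e) err * 0.3)
    w <- w + (if (it < 5) step0 else 0.5 * step0) * dw
  }
  best
}

#' Render a synthetic sheet into membrane and label movies
#'
#' Cells are drawn as an additively weighted power diagram around the truth
#' seed points; site weights are solved per frame (Newton iteration on a
#' boundary-length Laplacian) so that each cell's rendered, membrane-
#' excluded pixel count matches its true area to within a few pixels. The
#' tissue-scale ratchet is realised by scaling seed positions towards the
#' tissue centre. The membrane channel renders the cell outlines with a
#' Gaussian point-spread blur plus Poisson photon noise and Gaussian read
#' noise.
#'
#' @param truth A `sheet_truth` from [build_sheet_truth()].
#' @param noise_level Overrides the spec's photon-noise scale if given.
#' @return A list with `membrane` (an [intensity_movie()]), `labels` (a
#'   [label_movie()] with temporally consistent cell IDs and 0 on membrane
#'   ridges/background).
#' @export
render_sheet_movie <- function(truth, noise_level = NULL) {
  stopifnot(inherits(truth, "sheet_truth"))
  spec <- truth$spec
  if (is.null(noise_level)) noise_level <- spec$noise_level
  n <- spec$n_cells; ps <- spec$pixel_size
  side <- truth$side_px
  cx <- truth$centre_px[1]; cy <- truth$centre_px[2]
  gx_all <- rep(seq_len(side), times = side)
  gy_all <- rep(seq_len(side), each = side)
  # candidate pixels: a disk with room for the rim cells
  rc0 <- sqrt(truth$area_um2[1, 1] / pi) / ps
  keep <- (gx_all - cx)^2 + (gy_all - cy)^2 <=
    (truth$r0_px + 3 * rc0)^2
  gx <- gx_all[keep]; gy <- gy_all[keep]
  idx <- which(keep)
  sx0 <- truth$cells$seed_x; sy0 <- truth$cells$seed_y
  nfr <- spec$n_frames
  labs <- array(0L, c(side, side, nfr))
  mem <- array(0, c(side, side, nfr))
  mean0 <- mean(truth$area_um2[, 1])
  w <- rep(0, n)
  withr::with_seed(spec$seed + 104729L, {
    for (t in seq_len(nfr)) {
      at <- truth$area_um2[, t]
      lambda <- sqrt(mean(at) / mean0)
      sx <- cx + lambda * (sx0 - cx)
      sy <- cy + lambda * (sy0 - cy)
      rc <- sqrt(mean(at) / pi) / ps
      tau <- (1.6 * rc)^2
      target <- at / ps^2
      sol <- pd_solve_weights(gx, gy, sx, sy, w, tau, side, target, idx,
                              maxit = if (t == 1) 18 else 10)
      w <- sol$w
      labz <- ridge_zero(sol$lab)
      labs[, , t] <- labz
      clean <- 0.12 + 0.88 * membrane_mask(sol$lab)
      clean <- as.matrix(EBImage::gblur(clean, sigma = spec$psf_sigma))
      if (noise_level > 0) {
        peak <- max(4, round(1 / noise_level^2))
        img <- rpois(length(clean), clean * peak) / peak +
          rnorm(length(clean), 0, 0.25 * noise_level)
        clean <- matrix(pmax(img, 0), side, side)
      }
      mem[, , t] <- clean
    }
  })
  list(membrane = intensity_movie(mem, ps, spec$frame_interval),
       labels = label_movie(labs, ps, spec$frame_interval))
}

#' Generate a ground-truthed synthetic sheet movie
#'
#' Convenience wrapper: [build_sheet_truth()] followed by
#' [render_sheet_movie()].
#'
#' @param spec A [sheet_spec()].
#' @return A list with `membrane`, `labels` (movies) and `truth`
#'   (the `sheet_truth` manifest).
#' @examples
#' sp <- sheet_spec(n_cells = 9, n_frames = 3, noise_level = 0, seed = 7)
#' mv <- generate_sheet_movie(sp)
#' dim(mv$membrane)
#' @export
generate_sheet_movie <- function(spec) {
  truth <- build_sheet_truth(spec)
  out <- render_sheet_movie(truth)
  out$truth <- truth
  out
}

#' Write a ground-truth manifest as JSON
#'
#' @param truth A `sheet_truth`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "sheet_truth"))
  obj <- list(spec = unclass(truth$spec),
              cells = truth$cells,
              time_s = truth$time_s,
              area_um2 = truth$area_um2)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Interior cells of a synthetic sheet
#'
#' Cells whose seed lies at least `margin` typical cell radii inside the
#' tissue rim. Rim cells have a free outer boundary and are measured less
#' accurately by any segmentation, so recovery criteria are stated for
#' interior cells.
#'
#' @param truth A `sheet_truth`.
#' @param margin Margin in units of the mean cell radius.
#' @return Integer vector of cell IDs.
#' @export
interior_cells <- function(truth, margin = 1.2) {
  stopifnot(inherits(truth, "sheet_truth"))
  rc <- sqrt(mean(truth$area_um2[, 1]) / pi) / truth$spec$pixel_size
  d <- sqrt((truth$cells$seed_x - truth$centre_px[1])^2 +
              (truth$cells$seed_y - truth$centre_px[2])^2)
  truth$cells$cell_id[d < truth$r0_px - margin * rc]
}
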