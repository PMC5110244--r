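#' Shi-Tomasi corner features
#'
#' Ranks pixels by the smaller eigenvalue of the locally averaged
#' structure tensor ("good features to track") and returns the strongest
#' corners subject to a quality threshold and a minimum mutual distance.
#'
#' @param img Numeric matrix.
#' @param n Number of features requested.
#' @param quality Quality level: features must score at least
#'   `quality * max(score)`.
#' @param min_dist Minimum distance between features, px.
#' @param mask Optional logical matrix restricting the search.
#' @param block Half-width of the tensor-averaging window, px.
#' @return A matrix with columns `x` (row coord) and `y` (col coord).
#' @export
good_features <- function(img, n = 11, quality = 0.01, min_dist = 10,
                          mask = NULL, block = 2) {
  img <- as.matrix(img)
  gr <- image_gradients(img)
  box <- matrix(1, 2 * block + 1, 2 * block + 1)
  box <- box / sum(box)
  sxx <- as.matrix(EBImage::filter2(gr$gx * gr$gx, box))
  syy <- as.matrix(EBImage::filter2(gr$gy * gr$gy, box))
  sxy <- as.matrix(EBImage::filter2(gr$gx * gr$gy, box))
  tr <- sxx + syy
  dd <- sqrt(pmax((sxx - syy)^2 + 4 * sxy^2, 0))
  lmin <- (tr - dd) / 2
  if (!is.null(mask)) lmin[!mask] <- -Inf
  # keep clear of the border, where tracking windows would clip
  b <- 4L
  lmin[c(seq_len(b), nrow(lmin) - seq_len(b) + 1L), ] <- -Inf
  lmin[, c(seq_len(b), ncol(lmin) - seq_len(b) + 1L)] <- -Inf
  thr <- quality * max(lmin)
  ord <- order(lmin, decreasing = TRUE)
  pts <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  for (k in ord) {
    if (lmin[k] < thr || nrow(pts) >= n) break
    x <- (k - 1) %% nrow(img) + 1
    y <- (k - 1) %/% nrow(img) + 1
    if (nrow(pts) == 0 ||
        min((pts[, 1] - x)^2 + (pts[, 2] - y)^2) >= min_dist^2) {
      pts <- rbind(pts, c(x, y))
    }
  }
  pts
}

image_gradients <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- img; gy <- img
  gx[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
  gx[1, ] <- img[2, ] - img[1, ]; gx[nr, ] <- img[nr, ] - img[nr - 1, ]
  gy[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
  gy[, 1] <- img[, 2] - img[, 1]; gy[, nc] <- img[, nc] - img[, nc - 1]
  list(gx = gx, gy = gy)
}

pyr_down <- function(img) {
  sm <- as.matrix(EBImage::gblur(img, sigma = 1))
  sm[seq(1, nrow(sm), by = 2), seq(1, ncol(sm), by = 2)]
}

# Iterative Lucas-Kanade step for one pyramid level: refine displacement
# (dx, dy) of points `p` from img1 to img2.
lk_level <- function(img1, img2, p, disp, win = 21, iters = 10) {
  half <- win %/% 2
  off <- as.vector(outer(-half:half, rep(1, win)))
  offx <- rep(-half:half, times = win)
  offy <- rep(-half:half, each = win)
  gr <- image_gradients(img1)
  for (i in seq_len(nrow(p))) {
    x0 <- p[i, 1] + offx
    y0 <- p[i, 2] + offy
    ix <- bilinear_sample(gr$gx, x0, y0)
    iy <- bilinear_sample(gr$gy, x0, y0)
    t1 <- bilinear_sample(img1, x0, y0)
    A11 <- sum(ix * ix); A22 <- sum(iy * iy); A12 <- sum(ix * iy)
    detA <- A11 * A22 - A12^2
    if (detA < 1e-10) next
    d <- disp[i, ]
    for (it in seq_len(iters)) {
      t2 <- bilinear_sample(img2, x0 + d[1], y0 + d[2])
      dt <- t2 - t1
      b1 <- -sum(dt * ix); b2 <- -sum(dt * iy)
      step <- c(A22 * b1 - A12 * b2, A11 * b2 - A12 * b1) / detA
      d <- d + step
      if (sum(step^2) < 1e-8) break
    }
    disp[i, ] <- d
  }
  disp
}

#' Pyramidal Lucas-Kanade tracking of sparse points
#'
#' Tracks points from each frame to the next with the iterative
#' Lucas-Kanade method on a Gaussian image pyramid.
#'
#' @param movie An [intensity_movie()].
#' @param points Matrix of starting positions (columns x, y in px).
#' @param win Tracking window size, px (odd).
#' @param levels Pyramid levels.
#' @param iters Newton iterations per level.
#' @return An array `[n_points, 2, n_frames]` of positions.
#' @export
lk_track <- function(movie, points, win = 21, levels = 3, iters = 10) {
  nfr <- n_frames(movie)
  np <- nrow(points)
  out <- array(NA_real_, c(np, 2, nfr))
  out[, , 1] <- as.matrix(points)
  for (t in 2:nfr) {
    i1 <- movie[, , t - 1]
    i2 <- movie[, , t]
    pyr1 <- list(i1); pyr2 <- list(i2)
    for (l in seq_len(levels - 1)) {
      pyr1[[l + 1]] <- pyr_down(pyr1[[l]])
      pyr2[[l + 1]] <- pyr_down(pyr2[[l]])
    }
    p <- out[, , t - 1, drop = TRUE]
    if (np == 1) p <- matrix(p, 1)
    disp <- matrix(0, np, 2)
    for (l in rev(seq_len(levels))) {
      scale <- 2^(l - 1)
      disp <- lk_level(pyr1[[l]], pyr2[[l]],
                       (p - 1) / scale + 1, disp / scale,
                       win = win, iters = iters) * scale
    }
    out[, , t] <- p + disp
  }
  out
}

#' Post-ablation retraction-speed profile of a region
#'
#' Selects corner features inside the region at the cut frame, tracks them
#' with pyramidal Lucas-Kanade, takes the per-frame median speed over the
#' points (`|displacement| * pixel_size / dt`), Gaussian-smooths the
#' post-cut segment, and normalizes the profile by its median. The
#' pre-cut segment is excluded from the smoothing kernel so the recoil
#' peak is not averaged with still frames.
#'
#' @param movie An [intensity_movie()] (frame interval ~0.5 s).
#' @param region Region of interest: a logical matrix mask, or a polygon
#'   as a two-column matrix of (x, y) vertices in px.
#' @param cut_frame Last pre-cut frame (1-based).
#' @param n_points Features to track (11 by default); fewer than 5 usable
#'   features is an error.
#' @param stage_angle Optional opening-angle metadata, degrees.
#' @param region_label Optional label (e.g. `"central"`, `"distal"`).
#' @param sigma_frames Gaussian smoothing sigma, frames.
#' @param win,levels Lucas-Kanade parameters.
#' @param quality,min_dist Feature-selection parameters.
#' @return An object of class `retraction_profile`: tibble (`frame`,
#'   `time_s`, `speed_um_s`, `speed_smooth_um_s`, `speed_norm`) with
#'   attributes `max_speed_um_s` (max of the smoothed post-cut profile),
#'   `stage_angle`, `region_label`, `n_points`, `normalized` (FALSE with
#'   a zero median, in which case `speed_norm` is left `NA`).
#' @export
track_retraction <- function(movie, region, cut_frame, n_points = 11,
                             stage_angle = NA_real_,
                             region_label = NA_character_,
                             sigma_frames = 2, win = 21, levels = 3,
                             quality = 0.01, min_dist = 10) {
  nfr <- n_frames(movie)
  if (cut_frame >= nfr) abort("`cut_frame` must be < number of frames")
  mask <- region_mask(region, dim(movie)[1:2])
  pts <- good_features(movie[, , cut_frame], n = n_points,
                       quality = quality, min_dist = min_dist,
                       mask = mask)
  if (nrow(pts) < n_points && nrow(pts) >= 5) {
    warn(sprintf("only %d features found (requested %d)", nrow(pts),
                 n_points))
  }
  if (nrow(pts) < 5) abort("fewer than 5 trackable features in region")
  # track through the whole movie: the measured pre-cut speeds give the
  # jitter floor against which a response is judged
  pos <- lk_track(movie, pts, win = win, levels = levels)
  dt <- frame_interval(movie)
  ps <- pixel_size(movie)
  speed <- c(0, vapply(2:nfr, function(t) {
    dx <- pos[, 1, t] - pos[, 1, t - 1]
    dy <- pos[, 2, t] - pos[, 2, t - 1]
    median(sqrt(dx^2 + dy^2))
  }, numeric(1)) * ps / dt)
  # smooth pre- and post-cut segments separately so the recoil peak is
  # not averaged with still frames
  pre <- speed[seq_len(cut_frame)]
  post <- speed[(cut_frame + 1):nfr]
  smooth <- c(gauss_smooth(pre, sigma_frames),
              gauss_smooth(post, sigma_frames))
  med <- median(smooth)
  normalized <- med > 1e-12
  if (!normalized) {
    warn("profile median is zero: normalization skipped")
  }
  out <- tibble::tibble(
    frame = seq_len(nfr) - 1L,
    time_s = (seq_len(nfr) - 1L) * dt,
    speed_um_s = speed,
    speed_smooth_um_s = smooth,
    speed_norm = if (normalized) smooth / med else NA_real_)
  structure(out,
            max_speed_um_s = max(smooth[(cut_frame + 1):nfr]),
            noise_floor_um_s = max(mean(pre[-1]) + 2 * sd(pre[-1]), 1e-3),
            stage_angle = stage_angle, region_label = region_label,
            n_points = nrow(pts), normalized = normalized,
            cut_frame = cut_frame,
            class = c("retraction_profile", class(out)))
}

region_mask <- function(region, dims) {
  if (is.logical(region)) {
    stopifnot(all(dim(region) == dims))
    return(region)
  }
  region <- as.matrix(region)
  stopifnot(ncol(region) == 2, nrow(region) >= 3)
  gx <- rep(seq_len(dims[1]), times = dims[2])
  gy <- rep(seq_len(dims[2]), each = dims[1])
  matrix(point_in_polygon(gx, gy, region[, 1], region[, 2]),
         dims[1], dims[2])
}

# even-odd rule point-in-polygon test, vectorized over points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

gauss_smooth <- function(x, sigma) {
  if (sigma <= 0 || length(x) < 3) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    kk <- k[(lo - i + half + 1):(hi - i + half + 1)]
    out[i] <- sum(x[lo:hi] * kk) / sum(kk)
  }
  out
}

#' Bin retraction profiles by folding-stage angle
#'
#' Profiles are sorted into half-open 15-degree bins `[lo, lo + 15)` of
#' the opening angle, anchored so the developmental stages fall on the
#' conventional boundaries (..., 110-125, 125-140, 140-155, ...; an angle
#' of exactly 140 falls in `[140, 155)`). The bins partition `(0, 180]`,
#' and the distribution of maximum retraction speeds is summarised
#' per bin, with a one-way ANOVA across bins and Dunnett multiple
#' comparisons against a reference bin.
#'
#' @param profiles A tibble with one row per ablated tissue: columns
#'   `stage_angle` (degrees) and `max_speed` (um/s, e.g.
#'   `attr(profile, "max_speed_um_s")`).
#' @param bin_width Bin width, degrees.
#' @param anchor Offset of the bin boundaries, degrees (5 places the
#'   boundaries at 110, 125, 140, ...).
#' @param reference Reference bin label for Dunnett contrasts; default is
#'   the populated bin with the largest angles (the least-folded stage).
#' @return A list of class `angle_bins`: `summary` (per-bin tibble:
#'   `bin`, `n`, `median_max_speed`, `iqr`), `data` (input with `bin`),
#'   `anova` (the `aov` fit, `NULL` if < 2 populated bins), `dunnett`
#'   (multcomp `glht` summary or `NULL`).
#' @export
bin_by_angle <- function(profiles, bin_width = 15, anchor = 5,
                         reference = NULL) {
  stopifnot(all(c("stage_angle", "max_speed") %in% names(profiles)))
  ang <- profiles$stage_angle
  if (any(ang <= 0 | ang > 180)) abort("stage angles must lie in (0, 180]")
  lo <- floor((ang - anchor) / bin_width) * bin_width + anchor
  bin <- sprintf("[%g,%g)", lo, lo + bin_width)
  dat <- dplyr::mutate(profiles, bin = bin, bin_lo = lo)
  summ <- dat |>
    dplyr::group_by(.data$bin, .data$bin_lo) |>
    dplyr::summarise(n = dplyr::n(),
                     median_max_speed = median(.data$max_speed),
                     iqr = stats::IQR(.data$max_speed),
                     .groups = "drop") |>
    dplyr::arrange(.data$bin_lo)
  fit <- NULL; dun <- NULL
  if (length(unique(dat$bin)) >= 2) {
    if (is.null(reference)) {
      reference <- summ$bin[which.max(summ$bin_lo)]
    }
    dat$bin_f <- stats::relevel(factor(dat$bin), ref = reference)
    fit <- aov(max_speed ~ bin_f, data = dat)
    if (all(summ$n >= 2)) {
      dun <- tryCatch(
        summary(multcomp::glht(fit,
                               linfct = multcomp::mcp(bin_f = "Dunnett"))),
        error = function(e) NULL)
    }
  }
  structure(list(summary = summ, data = dat, anova = fit, dunnett = dun,
                 reference = reference),
            class = "angle_bins")
}

#' @export
print.angle_bins <- function(x, ...) {
  cat("<angle_bins>\n")
  print(x$summary)
  if (!is.null(x$anova)) {
    p <- summary(x$anova)[[1]][["Pr(>F)"]][1]
    cat(sprintf("one-way ANOVA p = %.3g (reference bin %s)\n", p,
                x$reference))
  }
  invisible(x)
}

#' @rdname bin_by_angle
#' @param x An `angle_bins` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.angle_bins <- function(x, ...) {
  p <- if (!is.null(x$anova)) summary(x$anova)[[1]][["Pr(>F)"]][1]
       else NA_real_
  top <- x$summary$bin[which.max(x$summary$median_max_speed)]
  tibble::tibble(n_bins = nrow(x$summary), anova_p = p,
                 top_bin = top,
                 top_bin_median = max(x$summary$median_max_speed))
}

#' Compare retraction between tissue regions
#'
#' Summarises retraction profiles per region and flags a "global
#' response" when a region's maximum smoothed speed exceeds
#' `noise_mult` times its own pre-cut noise floor (mean + 2 sd of the
#' pre-cut smoothed speeds, with a small absolute floor).
#'
#' @param profiles A named list of `retraction_profile` objects (names
#'   are region labels, e.g. `central`, `distal`), or a list with a
#'   `region_label` attribute on each element.
#' @param noise_mult Multiple of the noise floor required to flag a
#'   response.
#' @return A tibble (`region`, `max_speed_um_s`, `noise_floor_um_s`,
#'   `responding`).
#' @export
compare_regions <- function(profiles, noise_mult = 3) {
  if (!length(profiles)) abort("no profiles supplied")
  labs <- names(profiles)
  if (is.null(labs)) {
    labs <- vapply(profiles, function(p) {
      l <- attr(p, "region_label")
      if (is.null(l) || is.na(l)) "region" else l
    }, "")
  }
  rows <- purrr::map2(profiles, labs, function(p, lab) {
    floorv <- attr(p, "noise_floor_um_s")
    if (is.null(floorv) || !is.finite(floorv)) floorv <- 1e-3
    mx <- attr(p, "max_speed_um_s")
    tibble::tibble(region = lab, max_speed_um_s = mx,
                   noise_floor_um_s = floorv,
                   responding = mx > noise_mult * floorv)
  })
  dplyr::bind_rows(rows)
}

#' Fit the temporal decay constant of a retraction profile
#'
#' Log-linear fit of the raw post-cut speeds, restricted to speeds above
#' a fraction of the post-cut maximum so the late jitter floor does not
#' bias the slope.
#'
#' @param profile A `retraction_profile`.
#' @param min_frac Fraction of the post-cut maximum below which samples
#'   are dropped.
#' @return Decay time in seconds.
#' @export
fit_decay_time <- function(profile, min_frac = 0.25) {
  cut <- attr(profile, "cut_frame")
  dt <- diff(profile$time_s[1:2])
  post <- profile$speed_um_s[(cut + 1):nrow(profile)]
  keep <- which(post > min_frac * max(post))
  keep <- seq_len(max(keep))          # contiguous head of the decay
  sel <- post[keep] > 0
  fit <- lm(log(post[keep][sel]) ~ keep[sel])
  -dt / unname(coef(fit)[2])
}
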