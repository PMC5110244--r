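#' Specification of a synthetic laser-ablation movie
#'
#' A textured tissue image is displaced, after the cut frame, by a radial
#' recoil field whose magnitude decays exponentially in time,
#' `v(t) = peak_speed * exp(-t / decay_time)`. In `local` mode the field is
#' additionally attenuated with distance from the cut,
#' `exp(-d / decay_radius)`; in `global` mode the whole tissue recoils
#' without spatial decay, emulating the tissue-wide relaxation seen in a
#' 125-140 degree folding stage.
#'
#' @param stage_angle Opening angle of the folding stage, degrees, in
#'   `(0, 180]`. Supplied metadata, carried into retraction profiles.
#' @param response_mode `"local"` or `"global"`.
#' @param peak_speed Recoil speed at the cut immediately after ablation,
#'   um/s (>= 0).
#' @param decay_time Temporal decay constant of the recoil, seconds.
#' @param decay_radius Spatial decay length in `local` mode, um.
#' @param cut_frame Last frame before the cut (1-based; recoil starts at
#'   `cut_frame + 1`). Must be < `n_frames`.
#' @param n_frames,frame_interval,pixel_size Movie geometry; frame interval
#'   defaults to the 0.5 s of fast recoil imaging.
#' @param size_um Side length of the square field of view, um.
#' @param cut_frac Fractional (row, col) position of the cut.
#' @param noise_level Photon-noise scale.
#' @param seed Integer seed.
#' @return A list of class `ablation_spec`.
#' @export
ablation_spec <- function(stage_angle = 130,
                          response_mode = c("local", "global"),
                          peak_speed = 0.8, decay_time = 10,
                          decay_radius = 12, cut_frame = 10L,
                          n_frames = 60L, frame_interval = 0.5,
                          pixel_size = 0.3, size_um = 100,
                          cut_frac = c(0.5, 0.35),
                          noise_level = 0.05, seed = 1L) {
  response_mode <- match.arg(response_mode)
  if (stage_angle <= 0 || stage_angle > 180) {
    abort("`stage_angle` must lie in (0, 180]")
  }
  if (peak_speed < 0) abort("`peak_speed` must be >= 0")
  check_positive(decay_time, "decay_time")
  check_positive(decay_radius, "decay_radius")
  check_positive(frame_interval, "frame_interval")
  check_positive(pixel_size, "pixel_size")
  if (cut_frame >= n_frames) abort("`cut_frame` must be < `n_frames`")
  if (cut_frame < 1) abort("`cut_frame` must be >= 1")
  structure(list(stage_angle = stage_angle, response_mode = response_mode,
                 peak_speed = peak_speed, decay_time = decay_time,
                 decay_radius = decay_radius,
                 cut_frame = as.integer(cut_frame),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, pixel_size = pixel_size,
                 size_um = size_um, cut_frac = cut_frac,
                 noise_level = noise_level, seed = as.integer(seed)),
            class = "ablation_spec")
}

#' Generate a synthetic post-ablation recoil movie
#'
#' The tissue texture is filtered-noise speckle (sufficient for corner
#' detection and feature tracking); each post-cut frame warps the texture
#' by the cumulative truth displacement field using bilinear resampling.
#'
#' @param spec An [ablation_spec()].
#' @return A list with `movie` (an [intensity_movie()]), `truth` (list:
#'   `speed_um_s` per-frame recoil speed at the cut, `cut_px` cut position,
#'   `radial_gain(d_um)` spatial attenuation function, `cum_disp_um`
#'   per-frame cumulative displacement magnitude at the cut), and `spec`.
#' @export
generate_ablation_movie <- function(spec) {
  stopifnot(inherits(spec, "ablation_spec"))
  ps <- spec$pixel_size
  W <- ceiling(spec$size_um / ps)
  withr::with_seed(spec$seed, {
    tex <- matrix(runif(W * W), W, W)
    tex <- as.matrix(EBImage::gblur(tex, sigma = 2))
    tex <- 0.2 + 0.8 * (tex - min(tex)) / diff(range(tex))
    cut <- c(spec$cut_frac[1] * W, spec$cut_frac[2] * W)
    gx <- matrix(rep(seq_len(W), times = W), W)   # row coord
    gy <- matrix(rep(seq_len(W), each = W), W)    # col coord
    dx <- gx - cut[1]; dy <- gy - cut[2]
    d_px <- sqrt(dx^2 + dy^2)
    ux <- ifelse(d_px > 0, dx / pmax(d_px, 1e-9), 0)
    uy <- ifelse(d_px > 0, dy / pmax(d_px, 1e-9), 0)
    gain <- switch(spec$response_mode,
                   local = exp(-(d_px * ps) / spec$decay_radius),
                   global = matrix(1, W, W))
    dt <- spec$frame_interval
    tau <- pmax((seq_len(spec$n_frames) - spec$cut_frame - 1) * dt, 0)
    v <- ifelse(seq_len(spec$n_frames) > spec$cut_frame,
                spec$peak_speed * exp(-tau / spec$decay_time), 0)
    cum <- cumsum(v * dt)                     # um, at the cut
    out <- array(0, c(W, W, spec$n_frames))
    peak <- max(4, round(1 / max(spec$noise_level, 1e-6)^2))
    for (t in seq_len(spec$n_frames)) {
      if (cum[t] > 0) {
        mag <- (cum[t] / ps) * gain           # px
        frame <- bilinear_sample(tex, gx - mag * ux, gy - mag * uy)
        frame <- matrix(frame, W, W)
      } else frame <- tex
      if (spec$noise_level > 0) {
        frame <- matrix(pmax(rpois(length(frame), frame * peak) / peak +
                               rnorm(length(frame),
                                     0, 0.25 * spec$noise_level), 0), W)
      }
      out[, , t] <- frame
    }
    radial_gain <- switch(spec$response_mode,
                          local = local({
                            dr <- spec$decay_radius
                            function(d_um) exp(-d_um / dr)
                          }),
                          global = function(d_um) rep(1, length(d_um)))
    list(movie = intensity_movie(out, ps, dt),
         truth = list(speed_um_s = v, cut_px = cut,
                      radial_gain = radial_gain, cum_disp_um = cum),
         spec = spec)
  })
}

# Bilinear interpolation of img at fractional (row, col) positions.
# Out-of-range positions clamp to the border.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(as.vector(x), 1), nr)
  y <- pmin(pmax(as.vector(y), 1), nc)
  x0 <- pmin(floor(x), nr - 1L); y0 <- pmin(floor(y), nc - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- (y0 - 1) * nr + x0
  v00 <- img[i00];         v10 <- img[i00 + 1]
  v01 <- img[i00 + nr];    v11 <- img[i00 + nr + 1]
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}
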