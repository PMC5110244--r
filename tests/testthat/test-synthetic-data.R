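test_that("identical spec and seed give bit-identical movies", {
  sp <- sheet_spec(n_cells = 12, n_frames = 4, seed = 7)
  a <- generate_sheet_movie(sp)
  b <- generate_sheet_movie(sp)
  expect_identical(a$membrane, b$membrane)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth$area_um2, b$truth$area_um2)
})

test_that("degenerate dynamics give constant truth areas", {
  sp <- sheet_spec(n_cells = 8, n_frames = 6, osc_amplitude = 0,
                   ratchet_from = 20, ratchet_to = 20, seed = 2)
  tr <- build_sheet_truth(sp)
  expect_true(all(abs(tr$area_um2 - tr$area_um2[, 1]) < 1e-12))
})

test_that("truth series autocorrelation peaks at the oscillation period", {
  # 50 mHz sampled at 5 s: period 20 s = 4 frames
  sp <- sheet_spec(n_cells = 6, n_frames = 120, osc_freq = 50,
                   frame_interval = 5, ratchet_from = 20, ratchet_to = 20,
                   seed = 3)
  tr <- build_sheet_truth(sp)
  for (i in 1:6) {
    ac <- stats::acf(tr$area_um2[i, ], lag.max = 10, plot = FALSE)$acf[-1]
    expect_equal(which.max(ac), 4L)
  }
})

test_that("spec invariants are enforced", {
  expect_error(sheet_spec(n_cells = 3), "n_cells")
  expect_error(sheet_spec(frame_interval = 0), "frame_interval")
  expect_error(sheet_spec(pixel_size = -1), "pixel_size")
  expect_error(sheet_spec(ratchet_from = 10, ratchet_to = 20), "ratchet")
  expect_error(foci_spec(lifetime_mean = 0), "lifetime_mean")
  expect_error(foci_spec(indentation_depth = -1), "indentation_depth")
  expect_error(ablation_spec(stage_angle = 190), "stage_angle")
  expect_error(ablation_spec(peak_speed = -1), "peak_speed")
  expect_error(ablation_spec(cut_frame = 60, n_frames = 60), "cut_frame")
})

test_that("rendered label areas track truth areas within quantization", {
  mv <- small_sheet()
  n <- mv$truth$spec$n_cells
  ps <- mv$truth$spec$pixel_size
  meas <- apply(mv$labels, 3, function(L) tabulate(L[L > 0], n)) * ps^2
  err <- abs(meas - mv$truth$area_um2)
  # bound: one pixel layer along a fraction of the perimeter
  perim_px <- 2 * sqrt(pi * mv$truth$area_um2 / ps^2)
  expect_true(all(err <= ps^2 * (0.25 * perim_px + 4)))
})

test_that("independent phases give uncorrelated truth area series", {
  sp <- sheet_spec(n_cells = 40, n_frames = 300, seed = 13)
  tr <- build_sheet_truth(sp)
  rate <- t(apply(tr$area_um2, 1, diff))
  pairs <- t(utils::combn(40, 2))[1:150, ]
  r <- vapply(seq_len(nrow(pairs)), function(k) {
    cor(rate[pairs[k, 1], ], rate[pairs[k, 2], ])
  }, numeric(1))
  expect_lt(abs(median(r)), 0.2)
})

test_that("actin channel coupling matches its target", {
  sp <- sheet_spec(n_cells = 10, n_frames = 200, seed = 11)
  tr <- build_sheet_truth(sp)
  # rho = 1, noise = 0: per-cell rate correlation exactly 1
  ac1 <- generate_actin_channel(tr, rho = 1, noise = 0, seed = 4)
  r1 <- vapply(1:10, function(i) {
    cor(diff(ac1$intensity_au[i, ]), diff(tr$area_um2[i, ]))
  }, numeric(1))
  expect_true(all(r1 > 1 - 1e-9))
  expect_true(all(ac1$intensity_au >= 0))
  # rho = 0 over many cells: mean brute-force coefficient near 0
  sp50 <- sheet_spec(n_cells = 50, n_frames = 200, seed = 12)
  tr50 <- build_sheet_truth(sp50)
  ac0 <- generate_actin_channel(tr50, rho = 0, seed = 5)
  r0 <- vapply(1:50, function(i) {
    cor(diff(ac0$intensity_au[i, ]), diff(tr50$area_um2[i, ]))
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.1)
  expect_error(generate_actin_channel(tr, rho = 1.2), "rho")
})

test_that("focus events respect lifetimes and never touch other cells", {
  fx <- foci_sheet()
  fs <- foci_spec(event_rate = 2, lifetime_mean = 4,
                  contraction_step = 3, seed = 7)
  fc <- generate_foci_channel(fx$truth, fs)
  expect_gt(nrow(fc$events), 5)
  # mean lifetime near 4 min (truncated normal, floor 2 frames)
  expect_lt(abs(mean(fc$events$lifetime_min) - 4), 1)
  # lifetime = (end - start + 1) * dt / 60 exactly
  expect_equal(fc$events$lifetime_min,
               (fc$events$end_frame - fc$events$start_frame + 1) * 10 / 60)
  # conservation: cells without events keep their original truth series
  hosts <- unique(fc$events$cell_id)
  others <- setdiff(seq_len(30), hosts)
  expect_identical(fc$truth$area_um2[others, ], fx$truth$area_um2[others, ])
  # hosts lose exactly the accumulated steps by the end
  n_ev <- table(factor(fc$events$cell_id, seq_len(30)))
  dA_end <- fx$truth$area_um2[, 120] - fc$truth$area_um2[, 120]
  expect_equal(unname(dA_end[hosts]), 3 * as.numeric(n_ev[hosts]),
               tolerance = 1e-9)
})

test_that("zero event rate gives an empty focus channel", {
  fx <- foci_sheet()
  fc <- generate_foci_channel(fx$truth, foci_spec(event_rate = 0, seed = 1))
  expect_equal(nrow(fc$events), 0)
  expect_identical(fc$truth$area_um2, fx$truth$area_um2)
})

test_that("stabilized-condition lifetimes are recovered in truth", {
  fx <- foci_sheet()
  sp_long <- sheet_spec(n_cells = 30, n_frames = 360, frame_interval = 10,
                        ratchet_from = 25.4, ratchet_to = 25.4, seed = 41)
  tr_long <- build_sheet_truth(sp_long)
  fc <- generate_foci_channel(tr_long,
                              foci_spec(event_rate = 0.8,
                                        lifetime_mean = 21.5, seed = 7))
  expect_gt(nrow(fc$events), 3)
  expect_lt(abs(mean(fc$events$lifetime_min) - 21.5), 4)
})

test_that("ablation truth displacement follows the specified field", {
  # zero peak speed: no displacement, frames identical up to noise seed
  sp0 <- ablation_spec(peak_speed = 0, noise_level = 0, n_frames = 6,
                       cut_frame = 2, seed = 3)
  ab0 <- generate_ablation_movie(sp0)
  expect_true(all(ab0$truth$cum_disp_um == 0))
  expect_identical(ab0$movie[, , 1], ab0$movie[, , 6])
  # local mode: speed at 3 decay radii below 5% of the speed at the cut
  spL <- ablation_spec(response_mode = "local", decay_radius = 12)
  abL <- generate_ablation_movie(spL)
  expect_lt(abL$truth$radial_gain(3 * 12), 0.05)
  expect_equal(abL$truth$radial_gain(0), 1)
  # temporal decay: first post-cut speed is the peak
  expect_equal(max(abL$truth$speed_um_s), spL$peak_speed)
  expect_equal(which.max(abL$truth$speed_um_s), spL$cut_frame + 1L)
})

test_that("movies survive a TIFF round trip", {
  mv <- clean_sheet()
  tmp <- tempfile(fileext = ".tif")
  write_movie_tiff(mv$labels, tmp)
  back <- read_movie_tiff(tmp, pixel_size = 0.3, frame_interval = 5,
                          labels = TRUE)
  expect_equal(dim(back), dim(mv$labels))
  expect_true(all(back == mv$labels))
  unlink(tmp)
})
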