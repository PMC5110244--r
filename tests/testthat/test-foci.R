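test_that("isolated Gaussian blobs are detected and localized", {
  # one cell mask filling the frame interior, one bright blob on the band
  lab <- matrix(0L, 40, 40)
  lab[2:39, 2:39] <- 1L
  blob <- function(amp, x0, y0) {
    img <- matrix(0.05, 40, 40)
    img + amp * exp(-((row(img) - x0)^2 + (col(img) - y0)^2) / (2 * 1.5^2))
  }
  labs <- label_movie(list(lab, lab, lab), 0.3, 10)
  withr::with_seed(1, {
    noisy <- function(img) img + rnorm(length(img), 0, 0.01)
    mv5 <- intensity_movie(lapply(1:3, function(i) noisy(blob(0.5, 3, 20))),
                           0.3, 10)
  })
  ev <- detect_and_link_foci(mv5, labs, k_sigma = 3, min_area_px = 3)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$x_px - 3), 1)
  expect_lt(abs(ev$y_px - 20), 1)
  # a bump at ~1 sigma of the noise stays undetected
  withr::with_seed(2, {
    mv1 <- intensity_movie(lapply(1:3, function(i) {
      blob(0.01, 3, 20) + rnorm(1600, 0, 0.01)
    }), 0.3, 10)
  })
  expect_equal(nrow(detect_and_link_foci(mv1, labs, min_area_px = 3)), 0)
  # two blobs separated beyond r_max give two events
  withr::with_seed(3, {
    mv2 <- intensity_movie(lapply(1:3, function(i) {
      noisy(blob(0.5, 3, 8) + blob(0.5, 3, 32) - 0.05)
    }), 0.3, 10)
  })
  ev2 <- detect_and_link_foci(mv2, labs, min_area_px = 3, r_max_px = 6)
  expect_equal(nrow(ev2), 2)
})

test_that("detection on generator foci reaches recall/precision targets", {
  fx <- foci_sheet()
  fs <- foci_spec(event_rate = 2, lifetime_mean = 4, seed = 7)
  fc <- generate_foci_channel(fx$truth, fs, labels = fx$movie$labels)
  det <- detect_and_link_foci(fc$movie, fx$movie$labels)
  recall <- mean(vapply(seq_len(nrow(fc$events)), function(i) {
    e <- fc$events[i, ]
    any(det$cell_id == e$cell_id & det$start_frame <= e$end_frame &
          det$end_frame >= e$start_frame)
  }, logical(1)))
  fp <- mean(vapply(seq_len(nrow(det)), function(k) {
    d <- det[k, ]
    !any(sqrt((fc$events$x_px - d$x_px)^2 +
                (fc$events$y_px - d$y_px)^2) <= 6 &
           fc$events$start_frame <= d$end_frame &
           fc$events$end_frame >= d$start_frame)
  }, logical(1)))
  expect_gte(recall, 0.95)
  expect_lte(fp, 0.05)
  # lifetime recovery within one frame for matched events
  best <- vapply(seq_len(nrow(fc$events)), function(i) {
    e <- fc$events[i, ]
    m <- det[det$cell_id == e$cell_id & det$start_frame <= e$end_frame &
               det$end_frame >= e$start_frame, ]
    if (nrow(m)) max(m$lifetime_min) else NA_real_
  }, numeric(1))
  expect_lt(abs(mean(best, na.rm = TRUE) - mean(fc$events$lifetime_min)),
            10 / 60)
})

test_that("focus stability summarises lifetimes and compares conditions", {
  ev <- tibble::tibble(
    focus_id = 1:6,
    start_frame = c(10, 0, 5, 0, 0, 0),
    end_frame = c(33, 0, 10, 120, 130, 125),
    lifetime_min = c(24, 1, 6, 121, 131, 126) * 10 / 60,
    condition = rep(c("control", "stabilized"), each = 3))
  # frames 10..33 at dt = 10 s: 4 minutes
  expect_equal(ev$lifetime_min[1], 4)
  # single-frame event: dt / 60 minutes
  expect_equal(ev$lifetime_min[2], 10 / 60)
  st <- focus_stability(ev)
  expect_equal(nrow(st), 2)
  expect_true(attr(st, "test")$p.value < 0.05)
  expect_error(focus_stability(ev[0, ]), "no focus")
})

test_that("edge indentation is recovered to a pixel", {
  fs <- foci_spec(indentation_depth = 2.3, lifetime_mean = 4, seed = 9)
  em <- generate_edge_movie(fs, n_frames = 60, frame_interval = 10,
                            onset_frame = 15)
  ind <- ab_shortening(em$movie, column = 20,
                       start_frame = em$event$start_frame,
                       end_frame = em$event$end_frame)
  expect_lt(abs(attr(ind, "max_shortening_um") - 2.3), 0.3)
  expect_true(attr(ind, "reliable"))
  # no-displacement movie: shortening within the noise floor
  fs0 <- foci_spec(indentation_depth = 0, seed = 9)
  em0 <- generate_edge_movie(fs0, n_frames = 60, frame_interval = 10,
                             onset_frame = 15)
  ind0 <- ab_shortening(em0$movie, 20, em0$event$start_frame,
                        em0$event$end_frame)
  expect_lt(abs(attr(ind0, "max_shortening_um")), 0.3)
})

test_that("only the host cell contracts during a focus", {
  fx <- foci_sheet()
  fs <- foci_spec(event_rate = 2, contraction_step = 3, seed = 7)
  fc <- generate_foci_channel(fx$truth, fs)
  mv <- render_sheet_movie(fc$truth)
  meas <- measure_areas(truth_tracked(mv$labels, 30))
  fac <- focus_area_coupling(fc$events, meas$tracks, meas$neighbors)
  expect_lt(abs(mean(fac$host_dA_um2, na.rm = TRUE) + 3), 0.5)
  expect_lt(abs(mean(fac$neighbor_dA_um2, na.rm = TRUE)), 0.5)
  expect_lt(attr(fac, "test")$p.value, 0.01)
  # events on ambiguous tracks are excluded with a warning
  tracks2 <- meas$tracks
  tracks2$status[tracks2$cell_id == fc$events$cell_id[1]] <- "ambiguous"
  expect_warning(
    fac2 <- focus_area_coupling(fc$events, tracks2, meas$neighbors),
    "excluded")
  expect_gte(attr(fac2, "n_excluded"), 1)
})
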