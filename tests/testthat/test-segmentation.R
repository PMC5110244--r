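test_that("watershed recovers the rendered tessellation", {
  mv <- clean_sheet()
  img <- movie_frame(mv$membrane, 1)
  seg <- segment_frame(img)
  expect_equal(max(seg), 40)
  # determinism
  expect_identical(seg, segment_frame(img))
  # constant image is a degenerate input
  expect_error(segment_frame(matrix(0.5, 32, 32)), "constant")
})

test_that("interior cell areas are within 5% of truth on clean renders", {
  mv <- clean_sheet()
  seg <- segment_frame(movie_frame(mv$membrane, 1))
  L <- movie_frame(mv$labels, 1)
  ids <- interior_cells(mv$truth)
  m <- match_seg_to_truth(seg, L, 40)
  err <- vapply(ids, function(i) {
    abs(sum(seg == m[i]) - sum(L == i)) / sum(L == i)
  }, numeric(1))
  expect_true(all(err < 0.05))
})

test_that("tracking keeps ids through a static movie and flags removals", {
  mv <- clean_sheet()
  static <- label_movie(lapply(1:4, function(i) movie_frame(mv$labels, 1)),
                        0.3, 5)
  trk <- track_labels(static)
  interior <- interior_cells(mv$truth)
  expect_true(all(trk$cells$n_frames_present[trk$cells$cell_id %in%
                                               seq_len(40)] == 4))
  # cell removed mid-movie becomes ambiguous
  frames <- lapply(1:4, function(i) movie_frame(mv$labels, 1))
  victim <- interior[1]
  for (i in 3:4) frames[[i]][frames[[i]] == victim] <- 0L
  trk2 <- track_labels(label_movie(frames, 0.3, 5))
  expect_equal(trk2$cells$status[victim], "ambiguous")
  expect_lt(trk2$cells$n_frames_present[victim], 4)
})

test_that("tracking is invariant to per-frame label permutation", {
  mv <- clean_sheet()
  f1 <- movie_frame(mv$labels, 1)
  perm <- withr::with_seed(9, sample(40))
  f2 <- ifelse(f1 > 0, perm[pmax(f1, 1)], 0L)
  trk_a <- track_labels(label_movie(list(f1, f1, f1), 0.3, 5))
  trk_b <- track_labels(label_movie(list(f1, f2, f1), 0.3, 5))
  # same correspondence: every region carries one id through the movie
  expect_identical(trk_a$cells$status, trk_b$cells$status)
  expect_identical(trk_a$labels[, , 3], trk_b$labels[, , 3])
})

test_that("area measurement applies the pixel calibration exactly", {
  # 10 x 10 px square at 0.5 um/px: (10 * 0.5)^2 = 25 um^2
  f <- matrix(0L, 20, 20)
  f[6:15, 6:15] <- 1L
  tracked <- list(labels = label_movie(list(f, f), 0.5, 5),
                  cells = tibble::tibble(cell_id = 1L, status = "complete"))
  meas <- measure_areas(tracked)
  expect_equal(meas$tracks$area_um2, c(25, 25))
  expect_error(measure_areas(tracked, pixel_size = 0), "pixel_size")
})

test_that("pixel counts are conserved across labels and background", {
  mv <- small_sheet()
  L <- movie_frame(mv$labels, 1)
  expect_equal(sum(L > 0) + sum(L == 0), length(L))
  seg <- segment_frame(movie_frame(mv$membrane, 1))
  expect_equal(sum(tabulate(seg[seg > 0])) + sum(seg == 0), length(seg))
})

test_that("tracked areas on a noisy movie match truth within 5% (median)", {
  mv <- small_sheet()
  segm <- segment_movie(mv$membrane)
  trk <- track_labels(segm)
  meas <- measure_areas(trk)
  ids <- interior_cells(mv$truth)
  L1 <- movie_frame(mv$labels, 1)
  S1 <- movie_frame(trk$labels, 1)
  m <- match_seg_to_truth(S1, L1, 40)
  rel <- unlist(lapply(ids, function(i) {
    tr <- meas$tracks[meas$tracks$cell_id == m[i], ]
    truth <- mv$truth$area_um2[i, tr$frame + 1]
    abs(tr$area_um2 - truth) / truth
  }))
  expect_lt(median(rel), 0.05)
})

test_that("interior cells give complete tracks at default noise", {
  mv <- small_sheet()
  trk <- track_labels(segment_movie(mv$membrane))
  ids <- interior_cells(mv$truth)
  m <- match_seg_to_truth(movie_frame(trk$labels, 1),
                          movie_frame(mv$labels, 1), 40)
  status <- trk$cells$status[match(m[ids], trk$cells$cell_id)]
  expect_gte(mean(status == "complete"), 0.9)
})

test_that("mask-overlap intensity measurement averages per cell", {
  f <- matrix(0L, 12, 12)
  f[2:5, 2:5] <- 1L
  f[8:11, 8:11] <- 2L
  img <- matrix(0.1, 12, 12)
  img[f == 1] <- 0.5
  img[f == 2] <- 0.9
  mi <- measure_intensity(intensity_movie(list(img), 1, 1),
                          label_movie(list(f), 1, 1))
  expect_equal(mi$mean_intensity, c(0.5, 0.9))
})
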