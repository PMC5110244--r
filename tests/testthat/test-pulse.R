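test_that("area_rate differentiates and rescales to per-minute units", {
  expect_equal(area_rate(rep(5, 10), 5), rep(0, 10))
  # slope 0.1 um^2/s -> 6 um^2/min
  x <- 0.1 * (0:20) * 5
  expect_equal(area_rate(x, 5), rep(6, 21))
  expect_error(area_rate(c(1, 2), 5), "3 samples")
})

test_that("area_rate matches the closed-form sinusoid derivative", {
  # A sin(2 pi f t): extrema of the true derivative are 2 pi f A (per s)
  dt <- 1
  tt <- seq(0, 500, by = dt)
  x <- 3 * sin(2 * pi * 0.05 * tt)
  r <- area_rate(x, dt)
  truth <- 2 * pi * 0.05 * 3 * 60
  # 20 samples per cycle: discretization attenuation sin(w dt)/(w dt) ~ 0.984
  expect_lt(abs(max(r) - truth) / truth, 0.05)
  expect_lt(abs(min(r) + truth) / truth, 0.05)
})

test_that("area_rate is linear", {
  withr::with_seed(4, {
    x <- rnorm(50); y <- rnorm(50)
  })
  expect_equal(area_rate(2 * x + 3 * y, 5),
               2 * area_rate(x, 5) + 3 * area_rate(y, 5))
})

test_that("pulse_stats recovers frequency, net change and classification", {
  dt <- 5
  tt <- seq(0, 1495, by = dt)
  s <- pulse_stats(20 + 3 * sin(2 * pi * 0.05 * tt), dt)
  bin <- 1000 / (1500 - 60)  # spectral bin after detrend-edge trimming
  expect_lt(abs(s$dominant_freq_mHz - 50), 2 * bin)
  expect_equal(s$classification, "stable")

  # ratcheted decline 25.4 -> 15.3 um^2 classifies as constricting
  s2 <- pulse_stats(seq(25.4, 15.3, length.out = 301), dt)
  expect_lt(abs(s2$net_change_pct - (-39.8)), 4)
  expect_equal(s2$classification, "constricting")
  expect_true(is.na(s2$dominant_freq_mHz))  # no oscillation: undefined

  # constant series: stable, zero change, undefined frequency
  s3 <- pulse_stats(rep(7, 200), dt)
  expect_equal(s3$net_change_pct, 0)
  expect_equal(s3$classification, "stable")
  expect_true(is.na(s3$dominant_freq_mHz))
})

test_that("peak-to-peak amplitude matches the sinusoid rate excursion", {
  dt <- 1
  tt <- seq(0, 600, by = dt)
  x <- 20 + 3 * sin(2 * pi * 0.05 * tt)
  s <- pulse_stats(x, dt, window_s = 600)
  truth_pp <- 2 * 2 * pi * 0.05 * 3 * 60
  expect_lt(abs(s$peak_to_peak_um2_min - truth_pp) / truth_pp, 0.15)
})

test_that("classification scales monotonically with the decline", {
  dt <- 5
  base <- seq(25, 20, length.out = 301)     # -20%
  strong <- seq(25, 15, length.out = 301)   # -40%
  s1 <- pulse_stats(base, dt)
  s2 <- pulse_stats(strong, dt)
  expect_gt(abs(s2$net_change_pct), abs(s1$net_change_pct))
  expect_false(s2$classification == "relaxing")
})

test_that("neighbor synchrony classifies pairs by |R| at 0.5", {
  tt <- seq(0, 500, by = 5)
  a <- 20 + 3 * sin(2 * pi * 0.05 * tt)
  mk <- function(id, vals) tibble::tibble(cell_id = id,
                                          frame = seq_along(vals) - 1L,
                                          area_um2 = vals)
  tracks <- dplyr::bind_rows(mk(1, a), mk(2, a), mk(3, 40 - a))
  nb <- tibble::tibble(frame = rep(0:(length(tt) - 1), 2),
                       cell_a = rep(c(1, 1), each = length(tt)),
                       cell_b = rep(c(2, 3), each = length(tt)))
  sync <- neighbor_sync(tracks, nb, frame_interval = 5)
  expect_equal(sync$r[sync$cell_b == 2], 1, tolerance = 1e-9)
  expect_equal(sync$r[sync$cell_b == 3], -1, tolerance = 1e-9)
  expect_true(all(sync$synchronous))  # |R| >= 0.5 either sign
  expect_equal(attr(sync, "fraction_asynchronous"), 0)
  # zero-variance member is excluded with a warning
  tracks2 <- dplyr::bind_rows(tracks, mk(4, rep(5, length(tt))))
  nb2 <- dplyr::bind_rows(nb, tibble::tibble(frame = 0:(length(tt) - 1),
                                             cell_a = 1, cell_b = 4))
  expect_warning(sync2 <- neighbor_sync(tracks2, nb2, 5), "zero variance")
  expect_false(4 %in% sync2$cell_b)
})

test_that("asynchronous fraction matches a truth-series oracle", {
  sp <- sheet_spec(n_cells = 40, n_frames = 300, seed = 13)
  tr <- build_sheet_truth(sp)
  pairs <- t(utils::combn(40, 2))[1:120, ]
  r <- vapply(seq_len(nrow(pairs)), function(k) {
    cor(diff(tr$area_um2[pairs[k, 1], ]), diff(tr$area_um2[pairs[k, 2], ]))
  }, numeric(1))
  frac_oracle <- mean(abs(r) < 0.5)
  tracks <- truth_tracks(tr)
  nb <- tibble::tibble(frame = 0, cell_a = pairs[, 1], cell_b = pairs[, 2])
  # pairs listed in one frame only; require presence in >= half the movie
  nb <- dplyr::bind_rows(lapply(0:299, function(f) {
    tibble::tibble(frame = f, cell_a = pairs[, 1], cell_b = pairs[, 2])
  }))
  sync <- neighbor_sync(tracks, nb, 5)
  expect_lt(abs(attr(sync, "fraction_asynchronous") - frac_oracle), 0.05)
})

test_that("edge distance variation reports transients and finals", {
  a <- cbind(rep(0, 5), rep(0, 5))
  b <- cbind(c(10, 11, 12, 11, 10), rep(0, 5))
  v <- edge_distance_variation(a, b, pixel_size = 1)
  expect_equal(attr(v, "max_variation_pct"), 20)
  expect_equal(attr(v, "final_variation_pct"), 0)
  expect_equal(v$variation_pct[1], 0)
  # static points: zero everywhere
  v0 <- edge_distance_variation(a, a + 10, pixel_size = 0.5)
  expect_true(all(v0$variation_pct == 0))
  expect_error(edge_distance_variation(a, a), "zero")
})
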