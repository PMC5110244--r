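test_that("uniform translations are recovered within 10%", {
  for (v in c(0.5, 1.5, 3)) {
    m <- translation_movie(v)
    pts <- good_features(movie_frame(m, 1), n = 11)
    expect_gte(nrow(pts), 5)
    pos <- lk_track(m, pts)
    sp <- vapply(2:n_frames(m), function(t) {
      median(sqrt((pos[, 1, t] - pos[, 1, t - 1])^2 +
                    (pos[, 2, t] - pos[, 2, t - 1])^2))
    }, numeric(1))
    expect_lt(abs(median(sp) - v) / v, 0.10)
  }
})

test_that("rigid translation yields the arithmetic raw speed", {
  # 2 px/frame at 0.3 um/px and dt = 0.5 s: 1.2 um/s
  m <- translation_movie(2, n_frames = 14)
  W <- dim(m)[1]
  prof <- track_retraction(m, rect_mask(W, c(0.3, 0.7), c(0.3, 0.6)),
                           cut_frame = 2)
  post <- prof$speed_um_s[prof$frame >= 3 & prof$frame <= 10]
  expect_true(all(abs(post - 1.2) < 0.12))
})

test_that("a static movie gives zero speeds and skips normalization", {
  tex <- translation_movie(0, n_frames = 6)
  still <- intensity_movie(array(tex[, , 1], c(dim(tex)[1:2], 6)), 0.3, 0.5)
  W <- dim(still)[1]
  expect_warning(
    prof <- track_retraction(still, rect_mask(W, c(0.3, 0.7), c(0.3, 0.7)),
                             cut_frame = 3),
    "normalization skipped")
  expect_true(all(prof$speed_um_s < 1e-9))
  expect_true(all(is.na(prof$speed_norm)))
  expect_false(attr(prof, "normalized"))
})

test_that("normalized profiles have unit median", {
  asp <- ablation_spec(response_mode = "global", seed = 5)
  ab <- generate_ablation_movie(asp)
  W <- dim(ab$movie)[1]
  prof <- track_retraction(ab$movie, rect_mask(W, c(0.38, 0.62),
                                               c(0.25, 0.45)),
                           asp$cut_frame)
  expect_equal(median(prof$speed_norm), 1)
  expect_true(all(prof$speed_um_s >= 0))
})

test_that("generator recoil peak and decay are recovered", {
  asp <- ablation_spec(response_mode = "global", seed = 5)
  ab <- generate_ablation_movie(asp)
  W <- dim(ab$movie)[1]
  prof <- track_retraction(ab$movie, rect_mask(W, c(0.38, 0.62),
                                               c(0.25, 0.45)),
                           asp$cut_frame, region_label = "central")
  expect_lt(abs(attr(prof, "max_speed_um_s") - asp$peak_speed) /
              asp$peak_speed, 0.10)
  expect_lt(abs(fit_decay_time(prof) - asp$decay_time) / asp$decay_time,
            0.20)
})

test_that("doubling the generator peak speed doubles the recovery", {
  mk <- function(v) {
    asp <- ablation_spec(response_mode = "global", peak_speed = v,
                         decay_time = 6, seed = 5)
    ab <- generate_ablation_movie(asp)
    W <- dim(ab$movie)[1]
    attr(track_retraction(ab$movie, rect_mask(W, c(0.38, 0.62),
                                              c(0.25, 0.45)),
                          asp$cut_frame), "max_speed_um_s")
  }
  r <- mk(1.2) / mk(0.6)
  expect_lt(abs(r - 2) / 2, 0.15)
})

test_that("local ablations stay local and global ones do not", {
  regions <- function(W) list(
    central = rect_mask(W, c(0.38, 0.62), c(0.25, 0.45)),
    distal = rect_mask(W, c(0.38, 0.62), c(0.72, 0.9)))
  for (mode in c("local", "global")) {
    asp <- ablation_spec(response_mode = mode, seed = 5)
    ab <- generate_ablation_movie(asp)
    rg <- regions(dim(ab$movie)[1])
    pc <- track_retraction(ab$movie, rg$central, asp$cut_frame,
                           region_label = "central")
    pd <- track_retraction(ab$movie, rg$distal, asp$cut_frame,
                           region_label = "distal")
    cmp <- compare_regions(list(central = pc, distal = pd))
    expect_true(cmp$responding[cmp$region == "central"])
    expect_equal(cmp$responding[cmp$region == "distal"], mode == "global")
  }
})

test_that("angle bins partition the stage axis with field boundaries", {
  p <- tibble::tibble(stage_angle = c(130, 140, 126, 139.9, 170, 3, 180),
                      max_speed = 1:7)
  bb <- bin_by_angle(p)
  expect_equal(bb$data$bin[1:4],
               c("[125,140)", "[140,155)", "[125,140)", "[125,140)"))
  expect_error(bin_by_angle(tibble::tibble(stage_angle = 0, max_speed = 1)),
               "0, 180")
  # every angle maps to exactly one bin
  withr::with_seed(6, a <- runif(100, 0.01, 180))
  bb2 <- bin_by_angle(tibble::tibble(stage_angle = a, max_speed = a))
  expect_equal(sum(bb2$summary$n), 100)
})

test_that("a global-mode critical stage dominates the binned cohort", {
  angles <- c(70, 100, 130, 130, 145, 160)
  modes <- ifelse(angles >= 125 & angles < 140, "global", "local")
  profs <- purrr::map2_dfr(angles, seq_along(angles), function(a, i) {
    asp <- ablation_spec(stage_angle = a, response_mode = modes[i],
                         seed = 100 + i)
    ab <- generate_ablation_movie(asp)
    W <- dim(ab$movie)[1]
    p <- track_retraction(ab$movie, rect_mask(W, c(0.38, 0.62),
                                              c(0.72, 0.9)),
                          asp$cut_frame, stage_angle = a,
                          region_label = "distal")
    tibble::tibble(stage_angle = a, max_speed = attr(p, "max_speed_um_s"))
  })
  bb <- bin_by_angle(profs)
  g <- glance(bb)
  expect_equal(g$top_bin, "[125,140)")
  expect_lt(g$anova_p, 0.05)
})
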