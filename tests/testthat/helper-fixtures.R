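# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small noisy sheet movie (default regime scaled down)
small_sheet <- function() fixture("small_sheet", function() {
  generate_sheet_movie(sheet_spec(n_cells = 40, n_frames = 10, seed = 5))
})

# small noise-free sheet
clean_sheet <- function() fixture("clean_sheet", function() {
  generate_sheet_movie(sheet_spec(n_cells = 40, n_frames = 3,
                                  noise_level = 0, seed = 5))
})

# sheet without ratchet at dt = 10 s for focus experiments
foci_sheet <- function() fixture("foci_sheet", function() {
  spec <- sheet_spec(n_cells = 30, n_frames = 120, frame_interval = 10,
                     ratchet_from = 25.4, ratchet_to = 25.4, seed = 41)
  truth <- build_sheet_truth(spec)
  movie <- render_sheet_movie(truth)
  list(spec = spec, truth = truth, movie = movie)
})

# map generator cell ids to measured tracks on generator labels
truth_tracked <- function(labels, n_cells) {
  list(labels = labels,
       cells = tibble::tibble(cell_id = seq_len(n_cells),
                              status = "complete"))
}

# match each truth cell to the segmented label covering most of it
match_seg_to_truth <- function(seg, truth_lab, n_cells) {
  vapply(seq_len(n_cells), function(i) {
    v <- seg[truth_lab == i]
    v <- v[v > 0]
    if (!length(v)) return(NA_integer_)
    as.integer(names(which.max(table(v))))
  }, integer(1))
}

# rigid-translation speckle movie for flow tests
translation_movie <- function(v_px, n_frames = 8, side = 150, seed = 3) {
  withr::with_seed(seed, {
    tex <- as.matrix(EBImage::gblur(matrix(runif(side^2), side), 2))
    tex <- 0.2 + 0.8 * (tex - min(tex)) / diff(range(tex))
    gx <- matrix(rep(seq_len(side), times = side), side)
    gy <- matrix(rep(seq_len(side), each = side), side)
    frames <- lapply(seq_len(n_frames) - 1, function(k) {
      matrix(epipulse:::bilinear_sample(tex, gx - k * v_px, gy), side)
    })
    intensity_movie(frames, pixel_size = 0.3, frame_interval = 0.5)
  })
}

rect_mask <- function(W, rows, cols) {
  m <- matrix(FALSE, W, W)
  m[(rows[1] * W):(rows[2] * W), (cols[1] * W):(cols[2] * W)] <- TRUE
  m
}

# Full-scale study conditions: 100 cells, dt = 5 s, 25 min, 50 mHz,
# ratchet 25.4 -> 15.3 um^2, default noise; segmented, tracked, measured,
# and matched back to truth ids.
default_pipeline <- function() fixture("default_pipeline", function() {
  spec <- sheet_spec(seed = 101)           # defaults ARE the conditions
  mv <- generate_sheet_movie(spec)
  trk <- track_labels(segment_movie(mv$membrane))
  meas <- measure_areas(trk)
  map <- match_seg_to_truth(movie_frame(trk$labels, 1),
                            movie_frame(mv$labels, 1), spec$n_cells)
  list(spec = spec, movie = mv, tracked = trk, meas = meas, map = map)
})

# noise-free render of the same regime, shorter
clean_big <- function() fixture("clean_big", function() {
  spec <- sheet_spec(n_frames = 12, noise_level = 0, seed = 101)
  mv <- generate_sheet_movie(spec)
  trk <- track_labels(segment_movie(mv$membrane))
  map <- match_seg_to_truth(movie_frame(trk$labels, 1),
                            movie_frame(mv$labels, 1), spec$n_cells)
  list(spec = spec, movie = mv, tracked = trk, map = map)
})
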