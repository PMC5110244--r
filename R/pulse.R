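#' First time-derivative of an area series (constriction rate)
#'
#' Central finite differences in the interior, one-sided at the ends,
#' scaled to um^2/min (`x 60 / frame_interval`). Linear in its input:
#' `area_rate(a*x + b*y) = a*area_rate(x) + b*area_rate(y)`.
#'
#' @param x Numeric vector of areas (um^2), or a tracks data frame with
#'   `cell_id` and `area_um2` columns.
#' @param frame_interval Seconds between samples.
#' @param ... Unused.
#' @return For numeric input, a numeric vector of rates (um^2/min); for a
#'   data frame, the same frame with a `rate_um2_min` column added per
#'   cell.
#' @examples
#' area_rate(c(1, 2, 3, 4), frame_interval = 10)  # 6 um^2/min throughout
#' @export
area_rate <- function(x, ...) UseMethod("area_rate")

#' @rdname area_rate
#' @export
area_rate.numeric <- function(x, frame_interval, ...) {
  n <- length(x)
  if (n < 3) abort("need at least 3 samples for a derivative")
  check_positive(frame_interval, "frame_interval")
  d <- numeric(n)
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d * 60 / frame_interval
}

#' @rdname area_rate
#' @export
area_rate.data.frame <- function(x, frame_interval, ...) {
  stopifnot(all(c("cell_id", "area_um2") %in% names(x)))
  x |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(rate_um2_min =
                    area_rate(.data$area_um2, frame_interval)) |>
    dplyr::ungroup()
}

# Alternating extrema of a series, filtered by prominence (height above
# the higher of the two flanking minima, and conversely for minima).
find_extrema <- function(x, prominence) {
  n <- length(x)
  dx <- diff(x)
  s <- sign(dx)
  # collapse flats
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  idx <- which(diff(s) != 0) + 1L
  if (!length(idx)) return(tibble::tibble(index = integer(),
                                          type = character()))
  type <- ifelse(s[idx - 1] > 0, "max", "min")
  keep <- logical(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    lo <- if (k == 1) 1L else idx[k - 1]
    hi <- if (k == length(idx)) n else idx[k + 1]
    p <- if (type[k] == "max") {
      x[i] - max(min(x[lo:i]), min(x[i:hi]))
    } else {
      min(max(x[lo:i]), max(x[i:hi])) - x[i]
    }
    keep[k] <- p >= prominence
  }
  tibble::tibble(index = idx[keep], type = type[keep])
}

# Moving-average detrend with edge-shortened windows.
detrend_ma <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2 == 0) k <- k + 1L
  n <- length(x)
  half <- k %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  x - (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Periodogram via FFT of the (already detrended) series; returns
# frequencies in mHz and power.
periodogram_mHz <- function(x, dt) {
  n <- length(x)
  P <- Mod(fft(x - mean(x)))^2 / n
  nf <- n %/% 2
  tibble::tibble(freq_mHz = (seq_len(nf)) / (n * dt) * 1000,
                 power = P[2:(nf + 1)])
}

#' Oscillation and constriction statistics of an area series
#'
#' Computes, per cell: the dominant frequency of the detrended series
#' (periodogram peak within a physiological band, flagged `NA` when no
#' peak stands out of the background), the mean peak-to-peak amplitude of
#' the constriction-rate series over consecutive prominent extremum pairs,
#' the net relative area change over the analysis window, and the
#' ratchet classification (`constricting` / `relaxing` when the net change
#' exceeds the threshold over the window, else `stable`).
#'
#' @param x Numeric area series (um^2), or a tracks data frame with
#'   `cell_id` and `area_um2`.
#' @param frame_interval Seconds between samples.
#' @param window_s Analysis window for the net change, seconds (default
#'   25 min). Windows longer than the series are truncated.
#' @param change_threshold_pct Net-change threshold (percent) of the
#'   classification rule.
#' @param detrend_window_s Moving-average window used to separate the slow
#'   ratchet from the fast pulses before spectral analysis, seconds.
#' @param band_mHz Frequency band searched for the dominant peak.
#' @param peak_snr Required ratio of peak power to the median in-band
#'   power; below it the frequency is reported as `NA` (undefined), never
#'   as zero.
#' @param prominence_k Extremum prominence threshold in units of the rate
#'   series' standard deviation.
#' @param freq_method `"periodogram"` (default) or `"peaks"` (median
#'   reciprocal spacing of successive rate maxima).
#' @param edge_window_s Averaging window at both ends of the analysis
#'   window used for the net-change endpoints, seconds.
#' @param ... Unused.
#' @return A one-row tibble (`dominant_freq_mHz`,
#'   `peak_to_peak_um2_min`, `net_change_pct`, `classification`,
#'   `n_extrema`), or one row per cell for data-frame input.
#' @export
pulse_stats <- function(x, ...) UseMethod("pulse_stats")

#' @rdname pulse_stats
#' @export
pulse_stats.numeric <- function(x, frame_interval, window_s = 1500,
                                change_threshold_pct = 20,
                                detrend_window_s = 60,
                                band_mHz = c(10, 200), peak_snr = 5,
                                prominence_k = 0.5,
                                freq_method = c("periodogram", "peaks"),
                                edge_window_s = 60, ...) {
  freq_method <- match.arg(freq_method)
  check_positive(frame_interval, "frame_interval")
  n <- length(x)
  if (n < 3) abort("series too short")
  dur <- (n - 1) * frame_interval
  if (window_s > dur + frame_interval / 2) window_s <- dur

  # net change on window-end means
  nwin <- min(n, max(1L, round(window_s / frame_interval) + 1L))
  xx <- x[seq_len(nwin)]
  ke <- max(1L, min(round(edge_window_s / frame_interval), nwin %/% 3))
  a_start <- mean(xx[seq_len(ke)])
  a_end <- mean(xx[(nwin - ke + 1):nwin])
  net <- 100 * (a_end - a_start) / a_start
  cls <- if (net <= -change_threshold_pct) "constricting"
         else if (net >= change_threshold_pct) "relaxing" else "stable"

  rate <- area_rate(x, frame_interval)
  det <- detrend_ma(x, detrend_window_s / frame_interval)
  # drop the edge-shortened detrend windows, which leave trend residue
  halfk <- ceiling(detrend_window_s / frame_interval / 2)
  if (n - 2 * halfk >= 16) det <- det[(halfk + 1):(n - halfk)]
  freq <- NA_real_
  if (sd(det) > 1e-12 && n >= 8) {
    pg <- periodogram_mHz(det, frame_interval)
    pg <- pg[pg$freq_mHz >= band_mHz[1] & pg$freq_mHz <= band_mHz[2], ]
    if (nrow(pg) >= 3) {
      pk <- which.max(pg$power)
      if (pg$power[pk] >= peak_snr * median(pg$power)) {
        freq <- pg$freq_mHz[pk]
      }
    }
    if (freq_method == "peaks") {
      ex <- find_extrema(rate, prominence_k * sd(rate))
      mx <- ex$index[ex$type == "max"]
      if (length(mx) >= 2) {
        freq <- 1000 / (median(diff(mx)) * frame_interval)
      } else freq <- NA_real_
    }
  }

  ex <- find_extrema(rate, prominence_k * sd(rate))
  pp <- NA_real_
  if (nrow(ex) >= 2) {
    vals <- rate[ex$index]
    pairs <- abs(diff(vals))         # consecutive (max, min) excursions
    pp <- mean(pairs)
  }
  tibble::tibble(dominant_freq_mHz = freq, peak_to_peak_um2_min = pp,
                 net_change_pct = net, classification = cls,
                 n_extrema = nrow(ex))
}

#' @rdname pulse_stats
#' @export
pulse_stats.data.frame <- function(x, frame_interval, ...) {
  stopifnot(all(c("cell_id", "area_um2") %in% names(x)))
  dots <- list(...)
  x |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      do.call(pulse_stats, c(list(d$area_um2, frame_interval), dots))
    }) |>
    dplyr::ungroup()
}

#' Pairwise synchrony of neighbouring oscillators
#'
#' Pearson correlation between the constriction-rate series of every
#' neighbouring cell pair; a pair is called synchronous when
#' `|R| >= r_thresh` (default 0.5), and the fraction of asynchronous
#' pairs is reported. Correlating rates rather than raw areas removes the
#' shared ratchet trend that would otherwise inflate R (`on = "area"`
#' switches to raw areas).
#'
#' @param tracks Tidy tracks (`cell_id`, `frame`, `area_um2`).
#' @param neighbors Neighbour edge list (`frame`, `cell_a`, `cell_b`), as
#'   from [measure_areas()]; pairs are evaluated if they are neighbours in
#'   at least half the frames.
#' @param frame_interval Seconds between frames.
#' @param on `"rate"` or `"area"`.
#' @param r_thresh Synchrony threshold on `|R|`.
#' @return A tibble (`cell_a`, `cell_b`, `r`, `synchronous`) with
#'   attribute `fraction_asynchronous`; retrieve it with
#'   `attr(, "fraction_asynchronous")`.
#' @export
neighbor_sync <- function(tracks, neighbors, frame_interval,
                          on = c("rate", "area"), r_thresh = 0.5) {
  on <- match.arg(on)
  nfr <- length(unique(tracks$frame))
  pairs <- neighbors |>
    dplyr::count(.data$cell_a, .data$cell_b) |>
    dplyr::filter(.data$n >= nfr / 2) |>
    dplyr::select("cell_a", "cell_b")
  wide <- tracks |>
    dplyr::select("cell_id", "frame", "area_um2") |>
    tidyr::pivot_wider(names_from = "cell_id", values_from = "area_um2")
  series <- function(id) wide[[as.character(id)]]
  res <- purrr::pmap_dfr(pairs, function(cell_a, cell_b) {
    a <- series(cell_a); b <- series(cell_b)
    if (is.null(a) || is.null(b)) return(NULL)
    ok <- complete.cases(a, b)
    if (sum(ok) < 3) return(NULL)
    a <- a[ok]; b <- b[ok]
    if (on == "rate") {
      a <- area_rate(a, frame_interval)
      b <- area_rate(b, frame_interval)
    }
    if (sd(a) < 1e-12 || sd(b) < 1e-12) {
      warn(sprintf("pair (%d, %d): zero variance, excluded",
                   cell_a, cell_b))
      return(NULL)
    }
    tibble::tibble(cell_a = cell_a, cell_b = cell_b, r = cor(a, b),
                   synchronous = abs(cor(a, b)) >= r_thresh)
  })
  attr(res, "fraction_asynchronous") <-
    if (nrow(res)) mean(!res$synchronous) else NA_real_
  res
}

#' Relative variation of the distance between two tracked points
#'
#' Tracks the Euclidean distance between two point series (e.g. the two
#' cells flanking a rounded mitotic cell) and reports its percent
#' variation relative to the first frame.
#'
#' @param a,b Two-column matrices (x, y in px), one row per frame.
#' @param pixel_size Micrometres per pixel.
#' @return A tibble (`frame` 0-based, `distance_um`, `variation_pct`)
#'   with attributes `max_variation_pct` and `final_variation_pct`.
#' @export
edge_distance_variation <- function(a, b, pixel_size = 1) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 2, ncol(b) == 2, nrow(a) == nrow(b))
  check_positive(pixel_size, "pixel_size")
  d <- sqrt(rowSums((a - b)^2)) * pixel_size
  if (d[1] <= .Machine$double.eps) abort("initial distance is zero")
  v <- 100 * (d - d[1]) / d[1]
  out <- tibble::tibble(frame = seq_along(d) - 1L, distance_um = d,
                        variation_pct = v)
  attr(out, "max_variation_pct") <- max(v)
  attr(out, "final_variation_pct") <- v[length(v)]
  out
}
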