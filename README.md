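# epipulse

Quantitative analysis of pulsatile, ratcheted constriction in epithelial
time-lapse movies, built around the cell behaviours that drive optic cup
folding in the zebrafish retina: basal cell surfaces oscillate at
~50 mHz, constrict progressively from ~25.4 to ~15.3 µm², couple
cortical actin accumulation to area expansion, condense transient
myosin-like cortical foci that locally contract single cells, and
release tension tissue-wide only in a narrow developmental window after
laser ablation.

The package is for developmental and mechanobiologists who have
segmented (or segmentable) membrane-channel movies and want the standard
quantitative readouts of pulsatile constriction without ad hoc scripts.

## What it computes

For per-cell area series $A_i(t)$ (µm²) with frame interval $\Delta t$:

- constriction rate $\dot A_i(t)$ (first derivative, µm²/min), dominant
  frequency (detrended periodogram, 10–200 mHz), mean peak-to-peak rate
  amplitude over prominent extremum pairs, net change over a 25-min
  window and the ±20% constricting/relaxing/stable classification;
- neighbour synchrony: Pearson $R$ between rate series, asynchronous if
  $|R| < 0.5$;
- cortical-intensity/area coupling: the cross-correlation
  $(f \star g)[n] = \mathcal{F}^{-1}\{\mathcal{F}\{f\}^{*}\cdot\mathcal{F}\{g\}\}$
  of the normalized rate series, scaled by the zero-lag
  autocorrelations so coefficients lie in $[-1, 1]$; per-cell maxima
  within ±2 frames of lag 0, against permutation and sinusoidal
  surrogate nulls, plus the coefficient-vs-intensity regression;
- cortical focus events: robust (median + 3·MAD) detection in a
  cortical band, centroid linking, lifetimes, apico-basal indentation
  at a focus, and host-vs-neighbour contraction tests;
- post-ablation recoil: Shi–Tomasi features tracked by pyramidal
  Lucas–Kanade, median speed of 11 points, Gaussian-smoothed and
  median-normalized retraction profiles, maximum retraction speeds
  binned into 15° opening-angle stages with ANOVA/Dunnett reports;
- organ-scale geometry: opening angles, apical/basal contour lengths,
  tissue width.

A seeded synthetic-movie generator (`sheet_spec()`,
`generate_sheet_movie()`, `generate_actin_channel()`,
`generate_foci_channel()`, `generate_ablation_movie()`) produces
ground-truthed movies in exactly these regimes; every analysis above is
validated against it.

## Worked example

```r
library(epipulse)

spec <- sheet_spec(n_cells = 40, n_frames = 120, seed = 5)
mv <- generate_sheet_movie(spec)          # membrane + labels + truth

trk  <- track_labels(segment_movie(mv$membrane))
meas <- measure_areas(trk)
ok   <- trk$cells$cell_id[trk$cells$status == "complete"]

stats <- pulse_stats(meas$tracks[meas$tracks$cell_id %in% ok, ],
                     frame_interval = 5)
dplyr::summarise(stats,
  freq = median(dominant_freq_mHz, na.rm = TRUE),
  pp   = mean(peak_to_peak_um2_min, na.rm = TRUE),
  net  = median(net_change_pct))
#> # A tibble: 1 × 3
#>    freq    pp   net
#>   <dbl> <dbl> <dbl>
#> 1    50  12.0 -36.3
```

The recovered dominant frequency is the generator's 50 mHz; the mean
peak-to-peak rate amplitude of ~12 µm²/min sits in the measured basal
regime (~11 µm²/min, plus a little measurement noise); and the median
net area change of −36% reflects the 25.4 → 15.3 µm² linear ratchet
over this 10-minute movie (the window-mean endpoints sit slightly
inside the full −40% decline), a `constricting` call for essentially
every cell.

Coupling analysis on the same sheet:

```r
tr <- mv$truth
ac <- generate_actin_channel(tr, rho = 0.4, seed = 21)
dat <- truth_tracks(tr)
dat$intensity <- as.vector(ac$intensity_au)
ca <- coupling_analysis(dat, frame_interval = 5, n_surrogates = 200,
                        seed = 31)
glance(ca)[, c("mean_coef", "median_coef", "null_mean_zero_lag", "p_value")]
#> # A tibble: 1 × 4
#>   mean_coef median_coef null_mean_zero_lag  p_value
#>       <dbl>       <dbl>              <dbl>    <dbl>
#> 1     0.410       0.420           0.000318 8.90e-27
```

An imposed coupling of 0.4 is recovered as a mean per-cell maximum
coefficient of ~0.41 (median ~0.42) against a surrogate null centred on
zero.

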