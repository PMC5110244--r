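---
title: "Quantifying pulsatile basal constriction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pulsatile basal constriction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

epipulse analyses time-lapse movies of epithelial sheets whose cells
constrict in a pulsatile, ratcheted fashion — the regime seen at the basal
surface of the zebrafish retinal neuroepithelium while the optic cup
folds. This vignette explains the models behind each analysis stage, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the underlying
procedures left them open.

## The measurement model

A movie is a calibrated array `[row, col, frame]` with a pixel size
(µm/px) and a frame interval (s). The analysis chain is:

1. **Segmentation** — each membrane-channel frame is smoothed (Gaussian,
   σ = 1 px), inverted, and flooded with a watershed whose tolerance
   plays the role of an h-minima depth (default 10% of the dynamic
   range). Membrane-bright pixels (≥ 50% of the dynamic range of the
   unsmoothed frame) are labelled 0, so a cell's area is its
   membrane-excluded interior. Basins touching the image border that are
   more than 3× the median region size are background, not cells.
2. **Tracking** — frame-to-frame correspondence by maximal
   intersection-over-union (IoU) of region masks. A match requires
   IoU ≥ 0.5, which guarantees uniqueness; ties are broken by larger
   intersection, then lower label, so tracking is deterministic and
   invariant to per-frame label permutations. Tracks touching the image
   border, missing in a frame, or involved in weak/split/merged matches
   are `ambiguous`; only `complete` tracks enter downstream statistics.
3. **Per-cell series** — area = pixel count × pixel_size², centroids,
   and a per-frame neighbour graph (cells whose interiors face each other
   across the membrane with at least `min_contact` = 3 px of shared
   boundary).

## Oscillation and ratchet statistics

The constriction rate is the first time-derivative of area (central
differences, one-sided at the ends), reported in µm²/min.

- **Dominant frequency**: periodogram peak of the detrended area series
  within 10–200 mHz. Detrending subtracts a 60-s moving average, which
  separates the slow ratchet from the fast pulses; half a detrend window
  is trimmed from each end before the FFT because the edge-shortened
  averages leave trend residue that would otherwise fake a low-frequency
  peak. A peak must exceed 5× the median in-band power, otherwise the
  frequency is *undefined* (`NA`), never zero.
- **Peak-to-peak amplitude**: mean absolute difference between
  consecutive prominent extrema of the rate series. Extrema alternate
  maxima/minima and must clear a prominence of 0.5× the rate SD — the
  reference workflow never states its peak criterion, so a
  scale-free prominence was chosen and is configurable.
- **Net change and classification**: percent change between window-mean
  areas at the start and end of a 25-min window (60-s edge means), with
  the ±20% rule: `constricting` ≤ −20%, `relaxing` ≥ +20%, otherwise
  `stable`.
- **Neighbour synchrony**: Pearson R between rate series of neighbouring
  cells; a pair is asynchronous when |R| < 0.5. Rates rather than raw
  areas are correlated because the shared ratchet trend would inflate R
  between any two constricting cells; `on = "area"` switches back.

## Cross-correlation with surrogate nulls

The coupling statistic between a cortical-intensity series and an area
series is built from the FFT cross-correlation
`(f ⋆ g)[n] = IFFT(conj(FFT(f)) · FFT(g))` of the mean-subtracted,
zero-padded signals, normalized by the zero-lag autocorrelations so that
coefficients live in [−1, 1] (the Pearson-at-lag form; the normalization
is stated as an idea, not a formula, in the source workflow). Both
series are differentiated and normalized by their mean absolute value
first. The reported per-cell coefficient is the maximum within ±2 frames
of lag zero, because coupling is only interpreted up to the sampling
limit (~5 s). No overlap correction is applied at finite lags (the
biased estimator); lags are restricted to near zero, where the bias is
negligible.

Significance comes from surrogates: seeded permutations (amplitude
distribution preserved, temporal order destroyed) or variance- and
frequency-matched sinusoids with random phase ("similar statistical
properties" is not further specified in the source, so both frequency
and variance are matched). Because the observed statistic is a maximum
over 5 lags, its null distribution has a small positive mean of order
`sqrt(2 log 5 / N)`; the same maximum is therefore taken on every
surrogate, which makes the empirical p-values exact, and the unbiased
zero-lag surrogate mean is reported separately as the null-calibration
summary.

## Focus detection and focus-coupled contraction

Cortical foci are connected components, within a 3-px cortical band
inside each cell mask, brighter than median + 3×MAD of the band (a
robust threshold; the source states no absolute criterion). Components
with fewer than 4 px are dropped; of components closer than `r_max`
(6 px) only the brightest survives, since a focus bleeding across a
membrane would otherwise appear in the neighbour's band too. Detections
are linked by nearest centroid within `r_max`, tolerating one missing
frame; an event ends when its host cell changes. Lifetime is
`(end − start + 1) × dt / 60` minutes.

Apico-basal indentation is measured on an edge-profile view: the basal
membrane's position along a line through the focus is the first
suprathreshold crossing (sub-pixel by linear interpolation), and
shortening is the drop relative to a 5-frame pre-onset baseline. The
measure is flagged unreliable if the edge is undetectable in over 20% of
frames. Focus-coupled contraction compares the host cell's area change
at the intensity peak (baseline: 5 pre-onset frames) with the mean
change of its tracked neighbours, by paired t-test.

## Post-ablation flow

Tissue recoil is quantified by sparse optical flow: Shi–Tomasi corners
(minimum eigenvalue of the structure tensor; quality 0.01, minimum
distance 10 px) selected in a region at the cut frame, tracked by
pyramidal Lucas–Kanade (21-px window, 3 levels, 10 iterations/level —
none of these are fixed by the source workflow, and all are arguments).
The per-frame speed is the median over the 11 tracked points of
|displacement| × pixel_size / dt. Points are tracked through the entire
movie so the pre-cut frames yield a measured jitter floor; profiles are
Gaussian-smoothed (σ = 2 frames) with the pre- and post-cut segments
smoothed separately — smoothing across the cut would average the recoil
peak with still frames and bias it low by tens of percent — and then
normalized by the profile median (smoothing before normalization; the
order is unstated in the source and documented here as a choice). The
maximum retraction speed is the post-cut maximum of the smoothed
profile.

Stage binning sorts ablated tissues into half-open 15° bins of the
opening angle anchored at the conventional stage boundaries
(…, 110–125, 125–140, 140–155, …), summarises per-bin maxima, and
reports a one-way ANOVA with Dunnett contrasts against the least-folded
populated bin. A region "responds" when its maximum smoothed speed
exceeds 3× its own pre-cut noise floor (mean + 2 SD of measured pre-cut
speeds).

## The synthetic-data generator

No raw live-imaging data accompany the reference measurements, so the
generator produces ground-truthed movies with the statistical structure
the analyses assume; its defaults are the measured regimes themselves.

- **Geometry**: Lloyd-relaxed random seed points in a disk approximate
  epithelial packing without a mechanical model. Cells are rendered as an
  additively weighted power diagram on the pixel grid; per frame, a
  Newton iteration on a boundary-length-weighted graph Laplacian solves
  the site weights so each cell's rendered membrane-excluded pixel count
  matches its true area (typically to well under 2%). The tissue-scale
  ratchet scales the seed constellation toward the centre.
- **Dynamics**: `A_i(t) = B_i · ρ(t) · (1 + a sin(2π f t + φ_i))` with a
  linear ratchet ρ(t) from 25.4 to 15.3 µm² across the movie
  ("progressive" is all the source states, so linear is the simplest
  faithful shape), f = 50 mHz, independent uniform phases, and base
  areas B_i with 7% CV. The default amplitude a = 0.023 makes the
  *measured* peak-to-peak rate amplitude ≈ 11 µm²/min at dt = 5 s: the
  first-difference derivative at 4 samples per cycle attenuates a
  sinusoid by sin(ω dt)/(ω dt) ≈ 0.64, and the reference rates were
  computed the same way, so the generator matches the measured, not the
  idealized, amplitude.
- **Rendering**: membrane outlines drawn at the label boundaries, a
  Gaussian PSF of σ = 0.8 px (a confocal lateral PSF at the 0.3 µm/px
  default calibration; the source never states its pixel size), Poisson
  photon noise with peak SNR 1/noise_level (default 10) plus Gaussian
  read noise.
- **Cortical intensity**: per-cell intensity whose rate is
  `ρ·z + sqrt(1−ρ²)·ε` against the standardized area rate, cumulated
  around a positive baseline (default ρ = 0.4, the measured coupling
  regime). With unit noise the rate-rate correlation equals ρ exactly.
- **Foci**: Poisson event counts per cell (default 2 events/cell/h — the
  source reports scattered, sparse foci but no rate, so a rate giving a
  handful of concurrent foci per field was fixed once), truncated-normal
  lifetimes (σ = 25% of mean, floor 2 frames) around 4 min (21.5 min
  emulates the myosin-stabilized condition), trapezoidal intensity
  profiles (condensation and dispersal take about a frame, so visible
  span tracks lifetime), a persistent (ratcheted) area step of 3 µm²
  completed by mid-event, and 2.3-µm basal indentations rendered in a
  separate edge-profile movie. Onsets are drawn so events complete
  within the movie: the reference lifetime measurements are of fully
  observed foci, and censored events would bias recovery tests.
- **Ablation**: filtered-noise speckle, recoil speed
  `v(t) = peak · exp(−t/τ)` (defaults 0.8 µm/s, τ = 10 s — the source
  plots normalized speeds only, so absolute values are realistic recoil
  magnitudes fixed once), radial displacement with `exp(−d/decay_radius)`
  attenuation in `local` mode (12 µm default) and none in `global` mode,
  which emulates the tissue-wide relaxation of the 125–140° stage.

What the generator does **not** emulate: z-drift and focal-plane loss,
mitotic rounding and divisions, uneven illumination, membrane-intensity
heterogeneity along a junction, cell rearrangements (T1 transitions),
and mechanical coupling between neighbours beyond area exchange. Tests
passing on this generator therefore validate the estimators under the
stated statistical regime, not segmentation robustness on hard real
data; on real movies the ambiguous-track fraction will be higher and
manual curation may still be needed.

## Problem sizes and degenerate inputs

The validation suite runs the full pipeline at the study scale — 100
cells, 300 frames at 5 s (25 min), with segmentation and tracking of
every frame — and scaled-down variants elsewhere (26 cells for coupling,
30 cells at 10 s for foci, 6-movie ablation cohorts); these sizes keep a
complete run in the minutes range on a single core while leaving every
statistical check well-powered.

Degenerate inputs are first-class: constant images refuse to segment,
constant series report undefined (not zero) frequency, zero-variance
pairs are excluded from synchrony with a warning, static recoil movies
skip median normalization with a flag, and all-zero rate series refuse
normalization.

## Known limitations

- The tracker has no lineage model: divisions end tracks (ambiguous), as
  intended for constriction statistics but unsuitable for lineage work.
- Focus events that drift across a cell boundary are terminated at the
  host change; how the reference measurements handled drifting foci is
  unstated.
- The per-cell coupling regression against mean intensity rate is only
  informative when coupling genuinely varies between cells; on generator
  data with a single ρ its slope is near zero by construction.
- Whether the reference synchrony thresholded areas or rates is
  unstated; rates are the default here for the reason above, and the
  choice is exposed.
- Synchrony fractions are estimator-dependent: white measurement noise
  attenuates every pairwise |R|, so the asynchronous fraction measured
  from a noisy movie is an upper bound on the fraction in the underlying
  dynamics. On generator data with one shared frequency and independent
  phases the true rate correlation behaves like cos(Δφ) (a third of
  pairs synchronous by chance); under the default rendering noise the
  measured asynchronous fraction rises substantially above that. Any
  comparison across conditions should therefore hold imaging noise
  constant.
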