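---
title: "Methods: rhythm quantification in circaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm quantification in circaquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaquant)
```

# Scope

`circaquant` quantifies circadian rhythmicity in four record types:
per-pixel bioluminescence movies of SCN explants, single luminescence
traces, locomotor actograms, and cycloheximide-chase protein decay
courses. This vignette documents the statistical models, the default
parameters and why they were chosen, the synthetic-data generator that
underwrites the test suite, and the numerical decisions that were
genuinely open.

# The chi-squared periodogram

For a uniformly sampled series $x_1,\dots,x_n$ ($\Delta t$ hours per
sample) and a trial period of $P$ samples, the record is folded into
$K = \lfloor n/P \rfloor$ complete cycles ($N = KP$ points used) and

$$Q_P \;=\; \frac{N\,K \sum_{h=1}^{P} (M_h - \bar M)^2}
                 {\sum_{i=1}^{N} (x_i - \bar M)^2},$$

where $M_h$ is the mean of the $K$ samples at fold position $h$ and
$\bar M$ the grand mean. Under the no-rhythm null, $Q_P$ is referred to
$\chi^2_{P-1}$. The search grid is specified in hours (default 20–28 h
in 0.1-h steps, both configurable); because folding requires a whole
number of samples, each grid point maps to $P = \mathrm{round}(p/\Delta
t)$ and the *achieved* period $P\,\Delta t$ is reported once per
distinct fold length. At a 55-min frame interval the achieved-period
resolution is therefore about 0.9 h; at 10-min actogram bins it is
10 min.

**Assumptions.** Uniform sampling without gaps; approximately stationary
noise after detrending. The $\chi^2$ reference distribution assumes
independent errors — which is why the pipeline does *not* smooth before
the periodogram (below).

## Familywise control of the rhythmicity call

A series is called rhythmic when *any* trial period is significant at
`alpha` (default 0.10, which is also the plotting threshold for pixel
maps). Scanning ~10–50 distinct fold lengths at a per-period 10% level
would flag the majority of pure-noise series, so the call and the
best-period selection use Bonferroni-adjusted p-values across the
distinct fold lengths. Monte-Carlo checks in the test suite confirm the
resulting false-positive rate stays at or below `alpha` on white noise,
which in turn is what makes oscillating-pixel percentages comparable
across genotypes. Raw per-period p-values are reported alongside for
periodogram plots. No correction is applied *across pixels*; the
oscillating fraction is a per-pixel descriptive statistic, not a
discovery set.

## Preprocessing order

The per-pixel pipeline is detrend → (optional normalize) → periodogram →
cosinor. Pre-smoothing is available (`smooth_window_h`, off by default;
`moving_average()` defaults to a 3-sample window ≈ 2.75 h at the 55-min
cadence when used for display or extrema detection) but is deliberately
not part of the default analysis path: a moving-average filter
autocorrelates the noise, which inflates the tail of $Q_P$ and raises
the false-positive rate of the scan several-fold even after Bonferroni
control. Detrending, by contrast, barely perturbs the null because the
subtracted baseline is nearly orthogonal to the 20–28 h band.

Normalization (z-score by default) has no effect on $Q_P$ (affine
invariance) or on acrophase; it matters only for cross-pixel display
and is skipped automatically for zero-variance series.

## Detrending

`detrend()` subtracts a centered moving-average baseline whose window
defaults to one circadian cycle (24 h). A window of exactly one period
has zero gain at that period, so the rhythm passes through unchanged
while baseline drift and the damping envelope are removed. When the
window corresponds to an even number of samples the two end samples get
half weight (the classical centered seasonal baseline); this keeps the
effective span exactly at the window length, which matters: a
nearest-odd 25-sample window at $\Delta t = 1$ h leaks ~4% of a 24-h
cosine back into the residual, while the half-weight 24-sample window
nulls it exactly. At the record edges the window shrinks symmetrically
rather than padding — no data are fabricated, at the cost of a less
accurate baseline in the first and last half-window.

# Cosinor estimation

`cosinor_fit()` fits $M + A\cos(2\pi (t-\phi)/P)$ at a fixed period by
the standard linearization, so the estimate is exact on noiseless
cosines and efficient under Gaussian noise. The acrophase convention is
**hours after the start of the record** at which the fitted cosine
peaks, in $[0, P)$; for actograms recorded against a clock,
`daily_acrophase()` adds the record's start clock time so LD acrophases
read as hours after midnight. Whether slice acrophases should instead be
projected onto zeitgeber time is unknowable from a free-running ex vivo
record, so the recording-start convention is used consistently; only
phase *differences* are interpreted.

## Acrophase maps at a common period

Phase differences are only defined on a shared cycle, so the relative
acrophase map fixes one common period — the mean best period over
oscillating pixels — for every pixel *and* for the mask-averaged
reference signal, then stores each pixel's circular difference from the
reference in $(-P/2, P/2]$. Period maps, by contrast, carry each
pixel's own best period. Pixels with no significant period still get an
acrophase (the map stays defined everywhere in the mask) but are
excluded from oscillating-fraction counts and distribution summaries.

## Period refinement

Because the periodogram's achieved periods are quantized to whole frame
intervals (~0.9 h at 55 min/frame), per-pixel period maps would carry a
large quantization error relative to the biological spread (~0.2–0.5 h
between cells). `analysis_config(refine_period = TRUE)` (the default)
therefore refines each oscillating pixel's estimate by least-squares
sinusoid fit over the fine hour grid within one frame interval of its
best fold period. Detection remains purely periodogram-based; the
refinement only sharpens the reported period. With refinement, per-pixel
period estimates on synthetic movies correlate with ground truth at
r > 0.9 under 20% amplitude noise (see `test-imaging.R`).

# Desynchrony

`desynchrony_course()` slides a one-cycle window (24 h default, 6-h
steps) along the movie, fits windowed cosinor phases for the oscillating
pixels at the common period, and reports the Kuramoto order parameter
$R = |\,\mathrm{mean}(e^{i\theta})\,| \in [0,1]$. $R \approx 1$ means
the cellular oscillators peak together; independent random phases give
$R \sim 1/\sqrt{n}$. On uncoupled phase-diffusing synthetic movies $R$
declines toward that floor and tracks the order parameter computed
directly from the generator's stored phase trajectories.

# Actogram statistics

`free_running_period()` runs the periodogram (20–28 h, 0.01-h grid) on
a DD segment of at least 7 days and returns the best significant
achieved period, or `NA` with no significant period — an explicit
no-period result rather than a guess. The estimate is invariant to
rescaling counts. `mean_daily_profile()` folds the record modulo 24 h
and conserves counts exactly. Activity onset/offset detection is not
offered as a supported statistic: phase is quantified via acrophase,
which is robust to the shape of the activity bout. Re-entrainment-day
counting and "splitting" decomposition are out of scope (no algorithmic
definition exists to implement).

`metabolic_phase_delay()` is the cosinor acrophase difference at a fixed
24-h period between two simultaneously recorded physiological rhythms,
wrapped to $(-12, 12]$ with positive = delay. Each input is screened by
periodogram (search capped at half the record span, so a two-day record
is screened over 20–24 h); a non-rhythmic input downgrades the result to
a flagged best-effort estimate instead of an error.

# Decay kinetics

Chase courses are normalized per replicate to their own $t = 0$ level
(each experiment's blot is its own reference), then fitted by log-linear
least squares, $\log y = -kt + c$; half-life $= \ln 2 / k$, infinite
when $k \le 0$. With only three chase timepoints (0/3/6 h) a nonlinear
exponential fit adds fragility without information, and the log-linear
fit is exact for clean first-order decay. Per-timepoint genotype
comparisons use Student's t-test on the normalized levels at each
post-zero timepoint ($t=0$ is identically 1 and carries no
information).

# The synthetic-data generator

The generator's job is to reproduce the statistical structure of the
recordings so each analysis stage can be validated by parameter
recovery.

**Cellular traces / movies.** Each rhythmic pixel is a damped cosine
with additive Gaussian noise:
$b + st + A e^{-\lambda t}\cos(2\pi(t - \phi + D_t)/\tau)$, where $D_t$
is a Gaussian random walk (one step per frame) producing gradual
desynchronization, optionally opposed by mean-field coupling of strength
$K$ toward the population's circular-mean phase. Defaults (chosen once
as the emulated recording): 60 × 60 frame, two-lobed elliptical mask
(~1530 px), 55-min frames for 5 days (131 frames), period
24 ± 0.2 h, initial phase SD 0.5 h, amplitude 100 on baseline 200 with
noise SD 5 (high signal-to-noise), slow downward trend −0.2 units/h,
damping 0.005/h, diffusion 0.05 h/frame, 4.1% arrhythmic pixels
(wild-type-like); knockout-like runs widen period SD to 0.4 h, phase SD
to 2 h, diffusion to 0.2 h/frame and raise the arrhythmic fraction to
16.7%. The arrhythmic count is rounded to whole pixels so the ground
truth fraction is exact. The per-pixel phase trajectories, periods,
acrophases and the rhythmic mask are returned as ground truth.

**What it does not emulate:** photon shot noise (noise is Gaussian, not
Poisson — variance does not scale with intensity), spatial coupling
kernels (coupling is mean-field only, sufficient as a wild-type-like
contrast), optical blur/bleed between pixels, movement artifacts, and
cell bodies as segmentable objects (analysis is per-pixel, as is the
quantification it validates). Passing recovery tests therefore shows
the estimators are correct under these noise models, not that real
recordings meet their assumptions.

**Actograms.** Poisson counts on 10-min bins whose rate is
`activity_level` (default 20/bin) during the subjective night — the
half cycle of an internal clock of period $\tau$ — and one fifth of
that (night:day ratio 5) otherwise; under an LD schedule, lights-on
activity can be masked to zero. Nightly acrophase truth is the
subjective-night midpoint.

**Metabolic pairs.** Two 24-h cosines (mesor 100, amplitude 20,
nocturnal acrophase 18 h) with the second delayed by `delay_h`. The
noisy-recovery condition used in tests is noise SD 2 (10% of
amplitude), emulating hourly-averaged oxygen-consumption error; at
noise approaching 25% of amplitude the acrophase information in 48
hourly samples is no longer sufficient for ±0.5-h recovery by any
estimator, so that regime is not claimed.

**Decay courses.** $e^{-kt}(1+\varepsilon)$, $\varepsilon \sim N(0,
\sigma)$ with $\sigma \ll 1$ (default tests use 0.05), three replicates
at 0/3/6 h.

All generators accept a `seed` and restore the caller's RNG state;
identical seeds give bit-identical output.

# Numerical choices and degenerate inputs

- **Extrema.** Local extrema with plateau ties resolved to the earliest
  sample; same-kind runs collapse to the most extreme member; a
  peak–trough pair closer than `min_separation_h` (default 6 h) is
  treated as one noise wiggle and removed as a pair; times are refined
  by 3-point parabolic interpolation (clamped to ±half a sample).
  Half-period sums exactly telescope to the spanned extrema interval.
- **Zero-variance series** give a degenerate periodogram ($Q_P = 0$
  everywhere, no best period) rather than an error; z-scoring a
  constant series is an error.
- **Wrapping.** Hour differences wrap to $(-P/2, P/2]$; boundary cases
  ($\pm P/2$, phases within $10^{-9}$ of $P$) are resolved to the
  positive/zero representative deterministically.
- **Ties** in the refinement grid resolve to the earliest candidate
  (`ties.method = "first"`), keeping `analyze_movie()` fully
  deterministic.
- **TIFF round-trip.** Movies are written as 32-bit float grayscale
  pages scaled to [0, 1] with the affine scale in the JSON sidecar;
  round-trip error is at float precision (~1e-7 relative).

# Problem sizes in the test suite

The suite validates the full-size recording geometry (60 × 60 × 131
movies) in the acceptance tests and uses a reduced geometry
(30 × 30 mask, ~750 in-mask pixels, 96–120 h) for module-level recovery
and property tests; Monte-Carlo sizes are 100–200 replicates for error
rates and 10–50 for heavier end-to-end recoveries. These sizes were
chosen so the whole suite completes in well under a minute while keeping
binomial envelopes tight enough to detect miscalibration.

# Known limitations

- The chi-square reference for $Q_P$ is approximate for small numbers
  of cycles (here $K \ge 4$ for movies, $\ge 12$ for 14-day actograms);
  the Bonferroni call is slightly conservative, which trades a little
  sensitivity for a guaranteed false-positive ceiling.
- Achieved-period quantization means the *periodogram's* best period is
  only as fine as one sample interval; downstream maps rely on the
  least-squares refinement.
- Acrophase maps at a single common period mildly misstate phases of
  pixels whose own period differs from it; over a 5-day record the
  discrepancy stays well under the between-genotype effects of
  interest.
- The behavioral module does not model splitting, re-entrainment
  latency, or activity-bout structure; its supported statistics are
  period, acrophase, and averaged profiles.
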