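# circaquant

Quantification of circadian rhythms in bioluminescence imaging, behavior,
and protein turnover.

Mammalian circadian rhythms are driven by the suprachiasmatic nucleus
(SCN), where thousands of cellular oscillators keep ~24-h time and stay
mutually synchronized. Experiments that probe this system typically
produce four kinds of records: time-lapse bioluminescence movies of SCN
explants carrying a PER2::LUC reporter (one luminescence time series per
pixel), per-well luminometer traces from cultured cells, locomotor
actograms from animals housed in light-dark (LD) or constant-dark (DD)
conditions, and cycloheximide-chase courses measuring clock-protein
degradation. `circaquant` implements the full quantification chain for
all four, plus a synthetic-data generator with known ground truth so that
every stage can be validated by parameter recovery — no animal data
needed.

## What it computes

**Chi-squared periodogram (Sokolove–Bushell).** For a trial period of
`P` samples the record is folded into `K` complete cycles and

```
Q_P = N * K * sum_h (M_h - M)^2 / sum_i (x_i - M)^2
```

compares the variance of the `P` fold-column means `M_h` against the
total variance of the `N = K*P` samples used; under the null `Q_P` is
referred to a chi-square distribution with `P - 1` degrees of freedom.
The rhythmicity call controls the familywise error of the whole period
scan (Bonferroni over the distinct fold lengths), so that at `alpha =
0.10` at most ~10% of non-rhythmic series are called oscillating.

**Cosinor.** Least-squares fit of `M + A cos(2*pi*(t - phi)/P)` via the
linearization `y = M + b1 cos(wt) + b2 sin(wt)`, giving mesor `M`,
amplitude `A = sqrt(b1^2 + b2^2)`, and acrophase
`phi = (P/2*pi) * atan2(b2, b1)` — the time at which the fitted cosine
peaks. Acrophases are circular quantities; the package wraps differences
into `(-P/2, P/2]` and summarizes distributions with circular mean/SD.

**Pixel pipeline.** Per in-mask pixel: detrend (centered one-cycle
moving-average baseline) → periodogram → oscillating call → cosinor
acrophase relative to the mask-averaged reference signal. Outputs are
period maps, relative-acrophase maps, oscillating-pixel percentages, and
a sliding-window Kuramoto order parameter `R = |mean(exp(i*theta))|`
that tracks progressive desynchronization among the cellular
oscillators.

**Behavior and physiology.** Free-running period of DD actograms
(periodogram over 20–28 h), per-day cosinor acrophases, averaged daily
activity profiles, and cosinor phase delay between paired 24-h
physiological rhythms (e.g. oxygen consumption in two genotypes).

**Protein decay.** Cycloheximide-chase courses normalized to their
`t = 0` level per replicate, log-linear decay fit with half-life, and
per-timepoint Student's t-tests between conditions. Group statistics
throughout use Student's t-test, the two-sided F-test for equality of
variances, and Tukey's HSD after one-way ANOVA.

## Worked example

Simulate a knockout-like SCN movie (16.7% arrhythmic pixels, widened
period/phase spread, phase diffusion) and quantify it:

```r
library(circaquant)
sim <- generate_scn_movie(movie_params(arrhythmic_fraction = 0.167,
  period_sd_h = 0.4, phase_sd_h = 2, phase_diffusion_sd = 0.2, seed = 42))
maps <- analyze_movie(sim$movie)
maps
#> <pixel_maps> 1528 in-mask blocks (binning 1), 84.2% oscillating at alpha = 0.1
#>   common acrophase period 24 h, reference acrophase 23.9 h
distribution_stats(maps, "period")
#> <distribution_summary> period: n = 1287, mean = 24.04 h, SD = 0.7444 h
distribution_stats(maps, "acrophase")
#> <distribution_summary> acrophase: n = 1287, mean = 0.03372 h, circular SD = 2.559 h
```

84.2% of the 1528 in-mask pixels are called oscillating — close to the
83.3% rhythmic fraction the generator was told to produce — and the
recovered period distribution (24.04 ± 0.74 h) reflects the widened
heterogeneity. The order parameter confirms progressive
desynchronization:

```r
R <- desynchrony_course(sim$movie, maps = maps)
round(range(R$values), 2)
#> 0.68 (last window) vs 0.84 (first window)
```

Actogram and decay analyses work the same way:

```r
act <- generate_actogram(tau_h = 24.17, n_days = 14, seed = 1)
free_running_period(act$record)
#> 24.167 h
fit_decay(generate_decay_course(log(2)/3, noise_sd = 0.05, seed = 1))
#> <decay fit> rate 0.2225 /h (SE 0.00478), half-life 3.115 h, R^2 0.997 (n = 9)
```

A thin command-line wrapper over the same functions lives at
`inst/cli/circaquant.R` (subcommands `simulate-movie`,
`simulate-actogram`, `simulate-decay`, `analyze-movie`,
`analyze-traces`, `analyze-actogram`, `analyze-decay`, `report`).

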