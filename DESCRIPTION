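Package: circaquant
Title: Quantification of Circadian Rhythms in Bioluminescence Imaging,
    Behavior, and Protein Turnover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-wise rhythm analysis of suprachiasmatic nucleus (SCN)
    bioluminescence movies and related circadian records. Implements the
    Sokolove-Bushell chi-squared periodogram, cosinor estimation of mesor,
    amplitude and acrophase, peak/trough half-period waveform analysis,
    actogram free-running period and acrophase statistics, metabolic phase
    delay, and cycloheximide-chase exponential decay fitting, together with
    a synthetic-data generator (heterogeneous damped cellular oscillators
    with phase diffusion and optional mean-field coupling, nocturnal
    Poisson actograms, exponential decay courses) so that every stage is
    testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
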