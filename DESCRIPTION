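Package: mmpe
Title: Modified Multivariable Permutation Entropy for Multichannel Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Ordinal-pattern complexity analysis for multichannel signals.
    Implements classical permutation entropy (PE), cross-channel multivariable
    permutation entropy (MPE), and a modified multivariable permutation
    entropy (MMPE) that combines per-channel Bandt-Pompe symbols into
    composite codes over an alphabet of size d!^m. Includes the
    normalize / PCA / re-normalize preprocessing chain for channel
    fusion, deterministic chaotic-system generators used for validation
    (the 2D sine-ICMIC modulation map and a simplified Lorenz flow with
    fixed-step fourth-order Runge-Kutta integration), synthetic multichannel
    EEG-like fixtures, and a sliding-window pipeline with one-way ANOVA for
    discriminating two recording states across subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
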