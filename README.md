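# mmpe

Ordinal-pattern complexity analysis for multichannel time series, built
around a **modified multivariable permutation entropy (MMPE)**.

## The problem

Permutation entropy (PE) is a fast, noise-robust complexity measure for a
*single* time series: slide a window of length *d* over the signal, replace
each window by the permutation that sorts it (its Bandt–Pompe ordinal
pattern, one of *d*! possibilities), and take the Shannon entropy of the
pattern distribution, normalized to [0, 1]:

    PE(x, d) = -1/ln(d!) * sum_theta p(pi_theta) ln p(pi_theta)

Many signals of interest — EEG above all — are intrinsically multichannel,
and per-channel PE discards the joint structure. Two multivariable
extensions are provided here:

* **MPE** ranks the *m* channel values at each time instant, so the
  channel count is the embedding dimension (alphabet *m*!, not tunable).
* **MMPE** symbolizes every channel separately at a chosen *d*, then fuses
  the simultaneous symbols `(s_1, ..., s_m)` into one composite code

      phi = s_1 * d!^(m-1) + s_2 * d!^(m-2) + ... + s_m,

  an injective, base-*d*! positional encoding with alphabet *d*!^*m*. The
  entropy of the composite-code distribution is normalized by
  `m * ln(d!)`. The larger alphabet lets MMPE see cross-channel structure
  that PE and MPE miss, while keeping O(n) cost.

Because *d*!^*m* explodes with the channel count, high-dimensional
recordings are first compressed by a **preprocessing chain**: per-channel
min–max normalization, correlation-matrix PCA on the standardized
channels (components retained until 85% of the variance is explained, or a
fixed count), and a final per-channel normalization of the scores.

The package validates the estimators on deterministic chaotic systems (the
2D sine-ICMIC modulation map and a simplified Lorenz flow with a single
bifurcation parameter), and applies them in a sliding-window, two-state
study design: per-subject window entropies, per-subject means, and a
one-way ANOVA comparing a rest state against a task state across subjects.
Synthetic 21-channel EEG-like fixtures with a built-in rest/task contrast
make the whole pipeline testable without any external data.

## Worked example

Complexity of the 2D-SIMM map at its reference chaotic setting
(`a = 1, b = 3, omega = pi`), measuring from the printed initial condition:

```r
library(mmpe)
X  <- simulate_2dsimm(10000, a = 1, b = 3, omega = pi, transient = 0)
Xn <- flip_minmax_normalize(X)
permutation_entropy(Xn[1, ], d = 4)
#> PE(d = 4, m = 1): 0.991749  [24/24 patterns observed, n = 9997]
mmpe(Xn, d = 4)
#> MMPE(d = 4, m = 2): 0.969275  [576/576 patterns observed, n = 9997]
```

PE saturates near 1 using 24 patterns; MMPE rates the same orbit slightly
lower on its 576-code alphabet — the extra patterns give it headroom that
makes parameter sweeps (`sweep_simm2d()`, `sweep_lorenz()`) separate
chaotic from periodic regimes more sharply.

A synthetic two-state EEG study (here scaled down to 12 subjects and
16,000 samples; the reference design uses 36 subjects, 31,000 samples and
10,000/500/40 windows):

```r
records <- synth_eeg_study(n_subjects = 12, n_channels = 21,
                           n_samples = 16000, seed = 1)
run_two_state_study(records, estimator = "MMPE", d = 4, m_override = 4,
                    length = 8000, step = 500, max_windows = 16)
#> Two-state study: MMPE(d = 4), 12 subjects, 16 windows/record
#> mean before = 0.5346, mean during = 0.5814
#>   source       SS df         MS      F         p
#>  Columns 0.013111  1 0.01311100 24.858 5.453e-05
#>    Error 0.011604 22 0.00052745     NA        NA
#>    Total 0.024715 23         NA     NA        NA
```

The task state carries more broadband and gamma-band activity, so its
MMPE is higher; the ANOVA table (Columns = between-state, Error = within)
rejects equality of the two state means at p < 0.05.
`random_channel_experiment()` reruns the same study on random raw channel
subsets without PCA — its p-values show why the channel-fusion step is
necessary.

Real recordings enter the pipeline as delimited text matrices (one channel
per row) via `read_series_csv()`; convert EDF files with any standard
exporter first. A thin command-line wrapper with subcommands
`entropy | simulate | sweep | eeg-run | channels-experiment` is installed
at `system.file("cli", "mmpe-cli", package = "mmpe")`.

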