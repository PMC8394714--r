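---
title: "Methods: ordinal multivariable complexity with mmpe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ordinal multivariable complexity with mmpe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design decisions
behind the package: what exactly is computed, which choices were open and
how they were fixed, and what the synthetic validation does and does not
demonstrate.

## Ordinal symbolization

For a univariate series $x_1,\dots,x_n$ and embedding dimension $d$, each
window $(x_i,\dots,x_{i+d-1})$ (lag 1, consecutive samples — no lag
parameter is exposed; coarser time scales are handled by explicit
subsampling, see below) is mapped to one of the $d!$ permutations that
sort it ascending, giving $n-d+1$ symbols.

Two conventions had to be fixed:

* **Pattern indexing.** Symbols enumerate permutations in lexicographic
  order of the *rank vector* — the vector of ranks of the window entries
  at their original positions (equivalently, the inverse of the sorting
  permutation). For $d=3$ this yields the enumeration
  $1{:}\,x_1\le x_2\le x_3$, $2{:}\,x_1\le x_3\le x_2$,
  $3{:}\,x_2\le x_1\le x_3$, $4{:}\,x_3\le x_1\le x_2$,
  $5{:}\,x_2\le x_3\le x_1$, $6{:}\,x_3\le x_2\le x_1$, which is frozen as
  a table in the test suite. Note that lexicographic order of the
  *sorting* permutation would swap patterns 4 and 5; the rank-vector
  order is the one used everywhere.
* **Ties.** Equal values are resolved by a stable ascending sort: the
  earlier sample counts as smaller. This is deterministic and is the
  common convention for ordinal patterns on finitely quantized data.

The implementation computes rank vectors by vectorized pairwise
comparison and converts them to indices with a Lehmer code; tests compare
it against a naive oracle that materializes every window, calls
`rank(..., ties.method = "first")` and tallies pattern strings in a
dictionary (agreement to 1e-12 on hundreds of random instances).

## The three estimators

With $p(\pi_\theta)$ the relative frequency of pattern $\theta$ (absent
patterns contribute nothing, by the convention $0\ln 0 = 0$):

* **PE**: $-\frac{1}{\ln d!}\sum_\theta p \ln p$ over the $d!$
  single-channel patterns.
* **MPE**: one symbol per time instant from ranking the $m$ channel
  values; the embedding dimension *is* the channel count, the alphabet is
  $m!$, and the normalizer $\ln m!$. Nothing is tunable, which is MPE's
  main practical weakness.
* **MMPE**: per-channel symbol streams at a chosen $d$ are fused into
  composite codes
  $\varphi_j = \sum_{i=1}^m s_{i,j}\, (d!)^{m-i}$,
  an injective positional encoding (its image is a shifted subset of the
  integers, with exactly $d!^m$ attainable codes). The entropy of the
  composite distribution — summed over all *observed* composite codes —
  is normalized by $S_{\max} = m \ln d!$, the log of the full
  $d!^m$ alphabet. MMPE reduces exactly to PE at $m=1$, and to PE$/m$ for
  $m$ stacked copies of one channel.

$d$ is capped at 7 and the product $d!^m$ is required to stay below
$2^{53}$ so composite codes remain exact in double precision; in practice
$d \in \{3,4,5\}$ and $m \le 5$ are the sensible range.

**Undersampling bias.** The Shannon estimate of a distribution over
$d!^m$ codes from $N$ windows cannot exceed $\ln N$, so normalized MMPE
is bounded by $\ln N / (m \ln d!)$ — about 0.72 for $m=4$, $d=4$,
$N \approx 10^4$. Near-independent, ordinally diverse channels pin the
estimate at that ceiling regardless of their dynamics. MMPE is therefore
informative exactly when the channels carry *repetitive, coupled* ordinal
structure (rhythms, shared dynamics), which is what PCA-compressed
physiological recordings look like. This bound drove the design of the
synthetic generator below and is the main caveat for interpreting
absolute MMPE values.

## Preprocessing chain

1. Per-channel flipped min–max normalization
   $\tilde x = (\max - x)/(\max - \min)$, mapping the maximum to 0 and
   the minimum to 1. The orientation reversal is harmless for ordinal
   statistics (a strictly decreasing map relabels patterns bijectively
   and leaves every entropy value unchanged, which is asserted in tests).
   A constant channel is an error by default (`const_action = "zero"`
   maps it to zeros instead; the parameter sweeps use that mode because a
   fixed-point orbit is legitimately constant, with complexity 0).
2. Channel standardization to z-scores (sample standard deviation,
   denominator $n-1$; requires $n > k$), applied to the already
   normalized channels — the chain re-standardizes rather than assuming
   unit scale.
3. PCA as the eigendecomposition of the correlation matrix
   $R = Z'Z/(n-1)$. Components are retained until the cumulative
   eigenvalue share reaches the threshold (default 0.85), or a fixed
   count overrides the rule (the reference EEG design fixes 4).
   Eigenvector signs are ambiguous, so each eigenvector's
   largest-magnitude entry is made positive; degenerate eigenvalues keep
   the solver's descending order with the sign rule applied afterwards.
   Determinism here matters only for reproducibility — entropies are
   insensitive to component sign.
4. The same flipped normalization on the scores.

In the windowed pipeline the chain (including the PCA fit) is applied
once per record by default. Fitting per window is available
(`scope = "window"`) but makes windows incomparable when the mixing is
stationary, and costs a factor of the window count; 60-second EEG
segments are treated as having stationary mixing.

## Validation systems

**2D-SIMM map.** The two-dimensional sine-ICMIC modulation map
$x_i = a\sin(\omega y_{i-1})\sin(b/x_{i-1})$,
$y_i = a\sin(\omega x_i)\sin(b/y_{i-1})$ (note the *current* $x_i$ in the
second equation, and the infinite-collapse factor $\sin(b/\cdot)$).
Orbits are bounded by $a$; at $a=1, b=3, \omega=\pi$ the map is
hyperchaotic, and sweeping $a \in [0.4, 4]$ crosses several periodic
windows. The map is singular at 0: for small $a$ the orbit collapses
toward the origin until $b/x$ overflows, which the simulator reports as
an error naming the step; sweeps label such parameter values
`degenerate` and carry `NA` values. The default transient is 1000
iterates; analyses that reference the printed initial condition
$(0.45, 0.95)$ use `transient = 0`.

**Simplified Lorenz flow.** $\dot x = 10(y-x)$,
$\dot y = -xz + (24-4c)x + cy$, $\dot z = xy - 8z/3$, integrated with
fixed-step RK4 at $h = 0.01$ (a single step is verified against an
independent hand-coded RK4 oracle to 1e-12). The initial state defaults
to $(1,1,1)$ with 10,000 transient steps discarded — the attractor
statistics are insensitive to the initial state once the transient is
removed, which is why the (unstated) choice is safe. Integer subsampling
periods $\tau$ thin the trajectory after integration; both PE and MMPE
increase with $\tau$ on the chaotic attractor (the flow decorrelates
between samples), with PE saturating toward 1 while MMPE levels off
lower — the sweep tests assert non-decrease up to a simulation tolerance
of 0.02 per step and PE$(\tau{=}25) > 0.85$.

**Regime labels without circularity.** Chaotic-versus-periodic assertions
need ground truth that does not come from the entropies being tested.
The map uses the cardinality of the orbit tail (≤ 32 distinct values at
10 significant digits ⇒ periodic); the flow uses the number of distinct
successive maxima of $z$ (≤ 16 at 2 decimals ⇒ periodic) — the classical
one-dimensional return-map reduction. On sweep grids of 60 map
parameters and 20 flow parameters these diagnostics find both regimes,
and MMPE's chaotic-minus-periodic gap exceeds PE's on both systems (the
composite alphabet scores periodic orbits much lower, while both
estimators saturate on chaos).

## Synthetic two-state EEG generator

`synth_eeg_study()` emulates a 36-subject, 21-channel, 31,000-sample
paired recording protocol (nominal 500 Hz). Per subject:

* four latent narrowband rhythm sources — AR(2) oscillators with poles of
  modulus 0.998 at 8, 10, 12 and 20 Hz — mixed into the channels by a
  subject-specific orthonormal $21 \times 4$ matrix;
* white sensor noise, sd 0.03 relative to unit-variance sources;
* the *task* state differs from *rest* by a larger broadband (white)
  fraction in every source (0.015 → 0.04) and an added 40 Hz gamma-band
  component (amplitude 0.05 → 0.3) — the standard electrophysiological
  signature of cognitive load (desynchronization plus gamma);
* lognormal subject-level jitters (sd 0.15–0.2) on the broadband, gamma
  and sensor-noise levels, shared between the two states of a subject.

Why it behaves like the real design is supposed to: the rhythmic sources
keep MMPE far below its undersampling ceiling, so the broadband/gamma
increase raises it measurably; sensor noise dominates raw-channel
*increments* (though not their variance), so single raw channels are
ordinally noise-masked and the random-channel control fails where the
PCA pipeline succeeds; and the gamma component produces curvature motifs
that longer windows resolve better, so the group separation sharpens as
$d$ grows from 3 to 5.

What the generator does **not** emulate: artifacts (ocular, muscular,
line noise), nonstationary mixing, heavy-tailed amplitude distributions,
volume-conduction correlation structure beyond linear mixing, or any
true neural dynamics. Passing pipeline tests therefore demonstrate the
statistical machinery — windowing, fusion, estimation, ANOVA — under a
controlled effect of realistic size, not the neurophysiological claim
itself.

## Windowed study and statistics

Windows of 10,000 samples advance by 500; a 31,000-sample record yields
43 windows by the formula, capped at 40 by default so every record
contributes the same number (the uncapped plan is available via
`max_windows = Inf`). Per-subject means over windows feed a textbook
one-way ANOVA (Columns / Error / Total), implemented directly so the
core statistic has no hidden dependency; it is cross-checked against
`stats::aov` and the identity $F = t^2$ (pooled two-sample $t$) to 1e-9.
Sum-of-squares and degree-of-freedom conservation are asserted on every
run. A Shapiro–Wilk screen of each group of means is reported but never
gates the analysis. The random-channel control draws channel subsets
without replacement (the same subset for all subjects within a repeat),
skips PCA, and reports the p-value distribution across repeats.

Window indices in all user-facing output are 1-based and inclusive.

## Problem sizes and tolerances in the test suite

Unit tests run the pipeline at reduced scale (8–12 subjects, 6,000–12,000
samples) chosen so that the effects of interest remain comfortably
detectable; the end-to-end checks run the full reference scale
(36 subjects, 31,000 samples, 10 seeds). Entropy oracle comparisons use
1e-12; linear-algebra identities 1e-8 to 1e-9; stochastic limit laws use
the bands 0.01 (PE of i.i.d. noise at $n = 10^4$) and 0.02 (MMPE of
independent channels at $n = 5\times 10^4$), consistent with the
$O(K/N)$ bias of plug-in entropy estimates.

## Known limitations

* MMPE values are comparable only at fixed $(d, m, N)$; the
  undersampling ceiling makes absolute values misleading when
  $d!^m \gtrsim N$.
* MPE is reported for completeness but is often insensitive or inverted
  as a complexity index (its alphabet ignores temporal ordering
  entirely); the flow sweeps show it decreasing where PE/MMPE increase.
* No multiscale coarse-graining, weighted/amplitude-aware variants, or
  Rényi generalizations.
* EDF files are not parsed natively; recordings enter as delimited text
  matrices (channels × samples).
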