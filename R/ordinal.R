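# Bandt-Pompe ordinal symbolization and the PE / MPE / MMPE estimators.

# factorials 1!..7!; d is capped at 7 so that d!^m stays exactly
# representable in doubles for the channel counts used in practice
.factorials <- cumprod(1:7)

.check_embedding_dim <- function(d) {
  if (length(d) != 1L || !is.numeric(d) || is.na(d) || d != round(d))
    stop("embedding dimension `d` must be a single integer", call. = FALSE)
  d <- as.integer(d)
  if (d < 2L || d > 7L)
    stop("embedding dimension `d` must be between 2 and 7", call. = FALSE)
  d
}

.as_channel_matrix <- function(x, arg = "x") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 1L || ncol(x) < 2L)
    stop("`", arg, "` must have at least 1 channel and 2 samples", call. = FALSE)
  if (!all(is.finite(x)))
    stop("`", arg, "` contains non-finite values", call. = FALSE)
  x
}

# Rank each row of the window matrix W (one window per row) and return the
# lexicographic index of the rank vector among all d! permutations.
# Ties: earlier position wins (stable ascending sort), so the rank of
# element b counts elements strictly smaller, plus equal elements at an
# earlier position.
.ordinal_codes <- function(W) {
  d <- ncol(W)
  N <- nrow(W)
  R <- matrix(1L, N, d)
  for (a in seq_len(d)) {
    Wa <- W[, a]
    for (b in seq_len(d)) {
      if (a == b) next
      if (a < b) {
        R[, b] <- R[, b] + (Wa < W[, b] | Wa == W[, b])
      } else {
        R[, b] <- R[, b] + (Wa < W[, b])
      }
    }
  }
  # Lehmer code of the rank vector -> lexicographic index (1-based)
  code <- numeric(N)
  for (i in seq_len(d - 1L)) {
    ci <- integer(N)
    for (j in (i + 1L):d) ci <- ci + (R[, j] < R[, i])
    code <- code + ci * .factorials[d - i]
  }
  as.integer(code) + 1L
}

#' Extract ordinal (Bandt-Pompe) symbols from a univariate series
#'
#' Slides a window of length `d` over the series (lag 1, consecutive
#' samples) and maps each window to the index of its ascending-order
#' permutation, yielding a symbol stream of length `n - d + 1` with symbols
#' in `1:factorial(d)`.
#'
#' Symbols index the `d!` permutations in lexicographic order of the *rank
#' vector* (the rank of each window element, earliest index winning ties).
#' For `d = 3` this enumerates: 1 = x1<=x2<=x3, 2 = x1<=x3<=x2,
#' 3 = x2<=x1<=x3, 4 = x3<=x1<=x2, 5 = x2<=x3<=x1, 6 = x3<=x2<=x1.
#' Equal values are resolved by a stable ascending sort (the earlier sample
#' is treated as smaller), the common Bandt-Pompe convention.
#'
#' @param x numeric vector, all values finite, `length(x) >= d`.
#' @param d embedding dimension (window length), integer in 2..7.
#' @return integer vector of `length(x) - d + 1` symbols in `1:factorial(d)`.
#' @examples
#' ordinal_symbols(c(1, 2, 3, 4, 5), d = 3)       # all ascending: 1 1 1
#' ordinal_symbols(c(0.1, 0.5, 0.9, 0.2), d = 3)  # 1 4
#' @export
ordinal_symbols <- function(x, d) {
  d <- .check_embedding_dim(d)
  if (!is.numeric(x))
    stop("`x` must be numeric", call. = FALSE)
  x <- as.numeric(x)
  if (!all(is.finite(x)))
    stop("`x` contains non-finite values", call. = FALSE)
  n <- length(x)
  if (n < d)
    stop("series of length ", n, " is shorter than embedding dimension ", d,
         call. = FALSE)
  N <- n - d + 1L
  W <- vapply(seq_len(d), function(k) x[k:(k + N - 1L)], numeric(N))
  if (N == 1L) W <- matrix(W, nrow = 1L)
  .ordinal_codes(W)
}

#' Empirical distribution of pattern codes
#'
#' Tallies relative frequencies over the observed codes. Codes never
#' observed carry probability zero and, by the convention `0 * log(0) = 0`,
#' contribute nothing to the Shannon entropy.
#'
#' @param symbols integer or numeric vector of pattern codes (symbols from
#'   [ordinal_symbols()] or composite codes from [combine_channel_symbols()]).
#' @param alphabet_size number of possible codes (`d!` for a single channel,
#'   `d!^m` for composite codes over `m` channels).
#' @return an object of class `pattern_distribution`: a list with `codes`
#'   (sorted distinct observed codes), `counts`, `p` (relative frequencies),
#'   `total` and `alphabet_size`.
#' @export
pattern_distribution <- function(symbols, alphabet_size) {
  if (length(symbols) == 0L)
    stop("empty symbol sequence", call. = FALSE)
  if (!is.numeric(symbols) || !all(is.finite(symbols)) || any(symbols < 1))
    stop("symbols must be finite positive codes", call. = FALSE)
  if (length(alphabet_size) != 1L || !is.finite(alphabet_size) ||
      alphabet_size < 1)
    stop("`alphabet_size` must be a positive number", call. = FALSE)
  u <- sort(unique(symbols))
  if (length(u) > alphabet_size)
    stop("more distinct symbols than `alphabet_size` allows", call. = FALSE)
  counts <- tabulate(match(symbols, u), nbins = length(u))
  structure(
    list(codes = u, counts = counts, total = length(symbols),
         p = counts / length(symbols), alphabet_size = alphabet_size),
    class = "pattern_distribution")
}

#' Number of distinct observed patterns
#' @param dist a `pattern_distribution`.
#' @return integer count of codes with nonzero frequency.
#' @export
n_observed_patterns <- function(dist) {
  stopifnot(inherits(dist, "pattern_distribution"))
  length(dist$codes)
}

.shannon <- function(dist) {
  p <- dist$p
  -sum(p * log(p))
}

.entropy_result <- function(dist, estimator, d, m, s_max) {
  value <- .shannon(dist) / s_max
  structure(
    list(value = value, estimator = estimator, d = d, m = m,
         distribution = dist, s_max = s_max),
    class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("%s(d = %d, m = %d): %.6f  [%d/%s patterns observed, n = %d]\n",
              x$estimator, x$d, x$m, x$value,
              n_observed_patterns(x$distribution),
              format(x$distribution$alphabet_size, big.mark = ","),
              x$distribution$total))
  invisible(x)
}

#' Permutation entropy of a univariate series
#'
#' Shannon entropy of the ordinal-pattern distribution, normalized by
#' `log(factorial(d))` so that the value lies in `[0, 1]`: 0 for a series
#' with a single ordinal pattern (e.g. strictly monotone), 1 when all `d!`
#' patterns are equally frequent.
#'
#' @inheritParams ordinal_symbols
#' @return an `entropy_result` with fields `value`, `estimator`, `d`, `m`,
#'   `distribution` and `s_max`.
#' @examples
#' permutation_entropy(sin(seq(0, 20, by = 0.1)), d = 3)$value
#' @export
permutation_entropy <- function(x, d) {
  d <- .check_embedding_dim(d)
  sym <- ordinal_symbols(x, d)
  dist <- pattern_distribution(sym, .factorials[d])
  .entropy_result(dist, "PE", d = d, m = 1L, s_max = log(.factorials[d]))
}

#' Combine per-channel ordinal symbols into composite codes
#'
#' Encodes the m-tuple of simultaneous per-channel symbols
#' `(s_1, ..., s_m)`, each in `1:d!`, as the single integer
#' `s_1 * d!^(m-1) + s_2 * d!^(m-2) + ... + s_m`. The map is injective on
#' tuples, so the composite stream has at most `d!^m` distinct codes.
#'
#' @param symbols a list of `m` equal-length integer symbol vectors (one per
#'   channel), or an `m x N` integer matrix with one channel per row.
#' @param d the embedding dimension the symbols were extracted with.
#' @return numeric vector of composite codes (doubles, exact integers).
#' @examples
#' combine_channel_symbols(rbind(1L, 1L), d = 3)  # 7
#' combine_channel_symbols(rbind(6L, 6L), d = 3)  # 42
#' @export
combine_channel_symbols <- function(symbols, d) {
  d <- .check_embedding_dim(d)
  if (is.list(symbols)) {
    lens <- lengths(symbols)
    if (length(unique(lens)) != 1L)
      stop("per-channel symbol streams have mismatched lengths", call. = FALSE)
    S <- do.call(rbind, symbols)
  } else if (is.matrix(symbols)) {
    S <- symbols
  } else {
    S <- matrix(symbols, nrow = 1L)
  }
  m <- nrow(S)
  fd <- .factorials[d]
  if (any(S < 1L) || any(S > fd))
    stop("symbols out of range 1..d! for d = ", d, call. = FALSE)
  if (m * log(fd) > 53 * log(2))
    stop("d!^m exceeds exact double-precision integer range (reduce d or m)",
         call. = FALSE)
  w <- fd^((m - 1L):0)
  drop(w %*% S)
}

#' Modified multivariable permutation entropy (MMPE)
#'
#' Symbolizes each channel with its own Bandt-Pompe stream at embedding
#' dimension `d`, combines the simultaneous symbols into composite codes
#' over the alphabet of size `d!^m` (see [combine_channel_symbols()]), and
#' returns the Shannon entropy of the composite-code distribution normalized
#' by `m * log(d!)`. With `m = 1` this reduces exactly to
#' [permutation_entropy()].
#'
#' The estimator expects its input on a common scale (the preprocessing
#' chain takes care of that in the pipeline); values themselves are
#' invariant under strictly monotone per-channel transformations.
#'
#' @param x numeric matrix, channels in rows, samples in columns (a vector
#'   is treated as a single channel).
#' @param d embedding dimension, integer in 2..7.
#' @return an `entropy_result`.
#' @examples
#' x <- rbind(sin(seq(0, 50, by = 0.05)), cos(seq(0, 50, by = 0.05)))
#' mmpe(x, d = 3)$value
#' @export
mmpe <- function(x, d) {
  d <- .check_embedding_dim(d)
  X <- .as_channel_matrix(x)
  m <- nrow(X)
  syms <- lapply(seq_len(m), function(i) ordinal_symbols(X[i, ], d))
  codes <- combine_channel_symbols(syms, d)
  dist <- pattern_distribution(codes, .factorials[d]^m)
  .entropy_result(dist, "MMPE", d = d, m = m, s_max = m * log(.factorials[d]))
}

#' Cross-channel multivariable permutation entropy (MPE)
#'
#' At every time instant the `m` channel values are ranked, giving one
#' ordinal symbol per sample over the alphabet of `m!` cross-channel
#' patterns; the embedding dimension is the channel count itself and cannot
#' be chosen. The value is the Shannon entropy of that distribution
#' normalized by `log(m!)`.
#'
#' @param x numeric matrix with at least 2 channels (rows).
#' @return an `entropy_result` with `d = m`.
#' @examples
#' x <- rbind(c(0, 1, 0, 1), c(1, 0, 1, 0))
#' mpe(x)$value  # alternating order: both patterns equally likely -> 1
#' @export
mpe <- function(x) {
  X <- .as_channel_matrix(x)
  m <- nrow(X)
  if (m < 2L)
    stop("MPE needs at least 2 channels; the channel count is its embedding dimension",
         call. = FALSE)
  if (m > 7L)
    stop("MPE with more than 7 channels is not supported (m! alphabet)",
         call. = FALSE)
  sym <- .ordinal_codes(t(X))
  dist <- pattern_distribution(sym, .factorials[m])
  .entropy_result(dist, "MPE", d = m, m = m, s_max = log(.factorials[m]))
}
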