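# Naive ordinal-entropy oracle: materializes every window, ranks it with a
# stable ascending sort, and tallies pattern strings in a dictionary.
# Shares nothing with the package's Lehmer-code implementation except the
# earliest-index tie convention, which is the documented contract.
oracle_entropy <- function(X, d = NULL, estimator = c("PE", "MMPE", "MPE")) {
  estimator <- match.arg(estimator)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  m <- nrow(X)
  n <- ncol(X)
  key <- function(w) paste(rank(w, ties.method = "first"), collapse = "-")
  if (estimator == "MPE") {
    keys <- vapply(seq_len(n), function(i) key(X[, i]), "")
    smax <- log(factorial(m))
  } else {
    N <- n - d + 1
    chan_keys <- lapply(seq_len(m), function(ch)
      vapply(seq_len(N), function(i) key(X[ch, i:(i + d - 1)]), ""))
    keys <- do.call(paste, c(chan_keys, sep = "|"))
    smax <- if (estimator == "PE") log(factorial(d)) else m * log(factorial(d))
  }
  tab <- table(keys)
  p <- as.numeric(tab) / sum(tab)
  -sum(p * log(p)) / smax
}

# Small reduced-scale synthetic study used by several pipeline tests.
make_small_study <- function(seed, n_subjects = 8, n_samples = 12000) {
  synth_eeg_study(n_subjects = n_subjects, n_channels = 21,
                  n_samples = n_samples, seed = seed)
}

small_plan <- list(length = 6000, step = 500, max_windows = 8)
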