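# Sliding-window analysis: window planning and per-window entropy.

#' Plan sliding windows over a recording
#'
#' Windows of `length` samples start at 1, 1 + step, 1 + 2*step, ...
#' (1-based inclusive indices). The count is
#' `min(floor((n - length) / step) + 1, max_windows)`; the cap reproduces
#' study designs that analyse a fixed number of windows per record (for a
#' 31,000-sample record with the 10,000 / 500 scheme the formula gives 43
#' windows, capped at 40 by default). Use `max_windows = Inf` for the
#' uncapped plan.
#'
#' @param n number of samples available.
#' @param length window length in samples (default 10000).
#' @param step start-to-start distance between consecutive windows
#'   (default 500).
#' @param max_windows cap on the number of windows (default 40).
#' @return data.frame with columns `window`, `start`, `end` (1-based,
#'   inclusive).
#' @export
plan_windows <- function(n, length = 10000, step = 500, max_windows = 40) {
  stopifnot(length >= 1, step >= 1)
  if (n < length)
    stop("record of ", n, " samples is shorter than the window length ",
         length, call. = FALSE)
  k <- floor((n - length) / step) + 1
  k <- as.integer(min(k, max_windows))
  start <- 1L + (seq_len(k) - 1L) * as.integer(step)
  data.frame(window = seq_len(k), start = start,
             end = start + as.integer(length) - 1L)
}

.estimator_fun <- function(estimator, d) {
  switch(estimator,
    PE = function(X) {
      if (nrow(X) != 1L)
        stop("PE needs a single channel; got ", nrow(X), call. = FALSE)
      permutation_entropy(X[1L, ], d)
    },
    MMPE = function(X) mmpe(X, d),
    MPE = function(X) mpe(X))
}

#' Per-window entropy of a multichannel record
#'
#' Runs the preprocessing chain, then evaluates the chosen estimator on
#' each planned window. With `scope = "record"` (default) preprocessing —
#' including the PCA fit — is done once on the whole record and the ordinal
#' symbol streams are computed once and sliced per window; this is exact
#' because ordinal symbols are local to their window and the record-level
#' min-max flip is strictly monotone per channel. With `scope = "window"`
#' every window is preprocessed (and PCA refitted) independently;
#' preprocessing failures are reported with the offending window index.
#'
#' For PE and MMPE the two scopes give identical values on the same PCA
#' basis (per-channel normalization is strictly monotone). MPE ranks
#' *across* channels and is not invariant to per-channel rescaling, so its
#' values depend mildly on which scope sets the normalization constants.
#'
#' @param x channels x samples matrix, or a `subject_record`.
#' @param windows a window plan from [plan_windows()]; by default planned
#'   from the record length with the given `length`, `step`, `max_windows`.
#' @param estimator one of `"MMPE"`, `"PE"`, `"MPE"`.
#' @param d embedding dimension for PE / MMPE.
#' @param use_pca,threshold,m_override,const_action preprocessing options,
#'   see [preprocess_chain()].
#' @param scope `"record"` (fit once) or `"window"` (fit per window).
#' @inheritParams plan_windows
#' @return list with `values` (one entropy per window), `mean`, `windows`
#'   (the plan), `estimator`, `d`.
#' @export
windowed_entropy <- function(x, windows = NULL,
                             estimator = c("MMPE", "PE", "MPE"), d = 4,
                             use_pca = TRUE, threshold = 0.85,
                             m_override = NULL,
                             const_action = c("error", "zero"),
                             scope = c("record", "window"),
                             length = 10000, step = 500, max_windows = 40) {
  estimator <- match.arg(estimator)
  scope <- match.arg(scope)
  const_action <- match.arg(const_action)
  if (inherits(x, "subject_record")) x <- x$series
  X <- .as_channel_matrix(x)
  if (is.null(windows))
    windows <- plan_windows(ncol(X), length, step, max_windows)
  if (estimator != "MPE") d <- .check_embedding_dim(d)

  if (scope == "window") {
    est <- .estimator_fun(estimator, d)
    values <- vapply(seq_len(nrow(windows)), function(i) {
      sl <- X[, windows$start[i]:windows$end[i], drop = FALSE]
      tryCatch(
        est(preprocess_chain(sl, use_pca, threshold, m_override,
                             const_action))$value,
        error = function(e)
          stop("window ", i, ": ", conditionMessage(e), call. = FALSE))
    }, numeric(1))
    return(list(values = values, mean = mean(values), windows = windows,
                estimator = estimator, d = d))
  }

  P <- preprocess_chain(X, use_pca, threshold, m_override, const_action)
  m <- nrow(P)
  if (estimator == "PE" && m != 1L)
    stop("PE needs a single channel after preprocessing; got ", m,
         call. = FALSE)
  if (estimator == "MPE") {
    if (m < 2L) stop("MPE needs at least 2 channels", call. = FALSE)
    codes <- .ordinal_codes(t(P))
    alphabet <- .factorials[m]
    s_max <- log(alphabet)
    slice <- function(i) codes[windows$start[i]:windows$end[i]]
    d_out <- m
  } else {
    syms <- lapply(seq_len(m), function(i) ordinal_symbols(P[i, ], d))
    codes <- combine_channel_symbols(syms, d)
    alphabet <- .factorials[d]^m
    s_max <- m * log(.factorials[d])
    slice <- function(i) codes[windows$start[i]:(windows$end[i] - d + 1L)]
    d_out <- d
  }
  values <- vapply(seq_len(nrow(windows)), function(i) {
    dist <- pattern_distribution(slice(i), alphabet)
    .shannon(dist) / s_max
  }, numeric(1))
  list(values = values, mean = mean(values), windows = windows,
       estimator = estimator, d = d_out)
}
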