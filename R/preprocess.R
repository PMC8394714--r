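# Channel-fusion preprocessing: min-max flip normalization, channel
# standardization, correlation PCA with an explained-variance retention
# rule, and the full normalize -> PCA -> re-normalize chain.

#' Flipped min-max normalization per channel
#'
#' Maps each channel to `(max - x) / (max - min)`, so the channel maximum
#' goes to 0 and the minimum to 1. The orientation reversal is deliberate
#' (it is the form the chain uses); ordinal entropies are unaffected because
#' a strictly decreasing map relabels patterns bijectively.
#'
#' @param x numeric matrix, channels in rows (a vector is one channel).
#' @param const_action what to do with a constant channel: `"error"`
#'   (default) or `"zero"` (map to all zeros, with a warning).
#' @return matrix of the same shape with all entries in `[0, 1]`.
#' @examples
#' flip_minmax_normalize(matrix(c(0, 5, 10), 1))  # 1.0 0.5 0.0
#' @export
flip_minmax_normalize <- function(x, const_action = c("error", "zero")) {
  const_action <- match.arg(const_action)
  X <- .as_channel_matrix(x)
  hi <- apply(X, 1L, max)
  lo <- apply(X, 1L, min)
  rng <- hi - lo
  flat <- rng == 0
  if (any(flat)) {
    if (const_action == "error")
      stop("constant channel(s): ", paste(which(flat), collapse = ", "),
           call. = FALSE)
    warning("constant channel(s) ", paste(which(flat), collapse = ", "),
            " mapped to zeros", call. = FALSE)
    rng[flat] <- 1
  }
  out <- (hi - X) / rng
  if (any(flat)) out[flat, ] <- 0
  dimnames(out) <- dimnames(X)
  out
}

#' Standardize channels to z-scores
#'
#' Column-wise standardization of the samples-by-channels matrix: each
#' channel is centred on its mean and scaled by its sample standard
#' deviation (denominator `n - 1`). Requires more samples than channels.
#'
#' @param x numeric matrix, channels in rows, samples in columns.
#' @return an object of class `standardized_channels`: list with `Z`
#'   (n x k matrix, rows = samples), `means`, `sds` and `k`, `n`.
#' @export
standardize_channels <- function(x) {
  X <- .as_channel_matrix(x)
  k <- nrow(X)
  n <- ncol(X)
  if (n <= k)
    stop("standardization requires more samples (", n, ") than channels (",
         k, ")", call. = FALSE)
  sds <- apply(X, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant channel(s): ", paste(which(sds == 0), collapse = ", "),
         call. = FALSE)
  means <- rowMeans(X)
  Z <- t((X - means) / sds)
  structure(list(Z = Z, means = means, sds = sds, k = k, n = n),
            class = "standardized_channels")
}

.std_matrix <- function(z) {
  if (inherits(z, "standardized_channels")) return(z$Z)
  if (!is.matrix(z)) stop("expected a standardized matrix", call. = FALSE)
  z
}

#' Fit PCA on standardized channels
#'
#' Eigendecomposition of the correlation matrix `R = Z'Z / (n - 1)`.
#' Eigenvalues are sorted in decreasing order; each eigenvector's sign is
#' fixed so its largest-magnitude entry is positive (determinism).
#' The number of retained components is the smallest `m` whose cumulative
#' eigenvalue share reaches `threshold`.
#'
#' @param z a `standardized_channels` object (or an n x k standardized
#'   matrix, rows = samples).
#' @param threshold cumulative explained-variance target in (0, 1],
#'   default 0.85.
#' @return an object of class `pca_model`: list with `correlation`,
#'   `eigenvalues`, `vectors` (orthonormal columns), `explained`
#'   (cumulative shares), `retained` and `threshold`.
#' @export
fit_pca <- function(z, threshold = 0.85) {
  Z <- .std_matrix(z)
  if (!all(is.finite(Z)))
    stop("non-finite entries in standardized matrix", call. = FALSE)
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0 || threshold > 1)
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  n <- nrow(Z)
  R <- crossprod(Z) / (n - 1)
  e <- eigen(R, symmetric = TRUE)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  shares <- cumsum(e$values) / sum(e$values)
  retained <- which(shares >= threshold - 1e-12)[1L]
  structure(
    list(correlation = R, eigenvalues = e$values, vectors = V,
         explained = shares, retained = retained, threshold = threshold),
    class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  k <- length(x$eigenvalues)
  cat(sprintf("PCA on %d channels: retain %d component(s) at threshold %.2f\n",
              k, x$retained, x$threshold))
  cat("eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = " "), "\n")
  invisible(x)
}

#' Project standardized channels onto retained principal components
#'
#' @param z a `standardized_channels` object (or standardized n x k matrix).
#' @param model a `pca_model` fitted on compatible data.
#' @param m_override optional component count overriding the threshold rule
#'   (the EEG study fixes 4 components regardless of the 85 percent rule).
#' @return score series as an m x n matrix (components in rows).
#' @export
transform_pca <- function(z, model, m_override = NULL) {
  Z <- .std_matrix(z)
  stopifnot(inherits(model, "pca_model"))
  k <- length(model$eigenvalues)
  if (ncol(Z) != k)
    stop("matrix has ", ncol(Z), " channels but model was fitted on ", k,
         call. = FALSE)
  m <- if (is.null(m_override)) model$retained else m_override
  if (m < 1L || m > k)
    stop("component count ", m, " out of range 1..", k, call. = FALSE)
  t(Z %*% model$vectors[, seq_len(m), drop = FALSE])
}

#' Full preprocessing chain: normalize, PCA, re-normalize
#'
#' Applies the flipped min-max normalization, then (optionally) channel
#' standardization + correlation PCA + projection onto the retained
#' components, then the same normalization again so every output channel
#' lies in `[0, 1]`. With `use_pca = FALSE` (or a single-channel input) only
#' the first normalization applies. PCA is fitted on the full series passed
#' in; fitting per window is the caller's choice of slicing.
#'
#' @inheritParams flip_minmax_normalize
#' @param use_pca logical; run the PCA reduction step.
#' @param threshold explained-variance retention target, default 0.85.
#' @param m_override optional fixed number of components.
#' @return matrix (channels x samples) with entries in `[0, 1]`.
#' @export
preprocess_chain <- function(x, use_pca = TRUE, threshold = 0.85,
                             m_override = NULL,
                             const_action = c("error", "zero")) {
  const_action <- match.arg(const_action)
  X <- flip_minmax_normalize(x, const_action)
  if (!use_pca || nrow(X) == 1L) return(X)
  std <- standardize_channels(X)
  model <- fit_pca(std, threshold)
  U <- transform_pca(std, model, m_override)
  flip_minmax_normalize(U, const_action)
}
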