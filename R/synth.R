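# Synthetic multichannel fixtures. These stand in for real EEG recordings:
# a small set of latent rhythm sources mixed into many correlated channels,
# plus sensor noise, with a "task" state of deliberately higher ordinal
# diversity than the "rest" state. All generators are seeded and
# deterministic.

.ar2_oscillator <- function(n, freq, fs, r) {
  theta <- 2 * pi * freq / fs
  s <- as.numeric(stats::filter(stats::rnorm(n),
                                c(2 * r * cos(theta), -r * r), "recursive"))
  s / stats::sd(s)
}

# One subject's paired recordings. Latent model: k narrowband AR(2)
# rhythms, shared orthonormal 21 x k mixing per subject, plus white sensor
# noise. The task state raises each source's broadband fraction (eta) and
# adds a gamma-band component; both changes raise ordinal-pattern diversity
# and live in the mixed sources, which is what makes PCA recovery matter.
# Subject-level lognormal jitters create realistic between-subject spread.
.synth_two_regime_pair <- function(m, n, freqs, fs, r, eta_rest, eta_task,
                                   gamma_rest, gamma_task, gamma_freq,
                                   noise_sd, eta_jitter, gamma_jitter,
                                   noise_jitter) {
  k <- length(freqs)
  Q <- qr.Q(qr(matrix(stats::rnorm(m * k), m, k)))
  ej <- exp(stats::rnorm(1L, 0, eta_jitter))
  gj <- exp(stats::rnorm(1L, 0, gamma_jitter))
  nj <- noise_sd * exp(stats::rnorm(1L, 0, noise_jitter))
  make_state <- function(eta, gamma_amp) {
    S <- do.call(rbind, lapply(freqs, function(f)
      .ar2_oscillator(n, f, fs, r) +
        gamma_amp * gj * .ar2_oscillator(n, gamma_freq, fs, r) +
        eta * ej * stats::rnorm(n)))
    Q %*% S + nj * matrix(stats::rnorm(m * n), m, n)
  }
  list(rest = make_state(eta_rest, gamma_rest),
       task = make_state(eta_task, gamma_task))
}

#' Generate a synthetic multichannel series
#'
#' Three fixture kinds:
#' \describe{
#'   \item{`iid_uniform`}{`m` independent channels of i.i.d. uniform noise
#'     (the maximum-entropy reference).}
#'   \item{`common_source`}{`k` latent narrowband rhythm sources mixed into
#'     `m` correlated channels through an orthonormal mixing matrix, plus
#'     white sensor noise. The correlation matrix is approximately rank
#'     `k`, so the 85 percent PCA rule retains about `k` components.}
#'   \item{`two_regime_eeg`}{a paired pair of recordings (`rest`, `task`)
#'     for one subject; the task state has strictly higher ordinal-pattern
#'     diversity (larger broadband fraction plus an added gamma-band
#'     rhythm). Returned as a list of two matrices.}
#' }
#'
#' @param kind fixture kind, see above.
#' @param m number of channels.
#' @param n number of samples (at least 100).
#' @param seed mandatory integer seed; identical calls are bit-identical.
#' @param k number of latent sources (`common_source`, `two_regime_eeg`).
#' @param ... tuning parameters forwarded to the generator; see
#'   [synth_eeg_study()] for the two-regime defaults.
#' @return an `m x n` matrix, or for `two_regime_eeg` a list with elements
#'   `rest` and `task` (each `m x n`).
#' @export
synth_series <- function(kind = c("iid_uniform", "common_source",
                                  "two_regime_eeg"),
                         m, n, seed, k = 4L, ...) {
  kind <- match.arg(kind)
  stopifnot(m >= 1, n >= 100)
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` is mandatory", call. = FALSE)
  set.seed(as.integer(seed))
  switch(kind,
    iid_uniform = matrix(stats::runif(m * n), m, n),
    common_source = {
      args <- list(...)
      fs <- args$fs %||% 500
      freqs <- args$freqs %||% (8 + 4 * seq_len(k))
      r <- args$r %||% 0.998
      noise_sd <- args$noise_sd %||% 0.1
      Q <- qr.Q(qr(matrix(stats::rnorm(m * k), m, k)))
      S <- do.call(rbind, lapply(freqs, function(f)
        .ar2_oscillator(n, f, fs, r)))
      Q %*% S + noise_sd * matrix(stats::rnorm(m * n), m, n)
    },
    two_regime_eeg = {
      defs <- .two_regime_defaults()
      args <- utils::modifyList(defs, list(...))
      .synth_two_regime_pair(m, n, args$freqs, args$fs, args$r,
                             args$eta_rest, args$eta_task,
                             args$gamma_rest, args$gamma_task,
                             args$gamma_freq, args$noise_sd,
                             args$eta_jitter, args$gamma_jitter,
                             args$noise_jitter)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.two_regime_defaults <- function() {
  list(freqs = c(8, 10, 12, 20), fs = 500, r = 0.998,
       eta_rest = 0.015, eta_task = 0.04,
       gamma_rest = 0.05, gamma_task = 0.3, gamma_freq = 40,
       noise_sd = 0.03,
       eta_jitter = 0.15, gamma_jitter = 0.2, noise_jitter = 0.15)
}

#' Generate a full synthetic two-state EEG study
#'
#' Builds paired `rest` / `task` records for `n_subjects` subjects from the
#' `two_regime_eeg` generator. Each subject gets its own mixing matrix and
#' lognormal jitters on the noise levels (shared between the two states, so
#' the state contrast is within-subject); the task state has a larger
#' broadband fraction and an added 40 Hz gamma component in every latent
#' source.
#'
#' The defaults emulate the conditions of a mental-arithmetic EEG protocol:
#' 36 subjects, 21 channels, 31,000 samples at a nominal 500 Hz, four
#' latent alpha/beta-band rhythm sources.
#'
#' @param n_subjects number of subjects (default 36).
#' @param n_channels channels per record (default 21).
#' @param n_samples samples per record (default 31000).
#' @param seed mandatory integer seed.
#' @param ... overrides for the generator parameters (`freqs`, `fs`, `r`,
#'   `eta_rest`, `eta_task`, `gamma_rest`, `gamma_task`, `gamma_freq`,
#'   `noise_sd`, `eta_jitter`, `gamma_jitter`, `noise_jitter`).
#' @return a list of `2 * n_subjects` subject records, each a list with
#'   `subject_id`, `state` (`"before"` or `"during"`) and `series`
#'   (channels x samples matrix).
#' @export
synth_eeg_study <- function(n_subjects = 36L, n_channels = 21L,
                            n_samples = 31000L, seed, ...) {
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` is mandatory", call. = FALSE)
  stopifnot(n_subjects >= 2, n_channels >= 1, n_samples >= 100)
  defs <- utils::modifyList(.two_regime_defaults(), list(...))
  set.seed(as.integer(seed))
  records <- vector("list", 2L * n_subjects)
  for (s in seq_len(n_subjects)) {
    pair <- .synth_two_regime_pair(n_channels, n_samples, defs$freqs,
                                   defs$fs, defs$r,
                                   defs$eta_rest, defs$eta_task,
                                   defs$gamma_rest, defs$gamma_task,
                                   defs$gamma_freq, defs$noise_sd,
                                   defs$eta_jitter, defs$gamma_jitter,
                                   defs$noise_jitter)
    records[[2L * s - 1L]] <- subject_record(sprintf("Subject%02d", s),
                                             "before", pair$rest)
    records[[2L * s]] <- subject_record(sprintf("Subject%02d", s),
                                        "during", pair$task)
  }
  records
}

#' Construct a subject record
#'
#' @param subject_id identifier string.
#' @param state `"before"` or `"during"` (the task).
#' @param series channels x samples numeric matrix.
#' @param sampling_rate optional sampling rate in Hz.
#' @return a `subject_record` list.
#' @export
subject_record <- function(subject_id, state = c("before", "during"),
                           series, sampling_rate = NULL) {
  state <- match.arg(state)
  series <- .as_channel_matrix(series, "series")
  structure(list(subject_id = as.character(subject_id), state = state,
                 series = series, sampling_rate = sampling_rate),
            class = "subject_record")
}
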