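# Delimited-text I/O for channel matrices, JSON result serialization, and
# run configuration with file + flag resolution.

#' Read a channels-by-samples matrix from delimited text
#'
#' Expects one channel per row. If the first column is non-numeric it is
#' taken as channel labels. The delimiter is explicit, never sniffed.
#'
#' @param path file path.
#' @param delim field delimiter, default `","` (use `"\t"` for TSV).
#' @return numeric matrix with `rownames` set to the channel labels when
#'   present.
#' @export
read_series_csv <- function(path, delim = ",") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = delim, header = "auto",
                          data.table = FALSE)
  labels <- NULL
  if (ncol(dt) > 1L && !is.numeric(dt[[1L]])) {
    labels <- as.character(dt[[1L]])
    dt <- dt[, -1L, drop = FALSE]
  }
  X <- as.matrix(dt)
  if (!is.numeric(X)) stop("non-numeric data in ", path, call. = FALSE)
  dimnames(X) <- NULL
  if (!is.null(labels)) rownames(X) <- labels
  X
}

#' Write a channels-by-samples matrix as delimited text
#'
#' @param x numeric matrix, channels in rows. Row names, or `labels`,
#'   become a leading `channel` column.
#' @param path output path.
#' @param delim field delimiter.
#' @param labels optional channel labels overriding row names.
#' @export
write_series_csv <- function(x, path, delim = ",", labels = NULL) {
  X <- .as_channel_matrix(x)
  if (is.null(labels)) labels <- rownames(X)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(X)))
  df <- data.frame(channel = labels, X, check.names = FALSE)
  colnames(df) <- c("channel", paste0("s", seq_len(ncol(X))))
  data.table::fwrite(df, path, sep = delim)
  invisible(path)
}

#' Write results as JSON (full precision, round-trippable)
#'
#' @param x a list (or result object coercible to one).
#' @param path output path.
#' @export
write_results_json <- function(x, path) {
  if (inherits(x, "two_state_study")) x <- unclass(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read back a JSON results file
#' @param path file path.
#' @return the parsed list.
#' @export
read_results_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export study window values in long format
#'
#' One row per subject / state / window — the boxplot-ready layout.
#'
#' @param study a `two_state_study`.
#' @return data.frame with columns `subject`, `state`, `window`, `value`.
#' @export
study_long_format <- function(study) {
  stopifnot(inherits(study, "two_state_study"))
  rows <- lapply(c("before", "during"), function(st) {
    M <- study$window_values[[st]]
    data.frame(subject = rep(study$subject_ids, each = ncol(M)),
               state = st,
               window = rep(seq_len(ncol(M)), times = nrow(M)),
               value = as.vector(t(M)))
  })
  do.call(rbind, rows)
}

#' Reference run configuration
#'
#' Defaults matching the reference study settings: MMPE at `d = 4`, PCA
#' enabled with threshold 0.85 and 4 components fixed, windows
#' 10,000 / 500 / 40, the standard 2D-SIMM sweep grid and Lorenz
#' integration step.
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    estimator = "MMPE",
    d = 4L,
    pca = list(enabled = TRUE, threshold = 0.85, m_override = 4L),
    window = list(length = 10000L, step = 500L, max_windows = 40L),
    simm2d = list(a = 1, b = 3, omega = pi, x0 = 0.45, y0 = 0.95,
                  n = 10000L, transient = 1000L,
                  sweep_from = 0.4, sweep_to = 4, sweep_step = 0.0064),
    lorenz = list(c_par = 2, h = 0.01, n = 20000L, transient = 10000L,
                  tau = 1L, init = c(1, 1, 1)),
    seed = NULL)
}

.check_known_keys <- function(cfg, ref, prefix = "") {
  for (key in names(cfg)) {
    if (!key %in% names(ref))
      stop("unknown configuration key: ", prefix, key, call. = FALSE)
    if (is.list(ref[[key]]) && is.list(cfg[[key]]))
      .check_known_keys(cfg[[key]], ref[[key]], paste0(prefix, key, "."))
  }
}

#' Resolve a run configuration from file and overrides
#'
#' Starts from [default_config()], merges a YAML config file when given,
#' then merges explicit overrides (command-line flags take precedence over
#' the file). Unknown keys and out-of-range values are rejected with a
#' message naming the key.
#'
#' @param file optional YAML file path.
#' @param overrides named list of overrides (possibly nested).
#' @return the resolved, validated configuration list.
#' @export
resolve_config <- function(file = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("no such config file: ", file, call. = FALSE)
    fromfile <- yaml::read_yaml(file)
    if (length(fromfile)) {
      .check_known_keys(fromfile, cfg)
      cfg <- utils::modifyList(cfg, fromfile)
    }
  }
  if (length(overrides)) {
    .check_known_keys(overrides, cfg)
    cfg <- utils::modifyList(cfg, overrides)
  }
  if (!cfg$estimator %in% c("PE", "MPE", "MMPE"))
    stop("estimator: must be one of PE, MPE, MMPE", call. = FALSE)
  .check_embedding_dim(cfg$d)
  with(cfg$pca, {
    if (threshold <= 0 || threshold > 1)
      stop("pca.threshold: must be in (0, 1]", call. = FALSE)
    if (!is.null(m_override) && (m_override < 1 || m_override != round(m_override)))
      stop("pca.m_override: must be a positive integer", call. = FALSE)
  })
  with(cfg$window, {
    if (length < 1 || step < 1 || max_windows < 1)
      stop("window: length, step and max_windows must be positive",
           call. = FALSE)
  })
  if (cfg$lorenz$h <= 0) stop("lorenz.h: must be positive", call. = FALSE)
  if (cfg$lorenz$tau < 1 || cfg$lorenz$tau != round(cfg$lorenz$tau))
    stop("lorenz.tau: must be a positive integer", call. = FALSE)
  cfg
}
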