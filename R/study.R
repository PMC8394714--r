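# Two-state group statistics: one-way ANOVA (written out as the textbook
# decomposition so the core statistic has no hidden dependency), a
# normality screen, the full windowed two-state study, and the
# random-channel control experiment.

#' One-way ANOVA for two groups
#'
#' Standard one-way decomposition (between-group / error / total) for two
#' independent groups, laid out as a Columns / Error / Total table. For two
#' groups the F statistic equals the square of the pooled two-sample t
#' statistic.
#'
#' @param group_b,group_d numeric vectors with at least 2 finite values
#'   each.
#' @return an object of class `anova_oneway`: list with the `table`
#'   (data.frame with columns `source`, `SS`, `df`, `MS`, `F`, `p`) and
#'   shortcuts `F`, `p`, `ss_columns`, `ss_error`, `ss_total`.
#' @examples
#' anova_oneway(c(1, 2, 3), c(2, 3, 4))$F  # 1.5
#' @export
anova_oneway <- function(group_b, group_d) {
  g1 <- as.numeric(group_b); g2 <- as.numeric(group_d)
  if (length(g1) < 2L || length(g2) < 2L || !all(is.finite(c(g1, g2))))
    stop("each group needs at least 2 finite values", call. = FALSE)
  all_v <- c(g1, g2)
  grand <- mean(all_v)
  ss_total <- sum((all_v - grand)^2)
  if (ss_total == 0)
    stop("all values identical across both groups: F undefined",
         call. = FALSE)
  ss_col <- length(g1) * (mean(g1) - grand)^2 +
            length(g2) * (mean(g2) - grand)^2
  ss_err <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  df_col <- 1L
  df_err <- length(all_v) - 2L
  ms_col <- ss_col / df_col
  ms_err <- ss_err / df_err
  f_stat <- if (ms_err == 0) Inf else ms_col / ms_err
  p <- stats::pf(f_stat, df_col, df_err, lower.tail = FALSE)
  tab <- data.frame(
    source = c("Columns", "Error", "Total"),
    SS = c(ss_col, ss_err, ss_total),
    df = c(df_col, df_err, df_col + df_err),
    MS = c(ms_col, ms_err, NA_real_),
    F = c(f_stat, NA_real_, NA_real_),
    p = c(p, NA_real_, NA_real_))
  structure(list(table = tab, F = f_stat, p = p,
                 ss_columns = ss_col, ss_error = ss_err, ss_total = ss_total,
                 df = c(columns = df_col, error = df_err,
                        total = df_col + df_err)),
            class = "anova_oneway")
}

#' @export
print.anova_oneway <- function(x, ...) {
  tab <- x$table
  tab$SS <- signif(tab$SS, 5); tab$MS <- signif(tab$MS, 5)
  tab$F <- signif(tab$F, 5); tab$p <- signif(tab$p, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Normality screen for a sample
#'
#' Shapiro-Wilk test, reported for inspection only — the analysis pipeline
#' never gates on it.
#'
#' @param values numeric vector with at least 8 finite, non-constant
#'   values.
#' @return list with `statistic` (W), `p_value`, `n`, `method`.
#' @export
normality_screen <- function(values) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) < 8L)
    stop("need at least 8 finite values", call. = FALSE)
  if (stats::sd(v) == 0)
    stop("constant sample: normality test undefined", call. = FALSE)
  sw <- stats::shapiro.test(v)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       n = length(v), method = "Shapiro-Wilk")
}

.split_states <- function(records) {
  stopifnot(length(records) >= 4L)
  states <- vapply(records, function(r) r$state, "")
  ids <- vapply(records, function(r) r$subject_id, "")
  before <- records[states == "before"]
  during <- records[states == "during"]
  idb <- vapply(before, function(r) r$subject_id, "")
  idd <- vapply(during, function(r) r$subject_id, "")
  if (!setequal(idb, idd))
    stop("before/during records are not paired by subject_id", call. = FALSE)
  during <- during[match(idb, idd)]
  list(before = before, during = during, subject_ids = idb)
}

#' Run the windowed two-state study
#'
#' For every subject record, computes per-window entropies with
#' [windowed_entropy()], takes the per-subject mean over windows, and
#' compares the before-task and during-task mean vectors with the one-way
#' ANOVA. Normality of each group of means is screened (reported only).
#'
#' @param records list of [subject_record()]s covering both states for the
#'   same set of subjects.
#' @param estimator,d,use_pca,threshold,m_override,scope,length,step,max_windows
#'   passed to [windowed_entropy()]; the defaults (`MMPE`, `d = 4`, PCA
#'   fixed at 4 components, 10,000 / 500 / 40 windows) are the reference
#'   study settings.
#' @return an object of class `two_state_study`: list with
#'   `window_values` (per state: subjects x windows matrix),
#'   `subject_means` (per state), `anova` (an `anova_oneway`),
#'   `normality` (per state), `subject_ids`, and the settings used.
#' @export
run_two_state_study <- function(records, estimator = "MMPE", d = 4,
                                use_pca = TRUE, threshold = 0.85,
                                m_override = 4L, scope = "record",
                                length = 10000, step = 500,
                                max_windows = 40) {
  sp <- .split_states(records)
  per_state <- lapply(sp[c("before", "during")], function(recs) {
    vals <- lapply(recs, function(r)
      windowed_entropy(r$series, estimator = estimator, d = d,
                       use_pca = use_pca, threshold = threshold,
                       m_override = m_override, scope = scope,
                       length = length, step = step,
                       max_windows = max_windows)$values)
    do.call(rbind, vals)
  })
  means <- lapply(per_state, rowMeans)
  aov1 <- anova_oneway(means$before, means$during)
  norm <- lapply(means, function(v)
    tryCatch(normality_screen(v), error = function(e) NULL))
  structure(
    list(window_values = per_state, subject_means = means, anova = aov1,
         normality = norm, subject_ids = sp$subject_ids,
         settings = list(estimator = estimator, d = d, use_pca = use_pca,
                         threshold = threshold, m_override = m_override,
                         scope = scope, length = length, step = step,
                         max_windows = max_windows)),
    class = "two_state_study")
}

#' @export
print.two_state_study <- function(x, ...) {
  cat(sprintf("Two-state study: %s(d = %s), %d subjects, %d windows/record\n",
              x$settings$estimator, x$settings$d,
              length(x$subject_ids), ncol(x$window_values$before)))
  cat(sprintf("mean before = %.4f, mean during = %.4f\n",
              mean(x$subject_means$before), mean(x$subject_means$during)))
  print(x$anova)
  invisible(x)
}

#' Random-channel control experiment
#'
#' Repeatedly draws `n_channels` channels at random (the same channels for
#' every subject within a repeat), skips the PCA reduction, reruns the full
#' windowed study on the raw channel subset, and records the ANOVA p-value.
#' Comparing the failure rate (p > 0.05) against the PCA pipeline shows
#' whether the channel-fusion step is necessary.
#'
#' @param records as in [run_two_state_study()].
#' @param n_channels channels drawn per repeat (default 4).
#' @param repeats number of random draws (default 50).
#' @param seed mandatory integer seed for the channel draws.
#' @param ... further settings passed to [run_two_state_study()]
#'   (`estimator`, `d`, window plan, ...); `use_pca` is forced off.
#' @return list with `p_values` (length `repeats`), `channels` (repeats x
#'   n_channels matrix of drawn indices), `min_p` and `frac_above_05`.
#' @export
random_channel_experiment <- function(records, n_channels = 4L,
                                      repeats = 50L, seed, ...) {
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` is mandatory", call. = FALSE)
  m <- nrow(records[[1L]]$series)
  if (m < n_channels)
    stop("records have ", m, " channels; cannot draw ", n_channels,
         call. = FALSE)
  set.seed(as.integer(seed))
  draws <- t(replicate(repeats, sample.int(m, n_channels)))
  p_values <- vapply(seq_len(repeats), function(r) {
    subset <- lapply(records, function(rec)
      subject_record(rec$subject_id, rec$state,
                     rec$series[draws[r, ], , drop = FALSE]))
    run_two_state_study(subset, use_pca = FALSE, m_override = NULL,
                        ...)$anova$p
  }, numeric(1))
  list(p_values = p_values, channels = draws, min_p = min(p_values),
       frac_above_05 = mean(p_values > 0.05))
}
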