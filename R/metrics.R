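# Descriptive behavioral surface: optimal-response proportions per
# subject x block x valence, group summaries, and per-group one-sample
# chance tests.

#' Optimal-response proportions by subject, block and valence
#'
#' Aggregates the per-trial `optimal` flags of one or more session logs into
#' the standard cell structure. Top-up trials are excluded. Under the default
#' task every cell holds 20 trials (2 stimuli per valence x 10 repetitions).
#'
#' @param logs A session log or a list of session logs.
#' @return A data frame with columns `subject_id`, `group`, `block`,
#'   `valence`, `n_trials`, `n_optimal`, `proportion_optimal`.
#' @export
accuracy_table <- function(logs) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  df <- do.call(rbind, lapply(logs, as.data.frame))
  needed <- c("subject_id", "group", "block", "valence", "optimal", "topup")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("malformed log: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[!df$topup, ]
  agg <- stats::aggregate(
    cbind(n_trials = rep(1L, nrow(df)), n_optimal = as.integer(df$optimal)),
    by = df[c("subject_id", "group", "block", "valence")], FUN = sum
  )
  agg$proportion_optimal <- agg$n_optimal / agg$n_trials
  agg <- agg[order(agg$subject_id, agg$block, agg$valence), ]
  rownames(agg) <- NULL
  agg
}

#' Group-level mean and SEM of optimal responding
#'
#' @param table An [accuracy_table()].
#' @return A data frame per group x block x valence with `n_subjects`,
#'   `mean_proportion` and `sem` (0 for a single subject, by convention).
#' @export
group_summary <- function(table) {
  if (nrow(table) == 0L) stop("empty accuracy table", call. = FALSE)
  agg <- stats::aggregate(
    proportion_optimal ~ group + block + valence, data = table,
    FUN = function(x) c(n = length(x), mean = mean(x),
                        sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                              else 0)
  )
  out <- data.frame(
    group = agg$group, block = agg$block, valence = agg$valence,
    n_subjects = agg$proportion_optimal[, "n"],
    mean_proportion = agg$proportion_optimal[, "mean"],
    sem = agg$proportion_optimal[, "sem"]
  )
  out <- out[order(out$valence, out$group, out$block), ]
  rownames(out) <- NULL
  out
}

#' One-sample chance tests per group and valence
#'
#' Each subject's accuracy is the mean of their block-wise optimal-response
#' proportions for that valence; each group x valence cell is then tested
#' against the chance level with a one-sample t-test. The Bonferroni-adjusted
#' significance level across the four groups (alpha = 0.05 / 4 = 0.0125) is
#' reported alongside. Cells with zero variance are flagged `degenerate` (the
#' t statistic diverges) rather than tested.
#'
#' @param table An [accuracy_table()].
#' @param null Chance level (0.5 for a two-option task).
#' @param alpha_adjusted The Bonferroni-corrected significance level to
#'   report.
#' @return A data frame per group x valence: `n`, `mean_accuracy`,
#'   `t`, `df`, `p_value`, `alpha_adjusted`, `significant`, `degenerate`.
#' @export
chance_test <- function(table, null = 0.5, alpha_adjusted = 0.0125) {
  per_subj <- stats::aggregate(
    proportion_optimal ~ subject_id + group + valence, data = table,
    FUN = mean
  )
  cells <- unique(per_subj[c("group", "valence")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    x <- per_subj$proportion_optimal[
      per_subj$group == cells$group[i] & per_subj$valence == cells$valence[i]]
    if (length(x) < 2)
      stop("need at least 2 subjects per group for a chance test",
           call. = FALSE)
    if (stats::sd(x) == 0) {
      data.frame(group = cells$group[i], valence = cells$valence[i],
                 n = length(x), mean_accuracy = mean(x),
                 t = if (mean(x) == null) 0 else Inf * sign(mean(x) - null),
                 df = length(x) - 1L, p_value = NA_real_,
                 alpha_adjusted = alpha_adjusted,
                 significant = NA, degenerate = TRUE)
    } else {
      tt <- stats::t.test(x, mu = null)
      data.frame(group = cells$group[i], valence = cells$valence[i],
                 n = length(x), mean_accuracy = mean(x),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, alpha_adjusted = alpha_adjusted,
                 significant = tt$p.value < alpha_adjusted,
                 degenerate = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$valence, out$group), ]
  rownames(out) <- NULL
  out
}

#' Learning-curve plot (group mean +/- SEM by block and valence)
#'
#' A rendering hook for the group summary; requires ggplot2.
#'
#' @param summary A [group_summary()] table.
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_learning_curves() requires ggplot2", call. = FALSE)
  ggplot2::ggplot(summary, ggplot2::aes(
    x = block, y = mean_proportion, colour = group, group = group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = mean_proportion - sem, ymax = mean_proportion + sem)) +
    ggplot2::facet_wrap(~valence) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "Block", y = "Proportion optimal responses",
                  colour = "Group")
}

utils::globalVariables(c("block", "mean_proportion", "group", "sem",
                         "proportion_optimal", "valence"))
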