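## Behavioral scoring and statistics -----------------------------------------

#' Score comprehension-question accuracy
#'
#' Accuracy is the average correct response across all questions and
#' trials, per participant and condition.
#'
#' @param tbl answer table: data frame with columns `participant_id`,
#'   `trial_id`, `condition`, `question`, `correct`.
#' @return data frame with columns `participant_id`, `condition`,
#'   `accuracy`, sorted by participant then condition.
#' @export
score_accuracy <- function(tbl) {
  stop_if_not(is.data.frame(tbl) && nrow(tbl) > 0, "`tbl` must be a non-empty data frame")
  stop_if_not(all(c("participant_id", "condition", "correct") %in% names(tbl)),
              "`tbl` must have participant_id, condition and correct columns")
  agg <- stats::aggregate(correct ~ participant_id + condition, tbl, mean)
  names(agg)[3] <- "accuracy"
  # every participant must appear in every condition present in the table
  counts <- table(agg$participant_id)
  n_cond <- length(unique(agg$condition))
  stop_if_not(all(counts == n_cond),
              "participant(s) %s have no trials in some condition",
              paste(names(counts)[counts != n_cond], collapse = ", "))
  agg[order(agg$participant_id, agg$condition), ]
}

#' One-sample t-test of accuracies against chance
#'
#' Chance for 3-alternative questions is exactly 1/3 (0.33 is display
#' rounding only).
#'
#' @param accuracies per-participant accuracy values.
#' @param chance chance level (default 1/3).
#' @return list with `t`, `df`, `p` (two-sided), `mean`, `sd`. If the
#'   accuracies have zero variance the result is flagged with
#'   `degenerate = TRUE` (t is `Inf`, 0 or undefined).
#' @export
test_vs_chance <- function(accuracies, chance = 1 / 3) {
  n <- length(accuracies)
  stop_if_not(n >= 2, "need at least 2 participants")
  m <- mean(accuracies); s <- stats::sd(accuracies)
  if (s == 0) {
    return(list(t = if (m == chance) 0 else sign(m - chance) * Inf,
                df = n - 1L, p = if (m == chance) 1 else 0,
                mean = m, sd = s, degenerate = TRUE))
  }
  t <- (m - chance) / (s / sqrt(n))
  list(t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), df = n - 1),
       mean = m, sd = s, degenerate = FALSE)
}

#' Median split of behavior by the neural phrase-level response
#'
#' Splits participants at the median of their (channel-averaged) 1 Hz
#' ITPC in the Structured condition and compares behavior between the
#' high and low groups with two-sample t-tests (two-tailed): once on
#' Structured-condition accuracy and once on the Structured minus
#' Non-Structured accuracy difference. With an odd number of
#' participants, the median participant is assigned to the lower group.
#'
#' @param accuracy_structured per-participant Structured accuracy.
#' @param accuracy_nonstructured per-participant Non-Structured accuracy.
#' @param itpc_1hz per-participant 1 Hz ITPC (Structured, channel-averaged).
#' @return list with `groups` (factor "low"/"high"), and for each of
#'   `structured` and `difference`: group means, `t`, `df`, `p`.
#' @export
median_split_by_neural <- function(accuracy_structured, accuracy_nonstructured,
                                   itpc_1hz) {
  n <- length(itpc_1hz)
  stop_if_not(length(accuracy_structured) == n &&
                length(accuracy_nonstructured) == n,
              "inputs must cover the same participants")
  stop_if_not(n >= 4, "need at least 4 participants")
  ord <- order(itpc_1hz)
  groups <- rep("high", n)
  groups[ord[seq_len(ceiling(n / 2))]] <- "low" # median ties to the lower group
  groups <- factor(groups, levels = c("low", "high"))
  two_sample <- function(x) {
    lo <- x[groups == "low"]; hi <- x[groups == "high"]
    df <- n - 2L
    sp2 <- ((length(lo) - 1) * stats::var(lo) + (length(hi) - 1) * stats::var(hi)) / df
    se <- sqrt(sp2 * (1 / length(lo) + 1 / length(hi)))
    dm <- mean(hi) - mean(lo)
    t <- if (se == 0) { if (dm == 0) 0 else sign(dm) * Inf } else dm / se
    p <- if (is.infinite(t)) 0 else if (se == 0) 1 else 2 * stats::pt(-abs(t), df)
    list(mean_low = mean(lo), mean_high = mean(hi), t = t, df = df, p = p)
  }
  list(groups = groups,
       structured = two_sample(accuracy_structured),
       difference = two_sample(accuracy_structured - accuracy_nonstructured))
}
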