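# Team/reader performance metrics. All metric functions take and return
# percentages; abnormal (1) is the positive class. Undefined metrics (empty
# gold stratum) are NA, never an error.

#' Accuracy, sensitivity and specificity from paired decisions and gold
#'
#' Accuracy is correct cases over all cases; sensitivity true positives over
#' gold-abnormal cases; specificity true negatives over gold-normal cases. A
#' metric whose gold stratum is empty is returned as `NA` (undefined).
#'
#' @param decisions,gold Equal-length 0/1 vectors (1 = abnormal = positive).
#' @return One-row tibble with `accuracy`, `sensitivity`, `specificity` in
#'   percent.
#' @export
confusion_metrics <- function(decisions, gold) {
  if (length(decisions) != length(gold) || length(gold) < 1L) {
    stop("`decisions` and `gold` must be nonempty vectors of equal length",
         call. = FALSE)
  }
  if (!all(decisions %in% c(0L, 1L)) || !all(gold %in% c(0L, 1L))) {
    stop("`decisions` and `gold` must be coded 0/1", call. = FALSE)
  }
  pos <- gold == 1L
  tibble::tibble(
    accuracy = 100 * mean(decisions == gold),
    sensitivity = if (any(pos)) 100 * mean(decisions[pos] == 1L) else NA_real_,
    specificity = if (any(!pos)) 100 * mean(decisions[!pos] == 0L) else NA_real_
  )
}

#' Efficiency: correct decisions per individual judgment elicited
#'
#' The workload-normalized accuracy: the number of correctly decided cases
#' divided by the total number of single judgments the protocol elicited
#' across all cases. Since every case costs at least one judgment, efficiency
#' never exceeds accuracy.
#'
#' @param n_correct Count of correctly decided cases.
#' @param total_judgments Total individual judgments (> 0).
#' @return Efficiency in percent.
#' @export
efficiency <- function(n_correct, total_judgments) {
  if (length(n_correct) != 1L || length(total_judgments) != 1L ||
      !is.finite(n_correct) || !is.finite(total_judgments) ||
      n_correct < 0 || total_judgments <= 0 || n_correct > total_judgments) {
    stop("need 0 <= n_correct <= total_judgments with total_judgments > 0",
         call. = FALSE)
  }
  100 * n_correct / total_judgments
}

#' Harmonic mean of sensitivity and specificity
#'
#' `2ab/(a + b)`, the 1-order harmonic mean, reported by the study under the
#' label "F1 score". Zero if either argument is zero (continuity limit).
#'
#' @param sens,spec Percentages.
#' @return Percentage.
#' @export
harmonic_mean_1 <- function(sens, spec) {
  ifelse(sens <= 0 | spec <= 0, 0, 2 * sens * spec / (sens + spec))
}

#' 2-order harmonic mean of accuracy and efficiency
#'
#' `5 * acc * eff / (acc + 4 * eff)`: an F-beta-style mean with beta = 2,
#' weighting efficiency higher than accuracy.
#'
#' @param acc,eff Percentages, not both zero.
#' @return Percentage.
#' @export
f2_acc_eff <- function(acc, eff) {
  if (any(acc < 0 | eff < 0, na.rm = TRUE)) {
    stop("`acc` and `eff` must be >= 0", call. = FALSE)
  }
  if (any(acc == 0 & eff == 0, na.rm = TRUE)) {
    stop("`acc` and `eff` must not both be zero", call. = FALSE)
  }
  5 * acc * eff / (acc + 4 * eff)
}

#' The six-metric set for one sequence of team outcomes
#'
#' @param decisions,gold Equal-length 0/1 vectors.
#' @param judgments Per-case judgment counts (>= 1).
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `efficiency`, `hm_sens_spec`, `f2_acc_eff`, all in percent.
#' @export
metric_set <- function(decisions, gold, judgments) {
  if (length(judgments) != length(gold) || any(judgments < 1L)) {
    stop("`judgments` must align with cases and be >= 1", call. = FALSE)
  }
  cm <- confusion_metrics(decisions, gold)
  eff <- efficiency(sum(decisions == gold), sum(judgments))
  cm$efficiency <- eff
  cm$hm_sens_spec <- harmonic_mean_1(cm$sensitivity, cm$specificity)
  cm$f2_acc_eff <- f2_acc_eff(cm$accuracy, eff)
  cm
}
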