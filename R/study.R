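# Published operating points of the knee-MRI double-reading study that this
# package emulates. These numbers are inputs to the analysis (they parametrise
# the synthetic panel and the reader-statistics reproduction), not outputs.

#' Accuracies of the ten retained study radiologists
#'
#' Panel accuracies (in percent, against the MRNet gold standard) of the ten
#' radiologists retained after outlier trimming in the knee-lesion
#' double-reading study. Two further readers (86.18% and 77.52%) were discarded
#' as the most and least accurate outliers; see [trim_outlier_readers()].
#'
#' @param include_outliers if `TRUE`, append the two trimmed outlier readers,
#'   giving the original 12-reader panel.
#' @return Named numeric vector of accuracies in percent.
#' @examples
#' mean(study_reader_accuracies())  # 80.77
#' @export
study_reader_accuracies <- function(include_outliers = FALSE) {
  acc <- c(
    reader01 = 81.26, reader02 = 79.39, reader03 = 81.50, reader04 = 78.69,
    reader05 = 79.16, reader06 = 84.07, reader07 = 79.86, reader08 = 81.97,
    reader09 = 78.92, reader10 = 82.90
  )
  if (include_outliers) {
    acc <- c(acc, reader_best_outlier = 86.18, reader_worst_outlier = 77.52)
  }
  acc
}

#' Study design constants
#'
#' Fixed design quantities of the emulated study: the number of annotated
#' cases, the size of the image repository they were sampled from, the case
#' prevalence target ("balanced"), and the confidence-gap and complexity
#' thresholds `tau` and `delta` used by the cautious protocol (the study set
#' them to the panel mean confidence difference and mean reported complexity,
#' 0.17 and 0.70 respectively).
#'
#' @return Named list with `n_cases`, `n_repository`, `prevalence`, `tau`,
#'   `delta`.
#' @export
study_design <- function() {
  list(
    n_cases = 427L,
    n_repository = 1129L,
    prevalence = 0.5,
    tau = 0.17,
    delta = 0.70
  )
}

#' Canonical protocol identifiers
#'
#' The eight double-reading protocol identifiers used throughout configuration
#' and reports, in the package's canonical order.
#'
#' @return Character vector of length 8.
#' @export
protocol_ids <- function() {
  c("majority", "acc_weighted", "conf_weighted", "specific",
    "sensitive", "cautious", "presumptuous", "or_rule")
}

#' Canonical metric identifiers
#'
#' The six team-performance metrics: accuracy, sensitivity, specificity,
#' efficiency (correct decisions over total individual judgments), the
#' 1-order harmonic mean of sensitivity and specificity, and the 2-order
#' harmonic mean of accuracy and efficiency.
#'
#' @return Character vector of length 6.
#' @export
metric_ids <- function() {
  c("accuracy", "sensitivity", "specificity", "efficiency",
    "hm_sens_spec", "f2_acc_eff")
}
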