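# Reader profiles: the generative operating characteristics of one human or
# machine reader. A profile's sensitivity/specificity act as the base correct-
# response probability p_base; per-case latent difficulty d depresses it to
# clamp(p_base - difficulty_slope * d, 0, 1), so the marginal accuracy of a
# simulated reader is p_base - difficulty_slope * E[d].

# mean of the latent difficulty distribution, Beta(2, 2), used by the
# generator; profile calibration in default_study_profiles() depends on it
DIFFICULTY_MEAN <- 0.5

#' Create a reader profile
#'
#' @param reader_id Opaque reader label.
#' @param kind `"human"` or `"machine"`.
#' @param sensitivity,specificity Base correct-response probabilities in
#'   \[0, 1\] on abnormal and normal cases respectively.
#' @param difficulty_slope Nonnegative; how strongly per-case latent difficulty
#'   depresses the correct-response probability.
#' @param confidence_bias Real; shifts the reader's ordinal confidence
#'   distribution (positive = more confident).
#' @param target_accuracy Optional expected marginal accuracy in percent at
#'   balanced prevalence (bookkeeping only; `NA` if unspecified).
#' @return One-row tibble with the profile fields.
#' @export
reader_profile <- function(reader_id, kind = c("human", "machine"),
                           sensitivity, specificity,
                           difficulty_slope = 0, confidence_bias = 0,
                           target_accuracy = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(length(reader_id) == 1L, length(sensitivity) == 1L,
            length(specificity) == 1L)
  if (!is.finite(sensitivity) || sensitivity < 0 || sensitivity > 1) {
    stop("`sensitivity` must be a finite probability in [0, 1]", call. = FALSE)
  }
  if (!is.finite(specificity) || specificity < 0 || specificity > 1) {
    stop("`specificity` must be a finite probability in [0, 1]", call. = FALSE)
  }
  if (!is.finite(difficulty_slope) || difficulty_slope < 0) {
    stop("`difficulty_slope` must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(confidence_bias)) {
    stop("`confidence_bias` must be finite", call. = FALSE)
  }
  tibble::tibble(
    reader_id = as.character(reader_id), kind = kind,
    sensitivity = as.numeric(sensitivity),
    specificity = as.numeric(specificity),
    difficulty_slope = as.numeric(difficulty_slope),
    confidence_bias = as.numeric(confidence_bias),
    target_accuracy = as.numeric(target_accuracy)
  )
}

# coerce a list of profiles / profile table to a validated tibble
as_profile_table <- function(profiles) {
  if (is.data.frame(profiles)) {
    tab <- tibble::as_tibble(profiles)
  } else if (is.list(profiles)) {
    tab <- dplyr::bind_rows(profiles)
  } else {
    stop("`profiles` must be a data frame or a list of reader profiles",
         call. = FALSE)
  }
  needed <- c("reader_id", "kind", "sensitivity", "specificity",
              "difficulty_slope", "confidence_bias")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("profile table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"target_accuracy" %in% names(tab)) tab$target_accuracy <- NA_real_
  if (anyDuplicated(tab$reader_id)) {
    stop("duplicated reader_id in profiles", call. = FALSE)
  }
  ok <- is.finite(tab$sensitivity) & tab$sensitivity >= 0 & tab$sensitivity <= 1 &
    is.finite(tab$specificity) & tab$specificity >= 0 & tab$specificity <= 1 &
    is.finite(tab$difficulty_slope) & tab$difficulty_slope >= 0
  if (!all(ok)) {
    stop("non-finite or out-of-range operating characteristics for reader(s): ",
         paste(tab$reader_id[!ok], collapse = ", "), call. = FALSE)
  }
  tab
}

#' Default study reader profiles
#'
#' Twelve profiles emulating the study panel: the ten retained human
#' radiologists calibrated so that each simulated reader's expected marginal
#' accuracy equals its published panel accuracy
#' ([study_reader_accuracies()]); a MobileNet-like machine (the team's second
#' reader) at 81.72% accuracy; and an InceptionV3-like "strong machine"
#' benchmark with sensitivity 94.76% and specificity 76.27%.
#'
#' Humans share a common difficulty slope, so their base probability is the
#' accuracy target plus `difficulty_slope * 0.5` (the mean of the Beta(2, 2)
#' latent difficulty). Machines have slope 0: their published operating points
#' are used verbatim, and machine error is independent of case difficulty.
#' With balanced prevalence the human profiles are symmetric
#' (sensitivity = specificity); the published tables constrain only the
#' machines' asymmetry.
#'
#' @param difficulty_slope Common slope for the human readers (default 0.25).
#' @return Tibble of 12 reader profiles.
#' @examples
#' p <- default_study_profiles()
#' mean(p$target_accuracy[p$kind == "human"])  # 80.77
#' @export
default_study_profiles <- function(difficulty_slope = 0.25) {
  acc <- study_reader_accuracies()
  p_base <- acc / 100 + difficulty_slope * DIFFICULTY_MEAN
  if (any(p_base > 1)) {
    stop("difficulty_slope too large: calibrated base probability exceeds 1",
         call. = FALSE)
  }
  humans <- purrr::map2(names(acc), seq_along(acc), function(id, i) {
    reader_profile(id, "human", p_base[[i]], p_base[[i]],
                   difficulty_slope = difficulty_slope,
                   target_accuracy = acc[[i]])
  })
  machines <- list(
    reader_profile("mobilenet", "machine", 0.8172, 0.8172,
                   difficulty_slope = 0, target_accuracy = 81.72),
    reader_profile("inceptionv3", "machine", 0.9476, 0.7627,
                   difficulty_slope = 0,
                   target_accuracy = (94.76 + 76.27) / 2)
  )
  dplyr::bind_rows(c(humans, machines))
}
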