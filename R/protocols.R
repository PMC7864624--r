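# The eight double-reading protocols. Each maps the ordered team's readings of
# a case (decisions coded 0 = normal, 1 = abnormal; confidences/complexities
# normalized to [0, 1]) to a team decision plus the number of individual
# judgments elicited. All functions are vectorized over cases; the readers
# involved on a case are always the first `judgments` members of the team in
# protocol order.

EPS <- 1e-9  # tolerance for threshold comparisons on the normalized grids

check_decisions <- function(...) {
  ds <- list(...)
  n <- unique(lengths(ds))
  if (length(n) != 1L) stop("decision vectors must have equal length", call. = FALSE)
  for (d in ds) {
    if (!all(d %in% c(0L, 1L))) {
      stop("decisions must be coded 0 (normal) / 1 (abnormal)", call. = FALSE)
    }
  }
  invisible(n)
}

outcome <- function(decision, judgments, fallback = NULL) {
  cols <- list(decision = as.integer(decision),
               judgments = as.integer(judgments))
  if (!is.null(fallback)) cols$fallback <- fallback
  tibble::new_tibble(cols, nrow = length(cols$decision))
}

#' Protocol parameters
#'
#' @param tau Confidence-gap threshold in \[0, 1\] for the cautious protocol
#'   (study value 0.17: the panel mean pairwise confidence difference).
#' @param delta Complexity threshold in \[0, 1\] for the cautious protocol
#'   (study value 0.70: the panel mean reported complexity).
#' @param tie_rule How an exact weight tie is resolved in weighted majorities:
#'   `"abnormal_wins"` (default, errs toward sensitivity) or `"normal_wins"`.
#' @param accuracies Named vector of reader accuracies (any common scale) used
#'   as weights by the accuracy-weighted protocol; if `NULL`, they are
#'   estimated from the panel at evaluation time.
#' @return List of class `protocol_params`.
#' @export
protocol_params <- function(tau = 0.17, delta = 0.70,
                            tie_rule = c("abnormal_wins", "normal_wins"),
                            accuracies = NULL) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(is.finite(tau), tau >= 0, tau <= 1, is.finite(delta),
            delta >= 0, delta <= 1)
  structure(list(tau = tau, delta = delta, tie_rule = tie_rule,
                 accuracies = accuracies),
            class = "protocol_params")
}

#' Simple-majority protocol
#'
#' The first two observers decide; the third is involved if and only if they
#' disagree, and the team decision is the majority of the three.
#'
#' @param d1,d2,d3 Decision vectors (0/1) of the first, second and third
#'   reader on the same cases.
#' @return Tibble with `decision` and `judgments` (2 or 3) per case.
#' @export
simple_majority <- function(d1, d2, d3) {
  check_decisions(d1, d2, d3)
  agree <- d1 == d2
  outcome(ifelse(agree, d1, as.integer(d1 + d2 + d3 >= 2L)),
          ifelse(agree, 2L, 3L))
}

#' Weighted-majority protocols
#'
#' As the simple majority (third reader involved only on disagreement), but the
#' decision among the involved readers is by summed weights per class: reader
#' accuracies for the accuracy-weighted protocol, per-case confidences for the
#' confidence-weighted one. An exact weight tie is resolved by `tie_rule`; if
#' all involved weights are zero the simple majority of the involved readers is
#' used instead (flagged in the `fallback` column).
#'
#' @inheritParams simple_majority
#' @param w1,w2,w3 Nonnegative finite weight vectors (recycled if scalar).
#' @param tie_rule `"abnormal_wins"` or `"normal_wins"`.
#' @return Tibble with `decision`, `judgments` (2 or 3), `fallback`.
#' @export
weighted_majority <- function(d1, d2, d3, w1, w2, w3,
                              tie_rule = c("abnormal_wins", "normal_wins")) {
  tie_rule <- match.arg(tie_rule)
  n <- check_decisions(d1, d2, d3)
  w1 <- rep_len(w1, n); w2 <- rep_len(w2, n); w3 <- rep_len(w3, n)
  if (!all(is.finite(c(w1, w2, w3))) || any(c(w1, w2, w3) < 0)) {
    stop("weights must be finite and >= 0", call. = FALSE)
  }
  agree <- d1 == d2
  # disagreement branch: weigh all three readers
  s_ab <- w1 * d1 + w2 * d2 + w3 * d3
  s_no <- w1 * (1L - d1) + w2 * (1L - d2) + w3 * (1L - d3)
  tie_dec <- if (tie_rule == "abnormal_wins") 1L else 0L
  weighted <- ifelse(s_ab > s_no, 1L, ifelse(s_no > s_ab, 0L, tie_dec))
  zero_w <- (s_ab + s_no) == 0
  maj3 <- as.integer(d1 + d2 + d3 >= 2L)
  dec3 <- ifelse(zero_w, maj3, weighted)
  outcome(ifelse(agree, d1, dec3),
          ifelse(agree, 2L, 3L),
          fallback = !agree & zero_w)
}

#' Specificity-oriented protocol
#'
#' The second observer is involved only if the first deems the case abnormal;
#' a first-two disagreement escalates to the third reader and a best-of-three
#' majority. A first-reader "normal" call closes the case with one judgment.
#'
#' @inheritParams simple_majority
#' @return Tibble with `decision` and `judgments` (1, 2 or 3).
#' @export
specificity_oriented <- function(d1, d2, d3) {
  check_decisions(d1, d2, d3)
  maj3 <- as.integer(d1 + d2 + d3 >= 2L)
  decision <- ifelse(d1 == 0L, 0L, ifelse(d2 == 1L, 1L, maj3))
  judgments <- ifelse(d1 == 0L, 1L, ifelse(d2 == 1L, 2L, 3L))
  outcome(decision, judgments)
}

#' Sensitivity-oriented protocol
#'
#' Label-swap mirror of [specificity_oriented()]: the second observer is
#' involved only if the first deems the case normal; a first-reader "abnormal"
#' call closes the case with one judgment.
#'
#' @inheritParams simple_majority
#' @return Tibble with `decision` and `judgments` (1, 2 or 3).
#' @export
sensitivity_oriented <- function(d1, d2, d3) {
  check_decisions(d1, d2, d3)
  maj3 <- as.integer(d1 + d2 + d3 >= 2L)
  decision <- ifelse(d1 == 1L, 1L, ifelse(d2 == 0L, 0L, maj3))
  judgments <- ifelse(d1 == 1L, 1L, ifelse(d2 == 0L, 2L, 3L))
  outcome(decision, judgments)
}

#' Cautious protocol
#'
#' If the first two readers' confidence gap is at least `tau` and their mean
#' perceived complexity is at most `delta`, the more confident of the two
#' decides (2 judgments); otherwise the third reader is involved and the
#' best-of-three majority decides (3 judgments). At an exact confidence tie
#' that still satisfies the gap condition (possible only when `tau = 0`) the
#' first reader's decision is used.
#'
#' @inheritParams simple_majority
#' @param conf1,conf2 Normalized confidences of the first two readers.
#' @param compl1,compl2 Normalized complexities of the first two readers.
#' @param tau,delta Thresholds in \[0, 1\]; study values 0.17 and 0.70.
#' @return Tibble with `decision` and `judgments` (2 or 3).
#' @export
cautious <- function(d1, d2, d3, conf1, conf2, compl1, compl2,
                     tau = 0.17, delta = 0.70) {
  check_decisions(d1, d2, d3)
  confident <- (abs(conf1 - conf2) >= tau - EPS) &
    ((compl1 + compl2) / 2 <= delta + EPS)
  lead <- ifelse(conf2 > conf1, d2, d1)
  maj3 <- as.integer(d1 + d2 + d3 >= 2L)
  outcome(ifelse(confident, lead, maj3), ifelse(confident, 2L, 3L))
}

#' Presumptuous protocol
#'
#' The strictly more confident of the first two readers decides (2 judgments);
#' at an exact confidence tie the third reader is involved and the
#' best-of-three majority decides (3 judgments).
#'
#' @inheritParams cautious
#' @return Tibble with `decision` and `judgments` (2 or 3).
#' @export
presumptuous <- function(d1, d2, d3, conf1, conf2) {
  check_decisions(d1, d2, d3)
  tie <- abs(conf1 - conf2) < EPS
  lead <- ifelse(conf1 > conf2, d1, d2)
  maj3 <- as.integer(d1 + d2 + d3 >= 2L)
  outcome(ifelse(tie, maj3, lead), ifelse(tie, 3L, 2L))
}

#' OR rule
#'
#' The team flags abnormal if either of the first two readers does: a
#' first-reader "abnormal" closes the case with one judgment; otherwise the
#' second reader's decision stands (2 judgments). The third reader is never
#' involved.
#'
#' @param d1,d2 Decision vectors (0/1) of the first two readers.
#' @return Tibble with `decision` and `judgments` (1 or 2).
#' @export
or_rule <- function(d1, d2) {
  check_decisions(d1, d2)
  outcome(ifelse(d1 == 1L, 1L, d2), ifelse(d1 == 1L, 1L, 2L))
}

#' Simple majority over a full odd-sized reader panel
#'
#' All supplied readers are always consulted; the majority decides. Used for
#' the team-size sweep (1 to 9 readers).
#'
#' @param decisions Matrix (readers x cases) or vector of 0/1 decisions.
#' @return Integer vector of team decisions per case.
#' @export
majority_panel <- function(decisions) {
  if (is.vector(decisions)) decisions <- matrix(decisions, ncol = 1L)
  k <- nrow(decisions)
  if (k %% 2L == 0L) {
    stop("majority_panel needs an odd number of readers", call. = FALSE)
  }
  if (!all(decisions %in% c(0L, 1L))) {
    stop("decisions must be coded 0 (normal) / 1 (abnormal)", call. = FALSE)
  }
  as.integer(colSums(decisions) >= (k + 1L) / 2L)
}

#' Mean pairwise confidence gap of a reader set (tau)
#'
#' Mean, over cases, of the mean absolute difference of normalized confidences
#' over all unordered reader pairs. The study computed this over its ten human
#' readers and froze the result (0.17) as the cautious protocol's `tau`.
#'
#' @param panel A `reader_panel`.
#' @param readers Reader ids (default: the panel's human readers).
#' @return Scalar in \[0, 1\].
#' @export
compute_tau <- function(panel, readers = NULL) {
  if (is.null(readers)) readers <- panel_readers(panel, "human")
  if (length(readers) < 2L) stop("need at least two readers", call. = FALSE)
  conf <- panel_matrix(panel, "confidence", readers)
  pairs <- utils::combn(nrow(conf), 2L)
  gaps <- abs(conf[pairs[1L, ], , drop = FALSE] -
                conf[pairs[2L, ], , drop = FALSE])
  mean(colMeans(gaps))
}

#' Mean reported complexity of a reader set (delta)
#'
#' Mean, over cases and readers, of the normalized complexity. The study froze
#' its panel value (0.70) as the cautious protocol's `delta`.
#'
#' @inheritParams compute_tau
#' @return Scalar in \[0, 1\].
#' @export
compute_delta <- function(panel, readers = NULL) {
  if (is.null(readers)) readers <- panel_readers(panel, "human")
  if (length(readers) < 1L) stop("need at least one reader", call. = FALSE)
  mean(panel_matrix(panel, "complexity", readers))
}

# dispatch a protocol on pre-extracted team reading vectors; `rd` is a list
# with decision/confidence/complexity 3-row matrices (team order) and the
# team's accuracy weights
protocol_outcome <- function(protocol, rd, params) {
  d <- rd$decision
  switch(
    protocol,
    majority = simple_majority(d[1L, ], d[2L, ], d[3L, ]),
    acc_weighted = weighted_majority(d[1L, ], d[2L, ], d[3L, ],
                                     rd$acc[[1L]], rd$acc[[2L]], rd$acc[[3L]],
                                     tie_rule = params$tie_rule),
    conf_weighted = weighted_majority(d[1L, ], d[2L, ], d[3L, ],
                                      rd$confidence[1L, ], rd$confidence[2L, ],
                                      rd$confidence[3L, ],
                                      tie_rule = params$tie_rule),
    specific = specificity_oriented(d[1L, ], d[2L, ], d[3L, ]),
    sensitive = sensitivity_oriented(d[1L, ], d[2L, ], d[3L, ]),
    cautious = cautious(d[1L, ], d[2L, ], d[3L, ],
                        rd$confidence[1L, ], rd$confidence[2L, ],
                        rd$complexity[1L, ], rd$complexity[2L, ],
                        tau = params$tau, delta = params$delta),
    presumptuous = presumptuous(d[1L, ], d[2L, ], d[3L, ],
                                rd$confidence[1L, ], rd$confidence[2L, ]),
    or_rule = or_rule(d[1L, ], d[2L, ])
  )
}

#' Apply a protocol to one team over all panel cases
#'
#' @param panel A `reader_panel`.
#' @param team Character vector `c(first, second, third)` of distinct reader
#'   ids (the study design places the machine second).
#' @param protocol One of [protocol_ids()].
#' @param params A [protocol_params()] object.
#' @return Tibble with `case_id`, `decision`, `judgments`; the involved
#'   readers on a case are the first `judgments` members of `team`.
#' @export
apply_protocol <- function(panel, team, protocol, params = protocol_params()) {
  protocol <- match.arg(protocol, protocol_ids())
  if (length(team) != 3L || anyDuplicated(team)) {
    stop("`team` must be three distinct reader ids", call. = FALSE)
  }
  acc <- params$accuracies
  if (is.null(acc)) acc <- reader_accuracies(panel, team)
  if (!all(team %in% names(acc))) {
    stop("accuracy weights missing for some team members", call. = FALSE)
  }
  rd <- list(decision = panel_matrix(panel, "decision", team),
             confidence = panel_matrix(panel, "confidence", team),
             complexity = panel_matrix(panel, "complexity", team),
             acc = acc[team])
  out <- protocol_outcome(protocol, rd, params)
  tibble::tibble(case_id = panel$cases$case_id,
                 decision = out$decision, judgments = out$judgments)
}
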