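# Synthetic reader-panel generator. A panel holds the gold standard and one
# reading (binary decision + ordinal confidence and perceived complexity) per
# (reader, case) pair, mirroring the annotation table of a multi-reader
# multi-case study.

# deterministic substream seeds: case stream is k = 0, reader i is k = i.
# Multipliers kept small enough that all products are exact in doubles.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) * 16807 + 12345
  s <- s %% 2147483647
  s <- (s * 69621 + (as.double(k) + 1) * 1013904223) %% 2147483647
  as.integer(s)
}

# map a latent value in [0,1] to an ordinal level in 1..L
ordinal_level <- function(x, L) {
  pmax(1L, pmin(as.integer(L), 1L + as.integer(floor(x * L))))
}

# normalized ordinal value on the exact grid {0, 1/(L-1), ..., 1}
normalize_level <- function(level, L) (level - 1) / (L - 1)

#' Generate a synthetic reader panel
#'
#' Simulates the annotation table of a multi-reader multi-case study. Gold
#' labels are balanced to `round(prevalence * n_cases)` abnormal cases
#' (half-up rounding); each case carries a latent difficulty drawn from
#' Beta(2, 2). Reader `r` answers case `c` correctly with probability
#' `clamp(p_base - difficulty_slope * difficulty_c, 0, 1)`, where `p_base` is
#' the profile's sensitivity on abnormal cases and specificity on normal ones.
#'
#' Correctness indicators are assigned by systematic
#' probability-proportional sampling within each gold stratum: each case's
#' marginal correctness probability is exactly the clamped value above, while
#' the reader's empirical sensitivity and specificity are pinned to within one
#' case of their expectations, emulating a study panel whose reader accuracies
#' are fixed observed quantities rather than binomial draws. Readers are
#' conditionally independent given case difficulty; with slope 0 they are
#' unconditionally independent.
#'
#' Human confidence is stochastically higher when the decision is correct and
#' the case easy; perceived complexity is a per-reader noisy ordinal
#' discretization of the shared latent difficulty. Machines emit a latent
#' abnormality score whose distance from 0.5 plays the role of confidence
#' (complexity is its complement), quantized to the same ordinal grids.
#'
#' Each reader consumes an independently derived substream of the root seed,
#' so adding a reader never perturbs the readings of existing ones.
#'
#' @param profiles Profile table or list of [reader_profile()] rows.
#' @param n_cases Number of cases (>= 1).
#' @param prevalence Fraction of abnormal cases in \[0, 1\].
#' @param seed Integer root seed; identical inputs reproduce the panel
#'   bit-exactly.
#' @return A `reader_panel`: list with `cases` (case_id, gold, difficulty),
#'   `readings` (one row per reader x case), `profiles`, and `seed`. Decisions
#'   and gold are coded 0 = normal, 1 = abnormal (abnormal is the positive
#'   class).
#' @export
generate_panel <- function(profiles, n_cases, prevalence = 0.5, seed = 1L) {
  profiles <- as_profile_table(profiles)
  if (nrow(profiles) < 1L) stop("need at least one reader profile", call. = FALSE)
  if (length(n_cases) != 1L || !is.finite(n_cases) || n_cases < 1) {
    stop("`n_cases` must be a single integer >= 1", call. = FALSE)
  }
  if (length(prevalence) != 1L || !is.finite(prevalence) ||
      prevalence < 0 || prevalence > 1) {
    stop("`prevalence` must be a single value in [0, 1]", call. = FALSE)
  }
  n <- as.integer(n_cases)
  n_pos <- as.integer(floor(prevalence * n + 0.5))  # half-up: 427 -> 214

  cases <- withr::with_seed(derive_seed(seed, 0L), {
    gold <- integer(n)
    if (n_pos > 0L) gold[sample.int(n, n_pos)] <- 1L
    tibble::tibble(
      case_id = sprintf("case%04d", seq_len(n)),
      gold = gold,
      difficulty = stats::rbeta(n, 2, 2)
    )
  })

  readings <- purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    withr::with_seed(derive_seed(seed, i),
                     simulate_reader(profiles[i, ], cases))
  })

  structure(
    list(cases = cases, readings = readings, profiles = profiles,
         seed = as.integer(seed)),
    class = "reader_panel"
  )
}

# systematic probability-proportional sampling: selects each unit with
# probability exactly p[i] while fixing the selected count to within one of
# sum(p). Random order decorrelates which units are jointly selected.
sys_pps_select <- function(p) {
  n <- length(p)
  ord <- sample.int(n)
  u <- stats::runif(1)
  cum <- cumsum(p[ord])
  hits <- (floor(cum - u) - floor(c(0, cum[-n]) - u)) >= 1
  sel <- logical(n)
  sel[ord] <- hits
  sel
}

# one reader's readings over all cases; called inside the reader's substream
simulate_reader <- function(profile, cases) {
  n <- nrow(cases)
  d <- cases$difficulty
  gold <- cases$gold
  p_base <- ifelse(gold == 1L, profile$sensitivity, profile$specificity)
  p <- pmin(1, pmax(0, p_base - profile$difficulty_slope * d))
  # correctness via systematic PPS within each gold stratum: per-case marginal
  # probability is exactly p, while the reader's empirical sensitivity and
  # specificity are pinned to their expected values (a study panel's reader
  # accuracies are fixed observed quantities, not binomial draws)
  correct <- logical(n)
  for (g in c(0L, 1L)) {
    idx <- which(gold == g)
    if (length(idx)) correct[idx] <- sys_pps_select(p[idx])
  }
  decision <- ifelse(correct, gold, 1L - gold)
  if (profile$kind == "human") {
    eta <- 0.9 + 0.6 * correct - 1.8 * d + profile$confidence_bias +
      stats::rnorm(n, 0, 0.7)
    conf_level <- ordinal_level(stats::plogis(eta), 5L)
    w <- pmin(1, pmax(0, 0.33 + 0.75 * d + stats::rnorm(n, 0, 0.12)))
    compl_level <- ordinal_level(w, 4L)
  } else {
    # latent abnormality score s: confidence = 2|s - 0.5|, complexity = 1 - conf
    margin <- stats::plogis(0.9 + 0.8 * correct - 1.6 * d +
                              profile$confidence_bias + stats::rnorm(n, 0, 0.8))
    conf_level <- ordinal_level(margin, 5L)
    compl_level <- ordinal_level(1 - margin, 4L)
  }
  tibble::tibble(
    reader_id = profile$reader_id,
    case_id = cases$case_id,
    decision = as.integer(decision),
    confidence_level = conf_level,
    confidence = normalize_level(conf_level, 5L),
    complexity_level = compl_level,
    complexity = normalize_level(compl_level, 4L)
  )
}

#' @export
print.reader_panel <- function(x, ...) {
  cat(sprintf(
    "<reader_panel> %d readers x %d cases (%d abnormal), seed %d\n",
    nrow(x$profiles), nrow(x$cases), sum(x$cases$gold), x$seed
  ))
  invisible(x)
}

# reader ids of a given kind
panel_readers <- function(panel, kind = NULL) {
  p <- panel$profiles
  if (!is.null(kind)) p <- p[p$kind %in% kind, ]
  p$reader_id
}

# field matrix (readers x cases), rows ordered as `readers`, columns in
# panel case order; errors on missing readings
panel_matrix <- function(panel, field, readers = NULL) {
  if (is.null(readers)) readers <- panel_readers(panel)
  unknown <- setdiff(readers, panel$profiles$reader_id)
  if (length(unknown)) {
    stop("unknown reader(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  r <- panel$readings[panel$readings$reader_id %in% readers, ]
  m <- tapply(
    r[[field]],
    list(factor(r$reader_id, levels = readers),
         factor(r$case_id, levels = panel$cases$case_id)),
    identity
  )
  if (anyNA(m)) {
    stop("panel is missing readings for some (reader, case) pairs",
         call. = FALSE)
  }
  m
}

#' Per-reader empirical accuracies on a panel
#'
#' @param panel A `reader_panel`.
#' @param readers Reader ids (default: all readers in the panel).
#' @return Named numeric vector of accuracies in percent.
#' @export
reader_accuracies <- function(panel, readers = NULL) {
  if (is.null(readers)) readers <- panel_readers(panel)
  d <- panel_matrix(panel, "decision", readers)
  gold <- panel$cases$gold
  acc <- rowMeans(d == matrix(gold, nrow(d), length(gold), byrow = TRUE)) * 100
  stats::setNames(acc, readers)
}

# Spearman correlation that flags degenerate inputs instead of erroring
safe_spearman <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    list(estimate = NA_real_, defined = FALSE)
  } else {
    list(estimate = stats::cor(x, y, method = "spearman"), defined = TRUE)
  }
}

#' Association structure diagnostics for a panel
#'
#' Rank-correlates, across cases, the per-case mean normalized confidence and
#' mean normalized complexity with the per-case success rate (fraction of
#' readers agreeing with gold). Under the generator's defaults confidence
#' should associate positively and complexity negatively with success,
#' mirroring the metadata structure of the emulated study.
#'
#' @param panel A `reader_panel`.
#' @param readers Reader ids to include (default: all).
#' @return One-row tibble with `confidence_success_cor`,
#'   `complexity_success_cor` and logical `confidence_defined`,
#'   `complexity_defined` flags (a degenerate, constant column yields an
#'   undefined correlation, flagged rather than thrown).
#' @export
check_association_structure <- function(panel, readers = NULL) {
  if (is.null(readers)) readers <- panel_readers(panel)
  d <- panel_matrix(panel, "decision", readers)
  conf <- panel_matrix(panel, "confidence", readers)
  compl <- panel_matrix(panel, "complexity", readers)
  gold <- panel$cases$gold
  success <- colMeans(d == matrix(gold, nrow(d), length(gold), byrow = TRUE))
  cc <- safe_spearman(colMeans(conf), success)
  cx <- safe_spearman(colMeans(compl), success)
  tibble::tibble(
    confidence_success_cor = cc$estimate,
    confidence_defined = cc$defined,
    complexity_success_cor = cx$estimate,
    complexity_defined = cx$defined
  )
}
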