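# The two study experiments: (1) all 90 human-machine-human teams of the ten
# retained readers under all eight protocols, each metric tested against the
# strong-machine benchmark scalar by one-sample t tests; (2) the 20 weak vs 20
# strong teams compared metric-wise by exact two-sample KS tests, Bonferroni
# corrected. Plus the outlier-trimming step and the team-size majority sweep.

#' Trim the most and least accurate reader as outliers
#'
#' Removes exactly one reader at each extreme of the accuracy vector,
#' reproducing the study's reduction of its 12-reader panel to 10. Ties for an
#' extreme are surfaced as an error rather than silently resolved.
#'
#' @param accuracies Named numeric vector of per-reader accuracies (names are
#'   reader ids; unnamed vectors are named by position).
#' @return The retained named subvector, in the original order.
#' @export
trim_outlier_readers <- function(accuracies) {
  if (length(accuracies) < 3L) stop("need at least three readers", call. = FALSE)
  if (is.null(names(accuracies))) {
    names(accuracies) <- sprintf("reader%02d", seq_along(accuracies))
  }
  hi <- max(accuracies); lo <- min(accuracies)
  if (sum(accuracies == hi) > 1L || sum(accuracies == lo) > 1L) {
    stop("tied extreme accuracies: outlier trimming is ambiguous", call. = FALSE)
  }
  accuracies[accuracies != hi & accuracies != lo]
}

#' Enumerate all machine-second teams over a human reader set
#'
#' All ordered pairs of distinct humans `(first, third)` with the machine
#' fixed as second reader: `n * (n - 1)` teams for `n` humans (90 for the full
#' panel of 10, 20 for a 5-reader split).
#'
#' @param humans Character vector of human reader ids (>= 2).
#' @param machine Machine reader id, not among `humans`.
#' @return Tibble with columns `first`, `second`, `third`.
#' @export
enumerate_teams <- function(humans, machine) {
  if (length(humans) < 2L) stop("need at least two human readers", call. = FALSE)
  if (machine %in% humans) {
    stop("`machine` must not be one of `humans`", call. = FALSE)
  }
  grid <- expand.grid(first = humans, third = humans,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$first != grid$third, ]
  tibble::tibble(first = grid$first, second = machine, third = grid$third)
}

#' Evaluate protocols for a set of teams on a panel
#'
#' @param panel A `reader_panel`.
#' @param teams Tibble from [enumerate_teams()].
#' @param protocols Protocol ids (default all eight).
#' @param params [protocol_params()]; if its `accuracies` slot is `NULL`,
#'   panel-estimated reader accuracies are used as the accuracy weights.
#' @return Tibble: one row per (team, protocol) with the six metrics in
#'   percent plus `total_judgments`.
#' @export
evaluate_teams <- function(panel, teams, protocols = protocol_ids(),
                           params = protocol_params()) {
  protocols <- match.arg(protocols, protocol_ids(), several.ok = TRUE)
  readers <- unique(c(teams$first, teams$second, teams$third))
  if (is.null(params$accuracies)) {
    params$accuracies <- reader_accuracies(panel, readers)
  }
  # extract each reader's aligned reading vectors once
  D <- panel_matrix(panel, "decision", readers)
  CONF <- panel_matrix(panel, "confidence", readers)
  COMPL <- panel_matrix(panel, "complexity", readers)
  gold <- panel$cases$gold
  pos <- gold == 1L
  n_rows <- nrow(teams) * length(protocols)
  first <- second <- third <- prot <- character(n_rows)
  tj <- integer(n_rows)
  met <- matrix(NA_real_, n_rows, 6L,
                dimnames = list(NULL, metric_ids()))
  k <- 0L
  for (i in seq_len(nrow(teams))) {
    team <- c(teams$first[[i]], teams$second[[i]], teams$third[[i]])
    idx <- match(team, readers)
    rd <- list(decision = D[idx, , drop = FALSE],
               confidence = CONF[idx, , drop = FALSE],
               complexity = COMPL[idx, , drop = FALSE],
               acc = params$accuracies[team])
    for (pr in protocols) {
      k <- k + 1L
      out <- protocol_outcome(pr, rd, params)
      correct <- out$decision == gold
      acc <- 100 * mean(correct)
      sens <- if (any(pos)) 100 * mean(correct[pos]) else NA_real_
      spec <- if (any(!pos)) 100 * mean(correct[!pos]) else NA_real_
      total <- sum(out$judgments)
      eff <- 100 * sum(correct) / total
      first[[k]] <- team[[1L]]; second[[k]] <- team[[2L]]
      third[[k]] <- team[[3L]]; prot[[k]] <- pr
      tj[[k]] <- total
      met[k, ] <- c(acc, sens, spec, eff,
                    harmonic_mean_1(sens, spec), f2_acc_eff(acc, eff))
    }
  }
  dplyr::bind_cols(
    tibble::tibble(first = first, second = second, third = third,
                   protocol = prot, total_judgments = tj),
    tibble::as_tibble(met)
  )
}

#' Metric set of a single reader acting alone
#'
#' One judgment per case, so the reader's efficiency equals its accuracy.
#' Used for the strong-machine benchmark scalar.
#'
#' @param panel A `reader_panel`.
#' @param reader Reader id.
#' @return One-row tibble of the six metrics in percent.
#' @export
solo_metrics <- function(panel, reader) {
  d <- panel_matrix(panel, "decision", reader)
  metric_set(as.integer(d[1L, ]), panel$cases$gold,
             rep(1L, nrow(panel$cases)))
}

# t-based 95% CI half-width
ci_halfwidth <- function(x, level = 0.95) {
  n <- length(x)
  stats::qt(1 - (1 - level) / 2, n - 1) * stats::sd(x) / sqrt(n)
}

#' Experiment 1: reader teams against the strong machine
#'
#' Enumerates all machine-second teams over the panel's human readers,
#' evaluates every protocol on every team, and tests each protocol's
#' distribution of team metric values against the benchmark machine's scalar
#' with two-sided one-sample t tests, Bonferroni corrected within each
#' metric's protocol family.
#'
#' @param panel A `reader_panel` containing the humans and both machines.
#' @param machine_member Reader id of the team's second reader (default
#'   `"mobilenet"`).
#' @param benchmark_machine Reader id of the benchmark (default
#'   `"inceptionv3"`); must differ from `machine_member`.
#' @param humans Human reader ids (default: panel profiles of kind human).
#' @param params [protocol_params()].
#' @param family_size Bonferroni family per metric (default: number of
#'   protocols).
#' @param test_metrics Metrics to test against the benchmark (default the four
#'   the study tabulates: accuracy, sensitivity, specificity, hm_sens_spec;
#'   efficiency testing is optional).
#' @return List of class `experiment_result`: `per_team` (rows = teams x
#'   protocols), `summary` (per protocol x metric: mean, 95% CI, t, df, p),
#'   `benchmark` (the benchmark machine's six metrics), `config`.
#' @export
run_experiment_1 <- function(panel, machine_member = "mobilenet",
                             benchmark_machine = "inceptionv3",
                             humans = NULL, params = protocol_params(),
                             family_size = NULL,
                             test_metrics = c("accuracy", "sensitivity",
                                              "specificity", "hm_sens_spec")) {
  if (machine_member == benchmark_machine) {
    stop("benchmark machine must differ from the team machine", call. = FALSE)
  }
  if (is.null(humans)) humans <- panel_readers(panel, "human")
  teams <- enumerate_teams(humans, machine_member)
  per_team <- evaluate_teams(panel, teams, params = params)
  benchmark <- solo_metrics(panel, benchmark_machine)
  if (is.null(family_size)) family_size <- length(protocol_ids())
  test_metrics <- match.arg(test_metrics, metric_ids(), several.ok = TRUE)

  summary <- per_team |>
    tidyr::pivot_longer(dplyr::all_of(metric_ids()),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$protocol, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      ci_lo = mean(.data$value) - ci_halfwidth(.data$value),
      ci_hi = mean(.data$value) + ci_halfwidth(.data$value),
      n_teams = dplyr::n(),
      test = list(
        if (.data$metric[[1L]] %in% test_metrics) {
          one_sample_t(.data$value, benchmark[[.data$metric[[1L]]]],
                       family_size = family_size)
        } else {
          tibble::tibble(statistic = NA_real_, df = NA_real_,
                         p_raw = NA_real_, p_corrected = NA_real_,
                         degenerate = NA)
        }
      ),
      .groups = "drop"
    ) |>
    tidyr::unnest("test") |>
    dplyr::select(dplyr::any_of(c("protocol", "metric", "mean", "ci_lo",
                                  "ci_hi", "n_teams", "statistic", "df",
                                  "p_raw", "p_corrected", "degenerate")))

  structure(
    list(per_team = per_team, summary = summary, benchmark = benchmark,
         config = list(experiment = 1L, machine_member = machine_member,
                       benchmark_machine = benchmark_machine, humans = humans,
                       params = params, family_size = family_size,
                       seed = panel$seed)),
    class = "experiment_result"
  )
}

#' Split human readers into weak and strong halves by panel accuracy
#'
#' @param panel A `reader_panel`.
#' @param humans Human reader ids (default: panel profiles of kind human;
#'   must be of even length).
#' @return List with `weak` (least accurate half) and `strong` ids.
#' @export
split_weak_strong <- function(panel, humans = NULL) {
  if (is.null(humans)) humans <- panel_readers(panel, "human")
  if (length(humans) %% 2L != 0L) {
    stop("need an even number of human readers to split", call. = FALSE)
  }
  acc <- sort(reader_accuracies(panel, humans))
  half <- length(humans) / 2L
  list(weak = names(acc)[seq_len(half)],
       strong = names(acc)[seq_len(half) + half])
}

#' Experiment 2: weak versus strong reader teams
#'
#' Splits the humans into the least and most accurate halves (panel-estimated
#' accuracy), enumerates machine-second teams within each half, evaluates all
#' protocols, and compares the strong and weak metric distributions with
#' two-sample KS tests for every ordered protocol pair (strong protocol on
#' rows, weak on columns), Bonferroni corrected within each metric's
#' protocol-pair family.
#'
#' @inheritParams run_experiment_1
#' @param family_size Bonferroni family per metric (default: number of
#'   protocol pairs, 64).
#' @param split Optional explicit split as `list(weak = ids, strong = ids)`;
#'   by default the humans are ranked by panel accuracy and halved.
#' @return List of class `experiment_result`: `per_team` (with a `group`
#'   column), `summary` (group x protocol x metric means), `ks_tests` (long
#'   tibble: metric, strong_protocol, weak_protocol, statistic, p_raw,
#'   p_corrected), `split`, `config`.
#' @export
run_experiment_2 <- function(panel, machine_member = "mobilenet",
                             humans = NULL, params = protocol_params(),
                             family_size = NULL, split = NULL) {
  if (is.null(split)) split <- split_weak_strong(panel, humans)
  if (length(intersect(split$weak, split$strong))) {
    stop("weak and strong splits overlap", call. = FALSE)
  }
  per_team <- dplyr::bind_rows(
    dplyr::mutate(
      evaluate_teams(panel, enumerate_teams(split$weak, machine_member),
                     params = params),
      group = "weak", .before = 1L),
    dplyr::mutate(
      evaluate_teams(panel, enumerate_teams(split$strong, machine_member),
                     params = params),
      group = "strong", .before = 1L)
  )
  n_proto <- length(protocol_ids())
  if (is.null(family_size)) family_size <- n_proto^2

  long <- per_team |>
    tidyr::pivot_longer(dplyr::all_of(metric_ids()),
                        names_to = "metric", values_to = "value")
  summary <- long |>
    dplyr::group_by(.data$group, .data$protocol, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), n_teams = dplyr::n(),
                     .groups = "drop")

  grid <- expand.grid(strong_protocol = protocol_ids(),
                      weak_protocol = protocol_ids(),
                      metric = metric_ids(), stringsAsFactors = FALSE)
  ks_tests <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    m <- grid$metric[[i]]
    a <- long$value[long$group == "strong" &
                      long$protocol == grid$strong_protocol[[i]] &
                      long$metric == m]
    b <- long$value[long$group == "weak" &
                      long$protocol == grid$weak_protocol[[i]] &
                      long$metric == m]
    res <- ks_two_sample(a, b, family_size = family_size)
    tibble::tibble(metric = m,
                   strong_protocol = grid$strong_protocol[[i]],
                   weak_protocol = grid$weak_protocol[[i]],
                   statistic = res$statistic, p_raw = res$p_raw,
                   p_corrected = res$p_corrected)
  })

  structure(
    list(per_team = per_team, summary = summary, ks_tests = ks_tests,
         split = split,
         config = list(experiment = 2L, machine_member = machine_member,
                       params = params, family_size = family_size,
                       seed = panel$seed)),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> experiment %d: %d (team, protocol) rows\n",
              x$config$experiment, nrow(x$per_team)))
  invisible(x)
}

#' Majority accuracy as a function of team size
#'
#' For each odd team size `k`, evaluates the always-consulted simple majority
#' over subsets of the given readers and summarizes the accuracy distribution.
#' All `choose(n, k)` subsets are used unless `max_teams` caps them, in which
#' case a random sample of subsets is drawn.
#'
#' @param panel A `reader_panel`.
#' @param readers Reader ids to draw teams from (default: humans).
#' @param sizes Odd team sizes (default 1, 3, 5, 7, 9).
#' @param max_teams Cap on subsets per size (default all).
#' @param seed Seed for subset sampling when capped.
#' @return Tibble: `size`, `n_teams`, `mean`, `min`, `max` accuracy (percent).
#' @export
sweep_panel_size <- function(panel, readers = NULL, sizes = c(1, 3, 5, 7, 9),
                             max_teams = Inf, seed = 1L) {
  if (is.null(readers)) readers <- panel_readers(panel, "human")
  if (any(sizes %% 2 == 0)) stop("team sizes must be odd", call. = FALSE)
  if (max(sizes) > length(readers)) {
    stop("team size exceeds the number of readers", call. = FALSE)
  }
  d <- panel_matrix(panel, "decision", readers)
  gold <- panel$cases$gold
  purrr::map_dfr(sizes, function(k) {
    subsets <- utils::combn(length(readers), k, simplify = FALSE)
    if (length(subsets) > max_teams) {
      subsets <- withr::with_seed(
        derive_seed(seed, k),
        sample(subsets, max_teams)
      )
    }
    acc <- vapply(subsets, function(idx) {
      100 * mean(majority_panel(d[idx, , drop = FALSE]) == gold)
    }, numeric(1))
    tibble::tibble(size = as.integer(k), n_teams = length(subsets),
                   mean = mean(acc), min = min(acc), max = max(acc))
  })
}
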