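# Panel and result table I/O. Decisions are stored as 0 = normal,
# 1 = abnormal everywhere; metric storage keeps full precision with rounded
# 2-decimal presentation twins. Validation rejects malformed rows (naming the
# row number) rather than coercing.

#' Write a panel to CSV
#'
#' Readings CSV: `reader_id,case_id,decision,confidence_level,
#' complexity_level`. Gold CSV: `case_id,gold`. Latent difficulty and the
#' generating profiles are not part of the annotation interchange format and
#' are not written.
#'
#' @param panel A `reader_panel`.
#' @param readings_path,gold_path Output CSV paths.
#' @return The two paths, invisibly.
#' @export
write_panel <- function(panel, readings_path, gold_path) {
  readr::write_csv(
    panel$readings[, c("reader_id", "case_id", "decision",
                       "confidence_level", "complexity_level")],
    readings_path
  )
  readr::write_csv(panel$cases[, c("case_id", "gold")], gold_path)
  invisible(c(readings_path, gold_path))
}

#' Read a panel from CSV
#'
#' Validates ordinal ranges (confidence 1-5, complexity 1-4), decision codes
#' (0/1), duplicate (reader, case) rows, and orphan case ids; violations are
#' rejected with the offending row number. Completeness (one reading per
#' reader x case pair) is enforced.
#'
#' @param readings_path,gold_path CSV paths as written by [write_panel()].
#' @return A `reader_panel` (without latent difficulties or generative
#'   profiles; profile rows record only the reader ids, with kind `"human"`).
#' @export
read_panel <- function(readings_path, gold_path) {
  readings <- readr::read_csv(readings_path, show_col_types = FALSE)
  gold <- readr::read_csv(gold_path, show_col_types = FALSE)
  need_r <- c("reader_id", "case_id", "decision", "confidence_level",
              "complexity_level")
  if (!all(need_r %in% names(readings))) {
    stop("readings CSV must have columns ", paste(need_r, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("case_id", "gold") %in% names(gold))) {
    stop("gold CSV must have columns case_id, gold", call. = FALSE)
  }
  bad_row <- function(what, rows) {
    stop(sprintf("%s at readings row(s) %s", what,
                 paste(utils::head(rows, 5L), collapse = ", ")),
         call. = FALSE)
  }
  if (length(bad <- which(!gold$gold %in% c(0L, 1L)))) {
    stop("gold labels must be 0/1 (gold row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), ")", call. = FALSE)
  }
  if (anyDuplicated(gold$case_id)) stop("duplicate case_id in gold CSV",
                                        call. = FALSE)
  if (length(bad <- which(!readings$decision %in% c(0L, 1L)))) {
    bad_row("decision codes must be 0 (normal) / 1 (abnormal)", bad)
  }
  if (length(bad <- which(!readings$confidence_level %in% 1:5))) {
    bad_row("confidence level out of range 1..5", bad)
  }
  if (length(bad <- which(!readings$complexity_level %in% 1:4))) {
    bad_row("complexity level out of range 1..4", bad)
  }
  key <- paste(readings$reader_id, readings$case_id)
  if (length(bad <- which(duplicated(key)))) {
    bad_row("duplicate (reader_id, case_id) pair", bad)
  }
  if (length(bad <- which(!readings$case_id %in% gold$case_id))) {
    bad_row("case_id not present in gold CSV", bad)
  }
  readers <- unique(readings$reader_id)
  if (nrow(readings) != length(readers) * nrow(gold)) {
    stop("panel must contain exactly one reading per (reader, case) pair",
         call. = FALSE)
  }
  cases <- tibble::tibble(case_id = gold$case_id,
                          gold = as.integer(gold$gold),
                          difficulty = NA_real_)
  readings <- tibble::tibble(
    reader_id = readings$reader_id,
    case_id = readings$case_id,
    decision = as.integer(readings$decision),
    confidence_level = as.integer(readings$confidence_level),
    confidence = normalize_level(as.integer(readings$confidence_level), 5L),
    complexity_level = as.integer(readings$complexity_level),
    complexity = normalize_level(as.integer(readings$complexity_level), 4L)
  )
  profiles <- tibble::tibble(
    reader_id = readers, kind = "human", sensitivity = NA_real_,
    specificity = NA_real_, difficulty_slope = NA_real_,
    confidence_bias = NA_real_, target_accuracy = NA_real_
  )
  structure(list(cases = cases, readings = readings, profiles = profiles,
                 seed = NA_integer_),
            class = "reader_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# append rounded 2-decimal presentation twins next to full-precision columns
with_presentation <- function(tab, cols) {
  for (cl in intersect(cols, names(tab))) {
    tab[[paste0(cl, "_2dp")]] <- round(tab[[cl]], 2)
  }
  tab
}

#' Write an experiment result to a directory
#'
#' Writes `metrics_by_team.csv`, `summary.csv`, for experiment 1
#' `benchmark.csv`, for experiment 2 one `ks_matrix_<metric>.csv` per metric
#' (corrected p-values, strong protocols on rows, weak on columns) plus
#' `ks_tests.csv`, and finally `manifest.json` (config, seed, file digests).
#' Percentages keep full precision with rounded `_2dp` twins.
#'
#' @param result An `experiment_result`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put <- function(tab, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(tab, p)
    paths <<- c(paths, p)
  }
  put(with_presentation(result$per_team, metric_ids()), "metrics_by_team.csv")
  put(with_presentation(result$summary, c("mean", "ci_lo", "ci_hi")),
      "summary.csv")
  if (!is.null(result$benchmark)) {
    put(with_presentation(result$benchmark, metric_ids()), "benchmark.csv")
  }
  if (!is.null(result$ks_tests)) {
    put(result$ks_tests, "ks_tests.csv")
    for (m in unique(result$ks_tests$metric)) {
      wide <- result$ks_tests |>
        dplyr::filter(.data$metric == m) |>
        dplyr::select("strong_protocol", "weak_protocol", "p_corrected") |>
        tidyr::pivot_wider(names_from = "weak_protocol",
                           values_from = "p_corrected")
      put(wide, sprintf("ks_matrix_%s.csv", m))
    }
  }
  manifest <- list(
    config = result$config[setdiff(names(result$config), "params")],
    protocol_params = unclass(result$config$params)[c("tau", "delta",
                                                      "tie_rule")],
    seed = result$config$seed,
    written = as.list(stats::setNames(
      unname(tools::md5sum(paths)), basename(paths))),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, mp))
}
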