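#!/usr/bin/env Rscript

# Stage 2: reader statistics on the published per-reader accuracies.
#
# Reproduces the panel summaries that are recomputable from the printed
# per-reader table: outlier trimming of the 12-reader panel, the retained
# group mean, the weak/strong five-reader split, and the pooled two-sample t
# comparison between the splits.
#
# Usage: Rscript analysis/02_reader_statistics.R [--out DIR]

suppressPackageStartupMessages(library(readfusion))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[[i + 1L]] else default
}
out <- get_arg("--out", "results")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

all12 <- study_reader_accuracies(include_outliers = TRUE)
kept <- trim_outlier_readers(all12)
cat(sprintf("trimmed %d -> %d readers (dropped %.2f and %.2f)\n",
            length(all12), length(kept), max(all12), min(all12)))
cat(sprintf("retained mean accuracy: %.2f (min %.2f, max %.2f)\n",
            mean(kept), min(kept), max(kept)))

weak <- sort(kept)[1:5]
strong <- sort(kept)[6:10]
tt <- two_sample_t(strong, weak)
cat(sprintf("weak five:   M = %.2f, SD = %.2f\n", mean(weak), sd(weak)))
cat(sprintf("strong five: M = %.2f, SD = %.2f\n", mean(strong), sd(strong)))
cat(sprintf("pooled t = %.2f, df = %d, two-sided p = %.2e\n",
            tt$statistic, as.integer(tt$df), tt$p_raw))

readr::write_csv(
  tibble::tibble(
    quantity = c("retained_mean", "weak_mean", "strong_mean",
                 "t_statistic", "df", "p_two_sided"),
    value = c(mean(kept), mean(weak), mean(strong),
              tt$statistic, tt$df, tt$p_raw)
  ),
  file.path(out, "reader_statistics.csv")
)
cat("wrote", file.path(out, "reader_statistics.csv"), "\n")
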