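#!/usr/bin/env Rscript

# Stage 5: majority accuracy as a function of team size.
#
# Evaluates the always-consulted simple majority over all odd-sized human
# reader subsets (1 to 9) of a default synthetic panel, summarizing mean,
# minimum and maximum team accuracy per size.
#
# Usage: Rscript analysis/05_team_size_sweep.R [--seed INT] [--out DIR]

suppressPackageStartupMessages(library(readfusion))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[[i + 1L]] else default
}
seed <- as.integer(get_arg("--seed", "1"))
out <- get_arg("--out", "results")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- study_design()
panel <- generate_panel(default_study_profiles(), design$n_cases,
                        design$prevalence, seed = seed)
sw <- sweep_panel_size(panel)
cat("majority accuracy by (odd) team size:\n")
for (i in seq_len(nrow(sw))) {
  cat(sprintf("  k = %d (%3d teams): mean %.2f, min %.2f, max %.2f\n",
              sw$size[i], sw$n_teams[i], sw$mean[i], sw$min[i], sw$max[i]))
}
readr::write_csv(sw, file.path(out, "team_size_sweep.csv"))
cat("wrote", file.path(out, "team_size_sweep.csv"), "\n")
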