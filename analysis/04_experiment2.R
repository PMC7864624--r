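#!/usr/bin/env Rscript

# Stage 4: experiment 2 - weak versus strong reader teams.
#
# Splits the simulated humans into the 5 least and 5 most accurate readers,
# evaluates all protocols on the 20 teams of each half, and compares the
# strong and weak metric distributions for every ordered protocol pair with
# exact two-sample KS tests (Bonferroni within each metric's 64-pair family).
#
# Usage: Rscript analysis/04_experiment2.R [--seed INT] [--out DIR]

suppressPackageStartupMessages(library(readfusion))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[[i + 1L]] else default
}
seed <- as.integer(get_arg("--seed", "1"))
out <- get_arg("--out", "results/experiment2")

design <- study_design()
panel <- generate_panel(default_study_profiles(), design$n_cases,
                        design$prevalence, seed = seed)
e2 <- run_experiment_2(panel)
write_results(e2, out)

cat(sprintf("weak readers:   %s\n", paste(e2$split$weak, collapse = ", ")))
cat(sprintf("strong readers: %s\n", paste(e2$split$strong, collapse = ", ")))
cat("group mean accuracy by protocol (strong / weak):\n")
for (pr in protocol_ids()) {
  s <- e2$summary[e2$summary$protocol == pr & e2$summary$metric == "accuracy", ]
  cat(sprintf("  %-13s %6.2f / %6.2f\n", pr,
              s$mean[s$group == "strong"], s$mean[s$group == "weak"]))
}
sig <- e2$ks_tests[e2$ks_tests$p_corrected < 0.05, ]
cat(sprintf("significant protocol-pair differences (corrected p < 0.05): %d of %d\n",
            nrow(sig), nrow(e2$ks_tests)))
cat("wrote", out, "\n")
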