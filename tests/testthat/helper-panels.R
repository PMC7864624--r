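# Panel fixtures built in code.

# assemble a reader_panel directly from a decisions matrix (readers x cases)
# and optional confidence/complexity level matrices
panel_from_matrices <- function(decisions, gold,
                                confidence_level = NULL,
                                complexity_level = NULL,
                                kind = "human") {
  readers <- rownames(decisions)
  if (is.null(readers)) {
    readers <- sprintf("r%02d", seq_len(nrow(decisions)))
  }
  n <- ncol(decisions)
  case_ids <- sprintf("case%04d", seq_len(n))
  if (is.null(confidence_level)) {
    confidence_level <- matrix(3L, nrow(decisions), n)
  }
  if (is.null(complexity_level)) {
    complexity_level <- matrix(2L, nrow(decisions), n)
  }
  readings <- do.call(rbind, lapply(seq_along(readers), function(i) {
    cl <- as.integer(confidence_level[i, ])
    xl <- as.integer(complexity_level[i, ])
    tibble::tibble(
      reader_id = readers[[i]], case_id = case_ids,
      decision = as.integer(decisions[i, ]),
      confidence_level = cl,
      confidence = (cl - 1) / 4,
      complexity_level = xl,
      complexity = (xl - 1) / 3
    )
  }))
  profiles <- tibble::tibble(
    reader_id = readers, kind = kind, sensitivity = NA_real_,
    specificity = NA_real_, difficulty_slope = NA_real_,
    confidence_bias = NA_real_, target_accuracy = NA_real_
  )
  structure(
    list(cases = tibble::tibble(case_id = case_ids, gold = as.integer(gold),
                                difficulty = NA_real_),
         readings = tibble::as_tibble(readings), profiles = profiles,
         seed = NA_integer_),
    class = "reader_panel"
  )
}

# one default-profile study-sized panel, generated once per test run
default_panel <- local({
  cache <- NULL
  function(seed = 424242) {
    if (is.null(cache)) {
      cache <<- readfusion::generate_panel(
        readfusion::default_study_profiles(), 427, 0.5, seed = seed)
    }
    cache
  }
})

human_ids <- function() names(readfusion::study_reader_accuracies())
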