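# Independent scalar brute-force oracles for the protocol layer. Coded as
# explicit vote counting over the involved readers, deliberately not sharing
# any logic with the package's vectorized implementations.

oracle_vote <- function(decisions) {
  # plain majority among the involved readers' decisions
  as.integer(sum(decisions == 1L) > sum(decisions == 0L))
}

oracle_majority <- function(d1, d2, d3) {
  if (d1 == d2) list(decision = d1, judgments = 2L)
  else list(decision = oracle_vote(c(d1, d2, d3)), judgments = 3L)
}

oracle_weighted <- function(d1, d2, d3, w1, w2, w3, tie = "abnormal_wins") {
  if (d1 == d2) return(list(decision = d1, judgments = 2L))
  ws <- c(w1, w2, w3); ds <- c(d1, d2, d3)
  if (sum(ws) == 0) return(list(decision = oracle_vote(ds), judgments = 3L))
  s1 <- sum(ws[ds == 1L]); s0 <- sum(ws[ds == 0L])
  dec <- if (s1 > s0) 1L else if (s0 > s1) 0L else {
    if (tie == "abnormal_wins") 1L else 0L
  }
  list(decision = dec, judgments = 3L)
}

oracle_specific <- function(d1, d2, d3) {
  if (d1 == 0L) return(list(decision = 0L, judgments = 1L))
  if (d2 == 1L) return(list(decision = 1L, judgments = 2L))
  list(decision = oracle_vote(c(d1, d2, d3)), judgments = 3L)
}

oracle_sensitive <- function(d1, d2, d3) {
  if (d1 == 1L) return(list(decision = 1L, judgments = 1L))
  if (d2 == 0L) return(list(decision = 0L, judgments = 2L))
  list(decision = oracle_vote(c(d1, d2, d3)), judgments = 3L)
}

oracle_cautious <- function(d1, d2, d3, c1, c2, x1, x2, tau, delta) {
  if (abs(c1 - c2) >= tau && (x1 + x2) / 2 <= delta) {
    dec <- if (c2 > c1) d2 else d1
    list(decision = dec, judgments = 2L)
  } else {
    list(decision = oracle_vote(c(d1, d2, d3)), judgments = 3L)
  }
}

oracle_presumptuous <- function(d1, d2, d3, c1, c2) {
  if (c1 > c2) list(decision = d1, judgments = 2L)
  else if (c2 > c1) list(decision = d2, judgments = 2L)
  else list(decision = oracle_vote(c(d1, d2, d3)), judgments = 3L)
}

oracle_or <- function(d1, d2) {
  if (d1 == 1L || d2 == 1L) {
    list(decision = 1L, judgments = if (d1 == 1L) 1L else 2L)
  } else {
    list(decision = 0L, judgments = 2L)
  }
}

oracle_panel_majority <- function(decisions) oracle_vote(decisions)

# exhaustive 0/1 decision triples
decision_triples <- expand.grid(d1 = 0:1, d2 = 0:1, d3 = 0:1)

# run a scalar oracle over a grid data frame, returning decision/judgment
# vectors comparable to a vectorized protocol call
run_oracle <- function(oracle, grid, ...) {
  res <- lapply(seq_len(nrow(grid)), function(i) {
    do.call(oracle, c(unname(as.list(grid[i, ])), list(...)))
  })
  list(decision = vapply(res, `[[`, integer(1), "decision"),
       judgments = vapply(res, `[[`, integer(1), "judgments"))
}

# exact two-sample KS p by full enumeration of all equally likely
# assignments of the pooled values to the two samples (tie-free inputs)
enumerate_ks_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  d_obs <- max(abs(stats::ecdf(a)(pooled) - stats::ecdf(b)(pooled)))
  picks <- utils::combn(length(pooled), n)
  ds <- apply(picks, 2, function(idx) {
    aa <- pooled[idx]; bb <- pooled[-idx]
    max(abs(stats::ecdf(aa)(pooled) - stats::ecdf(bb)(pooled)))
  })
  mean(ds >= d_obs - 1e-12)
}
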