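# Truth-table and oracle equivalence for the eight protocols, plus the
# reduction and symmetry properties among them.

test_that("simple majority matches the exhaustive truth-table oracle", {
  g <- decision_triples
  got <- simple_majority(g$d1, g$d2, g$d3)
  want <- run_oracle(oracle_majority, g)
  expect_identical(got$decision, want$decision)
  expect_identical(got$judgments, want$judgments)
  expect_true(all(got$judgments %in% 2:3))
})

test_that("weighted majority matches an argmax-of-summed-weights oracle", {
  set.seed(42)
  n <- 200
  g <- data.frame(
    d1 = sample(0:1, n, TRUE), d2 = sample(0:1, n, TRUE),
    d3 = sample(0:1, n, TRUE),
    w1 = sample(c(0, stats::runif(3)), n, TRUE),
    w2 = sample(c(0, stats::runif(3)), n, TRUE),
    w3 = sample(c(0, stats::runif(3)), n, TRUE)
  )
  for (tie in c("abnormal_wins", "normal_wins")) {
    got <- weighted_majority(g$d1, g$d2, g$d3, g$w1, g$w2, g$w3, tie_rule = tie)
    want <- run_oracle(oracle_weighted, g, tie = tie)
    expect_identical(got$decision, want$decision)
    expect_identical(got$judgments, want$judgments)
  }
})

test_that("weighted majority: dominant weight, tie rules, zero-weight fallback", {
  expect_identical(
    weighted_majority(1L, 0L, 0L, 0.9, 0.1, 0.1)$decision, 1L)
  # exact tie: configurable resolution
  expect_identical(weighted_majority(1L, 0L, 0L, 0.5, 0.25, 0.25,
                                     tie_rule = "abnormal_wins")$decision, 1L)
  expect_identical(weighted_majority(1L, 0L, 0L, 0.5, 0.25, 0.25,
                                     tie_rule = "normal_wins")$decision, 0L)
  # all-zero weights fall back to the simple majority, flagged
  z <- weighted_majority(1L, 0L, 0L, 0, 0, 0)
  expect_identical(z$decision, 0L)
  expect_true(z$fallback)
  # agreement never triggers the fallback flag
  z2 <- weighted_majority(1L, 1L, 0L, 0, 0, 0)
  expect_false(z2$fallback)
})

test_that("equal weights reduce the weighted majority to the simple one", {
  g <- decision_triples
  got <- weighted_majority(g$d1, g$d2, g$d3, 0.7, 0.7, 0.7)
  want <- simple_majority(g$d1, g$d2, g$d3)
  expect_identical(got$decision, want$decision)
  expect_identical(got$judgments, want$judgments)
})

test_that("specificity- and sensitivity-oriented match their oracles", {
  g <- decision_triples
  got_sp <- specificity_oriented(g$d1, g$d2, g$d3)
  want_sp <- run_oracle(oracle_specific, g)
  expect_identical(got_sp$decision, want_sp$decision)
  expect_identical(got_sp$judgments, want_sp$judgments)
  got_se <- sensitivity_oriented(g$d1, g$d2, g$d3)
  want_se <- run_oracle(oracle_sensitive, g)
  expect_identical(got_se$decision, want_se$decision)
  expect_identical(got_se$judgments, want_se$judgments)
  expect_true(all(got_sp$judgments %in% 1:3))
  expect_true(all(got_se$judgments %in% 1:3))
})

test_that("sensitivity-oriented is the label-swap mirror of specificity-oriented", {
  g <- decision_triples
  mirrored <- specificity_oriented(1L - g$d1, 1L - g$d2, 1L - g$d3)
  direct <- sensitivity_oriented(g$d1, g$d2, g$d3)
  expect_identical(direct$decision, 1L - mirrored$decision)
  expect_identical(direct$judgments, mirrored$judgments)
})

test_that("cautious branches match the predicate oracle on a factorial grid", {
  tau <- 0.17; delta <- 0.70; eps <- 0.01
  gaps <- c(0, tau - eps, tau, 1)
  compls <- c(0, delta, delta + eps, 1)
  g <- expand.grid(gap = gaps, mean_compl = compls,
                   d1 = 0:1, d2 = 0:1, d3 = 0:1, swap = c(FALSE, TRUE))
  c1 <- ifelse(g$swap, 0, g$gap)
  c2 <- ifelse(g$swap, g$gap, 0)
  got <- cautious(g$d1, g$d2, g$d3, c1, c2, g$mean_compl, g$mean_compl,
                  tau = tau, delta = delta)
  want <- run_oracle(
    function(d1, d2, d3, c1, c2, x) {
      oracle_cautious(d1, d2, d3, c1, c2, x, x, tau, delta)
    },
    data.frame(g$d1, g$d2, g$d3, c1, c2, g$mean_compl)
  )
  expect_identical(got$decision, want$decision)
  expect_identical(got$judgments, want$judgments)
  expect_true(all(got$judgments %in% 2:3))
})

test_that("cautious trivial branches behave as specified", {
  # clear gap, low complexity: the more confident first-two reader decides
  expect_identical(cautious(1L, 0L, 0L, 0.75, 0.25, 0.3, 0.3)$decision, 1L)
  expect_identical(cautious(1L, 0L, 0L, 0.75, 0.25, 0.3, 0.3)$judgments, 2L)
  # equal confidences always escalate for tau > 0
  out <- cautious(1L, 0L, 0L, 0.5, 0.5, 0, 0)
  expect_identical(out$judgments, 3L)
  expect_identical(out$decision, 0L)
})

test_that("cautious with tau > 1 degenerates to the three-reader majority", {
  set.seed(7)
  n <- 100
  d1 <- sample(0:1, n, TRUE); d2 <- sample(0:1, n, TRUE)
  d3 <- sample(0:1, n, TRUE)
  c1 <- sample((0:4) / 4, n, TRUE); c2 <- sample((0:4) / 4, n, TRUE)
  x1 <- sample((0:3) / 3, n, TRUE); x2 <- sample((0:3) / 3, n, TRUE)
  got <- cautious(d1, d2, d3, c1, c2, x1, x2, tau = 1.5, delta = 1)
  want <- simple_majority(d1, d2, d3)
  expect_identical(got$decision, want$decision)
  expect_true(all(got$judgments == 3L))
})

test_that("cautious with tau 0, delta 1 equals presumptuous off confidence ties", {
  set.seed(8)
  n <- 200
  d1 <- sample(0:1, n, TRUE); d2 <- sample(0:1, n, TRUE)
  d3 <- sample(0:1, n, TRUE)
  c1 <- sample((0:4) / 4, n, TRUE); c2 <- sample((0:4) / 4, n, TRUE)
  got_c <- cautious(d1, d2, d3, c1, c2, 0.5, 0.5, tau = 0, delta = 1)
  got_p <- presumptuous(d1, d2, d3, c1, c2)
  off_tie <- c1 != c2
  expect_identical(got_c$decision[off_tie], got_p$decision[off_tie])
  expect_identical(got_c$judgments[off_tie], got_p$judgments[off_tie])
})

test_that("presumptuous matches the predicate oracle on orderings x triples", {
  g <- expand.grid(c1 = (0:4) / 4, c2 = (0:4) / 4,
                   d1 = 0:1, d2 = 0:1, d3 = 0:1)
  got <- presumptuous(g$d1, g$d2, g$d3, g$c1, g$c2)
  want <- run_oracle(oracle_presumptuous,
                     data.frame(g$d1, g$d2, g$d3, g$c1, g$c2))
  expect_identical(got$decision, want$decision)
  expect_identical(got$judgments, want$judgments)
  # spot checks
  expect_identical(presumptuous(0L, 1L, 1L, 0.75, 0.25)$decision, 0L)
  tie <- presumptuous(0L, 1L, 1L, 0.5, 0.5)
  expect_identical(tie$decision, 1L)
  expect_identical(tie$judgments, 3L)
})

test_that("OR rule is the logical OR with 1 or 2 judgments", {
  g <- expand.grid(d1 = 0:1, d2 = 0:1)
  got <- or_rule(g$d1, g$d2)
  want <- run_oracle(oracle_or, g)
  expect_identical(got$decision, want$decision)
  expect_identical(got$decision, as.integer(g$d1 | g$d2))
  expect_identical(got$judgments, want$judgments)
  expect_true(all(got$judgments %in% 1:2))
})

test_that("panel majority matches the counting oracle on all quintuples", {
  g <- as.matrix(expand.grid(rep(list(0:1), 5)))
  got <- majority_panel(t(g))
  want <- apply(g, 1, oracle_panel_majority)
  expect_identical(got, as.integer(want))
  expect_identical(majority_panel(matrix(1L, 1, 3)), rep(1L, 3))
  expect_error(majority_panel(matrix(0L, 2, 3)), "odd")
})

test_that("tau and delta equal their brute-force double-loop values", {
  conf <- rbind(c(2L, 5L), c(4L, 1L), c(3L, 3L))
  compl <- rbind(c(1L, 4L), c(2L, 3L), c(4L, 1L))
  dec <- matrix(0L, 3, 2)
  panel <- panel_from_matrices(dec, gold = c(0L, 1L), conf, compl)
  cn <- (conf - 1) / 4
  xn <- (compl - 1) / 3
  tau_oracle <- mean(sapply(1:2, function(cs) {
    gaps <- c()
    for (i in 1:2) for (j in (i + 1):3) {
      gaps <- c(gaps, abs(cn[i, cs] - cn[j, cs]))
    }
    mean(gaps)
  }))
  expect_equal(compute_tau(panel, readers = c("r01", "r02", "r03")),
               tau_oracle)
  expect_equal(compute_delta(panel, readers = c("r01", "r02", "r03")),
               mean(xn))
})

test_that("tau and delta boundary cases", {
  conf <- matrix(3L, 2, 3)
  panel <- panel_from_matrices(matrix(0L, 2, 3), gold = c(0L, 1L, 0L),
                               conf, matrix(4L, 2, 3))
  expect_equal(compute_tau(panel, readers = c("r01", "r02")), 0)
  expect_equal(compute_delta(panel, readers = c("r01", "r02")), 1)
  panel_lo <- panel_from_matrices(matrix(0L, 2, 3), gold = c(0L, 1L, 0L),
                                  conf, matrix(1L, 2, 3))
  expect_equal(compute_delta(panel_lo, readers = c("r01", "r02")), 0)
  # single-pair identity: |0.25 - 0.75| = 0.5
  p2 <- panel_from_matrices(matrix(0L, 2, 1), gold = 1L,
                            rbind(2L, 4L), rbind(2L, 2L))
  expect_equal(compute_tau(p2, readers = c("r01", "r02")), 0.5)
})

test_that("apply_protocol routes readings consistently with direct calls", {
  panel <- default_panel()
  team <- c("reader01", "mobilenet", "reader02")
  d <- sapply(team, function(r) {
    rr <- panel$readings[panel$readings$reader_id == r, ]
    rr$decision[match(panel$cases$case_id, rr$case_id)]
  })
  out <- apply_protocol(panel, team, "majority")
  want <- simple_majority(d[, 1], d[, 2], d[, 3])
  expect_identical(out$decision, want$decision)
  expect_identical(out$judgments, want$judgments)
  expect_error(apply_protocol(panel, c("reader01", "reader01", "reader02"),
                              "majority"), "distinct")
})

test_that("OR rule team sensitivity dominates both members' sensitivities", {
  panel <- default_panel()
  gold <- panel$cases$gold
  pos <- gold == 1L
  for (team in list(c("reader01", "mobilenet", "reader02"),
                    c("reader04", "mobilenet", "reader06"))) {
    out <- apply_protocol(panel, team, "or_rule")
    sens_team <- mean(out$decision[pos] == 1L)
    for (r in team[1:2]) {
      rr <- panel$readings[panel$readings$reader_id == r, ]
      dr <- rr$decision[match(panel$cases$case_id, rr$case_id)]
      expect_gte(sens_team, mean(dr[pos] == 1L))
    }
  }
})

test_that("judgment counts stay in each protocol's admissible range", {
  panel <- default_panel()
  team <- c("reader03", "mobilenet", "reader07")
  ranges <- list(majority = 2:3, acc_weighted = 2:3, conf_weighted = 2:3,
                 specific = 1:3, sensitive = 1:3, cautious = 2:3,
                 presumptuous = 2:3, or_rule = 1:2)
  for (pr in protocol_ids()) {
    out <- apply_protocol(panel, team, pr)
    expect_true(all(out$judgments %in% ranges[[pr]]), info = pr)
  }
})
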