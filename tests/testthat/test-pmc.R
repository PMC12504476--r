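test_that("primary scores are bit means, rounded half-up in rounded2 mode", {
  scores <- eldercare_scores()
  sv <- pmc_primary_scores(scores, "P1")
  expect_equal(sv$X3, 0.67) # bits (1,1,0)
  both <- pmc_score_table(tibble::tibble(
    policy = "Z", X11 = 1, X12 = 1, X21 = 1, X22 = 0, X23 = 1), tiny_schema())
  expect_equal(as.numeric(pmc_primary_scores(both, "Z")[c("X1", "X2")]),
               c(1.00, 0.67))
  expect_equal(as.numeric(
    pmc_primary_scores(both, "Z", mode = "exact")[c("X1", "X2")]),
    c(1, 2 / 3))
  expect_valid_error(pmc_primary_scores(scores, "nope"))
})

test_that("rounding is half-up, not banker's", {
  expect_equal(round_half_up(2 / 3, 2), 0.67)
  expect_equal(round_half_up(0.665, 2), 0.67) # base round() gives 0.66
  expect_equal(round_half_up(-0.665, 2), -0.67)
  expect_equal(round_half_up(c(0.125, 0.135), 2), c(0.13, 0.14))
})

test_that("the evaluation reproduces every published cell for the bundled table", {
  res <- pmc_evaluate(eldercare_scores())
  expect_equal(res$pmc_index,
               c(8.67, 7.49, 7.35, 6.23, 7.07, 8.47, 6.91, 6.62, 7.94, 7.02))
  expect_equal(res$policy[order(res$rank)],
               c("P1", "P6", "P9", "P2", "P3", "P5", "P10", "P7", "P8", "P4"))
  expect_equal(res$grade[res$policy == "P1"], "Reasonable and Complete")
  expect_equal(res$grade[res$policy == "P4"], "Weak applicability")
  g <- glance(res)
  expect_equal(g$mean_index, 7.38)
  expect_equal(g$n_reasonable_and_complete, 3)
  expect_equal(g$n_focused, 6)
  expect_equal(g$n_weak_applicability, 1)
})

test_that("an independent brute-force oracle reproduces every score, index, grade, and rank", {
  bits <- printed_bits()
  res <- pmc_evaluate(eldercare_scores())
  ids <- paste0("X", 1:9)
  for (p in names(bits)) {
    expected <- oracle_scores(bits[[p]])
    expect_equal(as.numeric(res[res$policy == p, ids]), expected, info = p)
    expect_equal(res$pmc_index[res$policy == p],
                 trunc(sum(expected) * 100 + 0.5) / 100, info = p)
  }
  oracle_idx <- sapply(bits, function(b) sum(oracle_scores(b)))
  expect_equal(res$rank, as.integer(rank(-oracle_idx, ties.method = "first")))
  oracle_grade <- ifelse(oracle_idx <= 6.5, "Weak applicability",
                         ifelse(oracle_idx <= 7.5, "Focused",
                                "Reasonable and Complete"))
  expect_equal(res$grade, unname(oracle_grade))
})

test_that("exact mode diverges from rounded2 exactly where round-before-sum bites", {
  ex <- pmc_evaluate(eldercare_scores(), mode = "exact")
  pick <- function(p) ex$pmc_index[ex$policy == p]
  expect_equal(pick("P2"), 7.48) # exact-fraction oracle: 1+1+2/3+2/3+3/5+1+1+4/5+3/4
  expect_equal(round_half_up(1 + 1 + 2/3 + 2/3 + 3/5 + 1 + 1 + 4/5 + 3/4, 2),
               7.48)
  expect_equal(pick("P7"), 6.90)
  expect_equal(pick("P9"), 7.93)
  # where no primary score has a repeating fraction the modes agree
  expect_equal(pick("P1"), 8.67)
})

test_that("grade classification uses left-open right-closed intervals", {
  expect_equal(pmc_classify(c(7.49, 6.23, 7.50, 9.00, 6.50, 0)),
               c("Focused", "Weak applicability", "Focused",
                 "Reasonable and Complete", "Weak applicability",
                 "Weak applicability"))
  expect_valid_error(pmc_classify(9.5))
  expect_valid_error(pmc_classify(-0.1))
  expect_valid_error(pmc_grade_scale(c(7.5, 6.5)))
  expect_valid_error(pmc_grade_scale(labels = c("a", "b")))
})

test_that("variable means and group means match the published summary rows", {
  res <- pmc_evaluate(eldercare_scores())
  m <- pmc_variable_means(res)
  expect_equal(m$mean,
               c(0.77, 1.00, 0.50, 0.77, 0.70, 1.00, 1.00, 0.84, 0.80))
  expect_equal(pmc_group_mean(res, c("P3", "P4", "P5", "P6")), 7.28)
  expect_equal(pmc_group_mean(res, c("P7", "P8", "P9", "P10")), 7.12)
  expect_equal(pmc_group_mean(res, "P5"), 7.07)
  expect_valid_error(pmc_group_mean(res, character()))
  expect_valid_error(pmc_group_mean(res, "P99"))
})

test_that("improvement paths follow gap order with ascending-index tie-break", {
  res <- pmc_evaluate(eldercare_scores())
  paths <- pmc_improvement_path(res, c("P3", "P4"))
  expect_equal(paths$primary[paths$policy == "P3"],
               c("X3", "X1", "X9", "X8"))
  expect_equal(paths$primary[paths$policy == "P4"],
               c("X4", "X9", "X3", "X1", "X5", "X8"))
  # strictly-below-mean membership: P1 beats or meets every mean
  expect_equal(nrow(pmc_improvement_path(res, "P1")), 0)
  # gaps are nonincreasing within a policy
  by_policy <- split(paths$gap, paths$policy)
  for (g in by_policy) expect_true(all(diff(g) <= 0))
})

test_that("flipping any bit upward never decreases a score or the index", {
  scores <- simulate_score_table(eldercare_schema(), 3, prob = 0.5, seed = 7)
  base <- pmc_evaluate(scores)
  ids <- setdiff(names(scores), "policy")
  zero_cells <- which(as.matrix(scores[ids]) == 0, arr.ind = TRUE)
  pick <- zero_cells[seq(1, nrow(zero_cells), length.out = min(12, nrow(zero_cells))), ,
                     drop = FALSE]
  for (k in seq_len(nrow(pick))) {
    flipped <- tibble::as_tibble(scores)
    flipped[pick[k, 1], ids[pick[k, 2]]] <- 1L
    res <- pmc_evaluate(pmc_score_table(flipped, eldercare_schema()))
    expect_true(all(res$pmc_index >= base$pmc_index))
    expect_true(all(as.matrix(res[paste0("X", 1:9)]) >=
                      as.matrix(base[paste0("X", 1:9)])))
  }
  expect_true(all(base$pmc_index >= 0 & base$pmc_index <= 9))
})

test_that("scores are invariant to reordering secondaries within a primary", {
  scores <- simulate_score_table(eldercare_schema(), 4, prob = 0.6, seed = 11)
  sch <- eldercare_schema()
  permuted <- tibble::as_tibble(scores)
  # swap the bit columns of primary 5 around: X51<->X55, X52<->X54
  permuted[paste0("X5", 1:5)] <- permuted[paste0("X5", c(5, 4, 3, 2, 1))]
  res1 <- pmc_evaluate(scores)
  res2 <- pmc_evaluate(pmc_score_table(permuted, sch))
  expect_equal(res2$pmc_index, res1$pmc_index)
  expect_equal(res2$X5, res1$X5)
})

test_that("tidy and glance expose the result in broom shapes", {
  res <- pmc_evaluate(eldercare_scores())
  td <- tidy(res)
  expect_equal(nrow(td), 90)
  expect_named(td, c("policy", "primary", "score", "pmc_index", "grade", "rank"))
  expect_equal(sum(td$score[td$policy == "P1"]), 8.67)
  g <- glance(res)
  expect_equal(g$n_policies, 10)
  # a single all-ones policy ranks first at the maximum index
  ones <- pmc_score_table(tibble::tibble(
    policy = "U", !!!stats::setNames(as.list(rep(1L, 33)),
                                     eldercare_schema()$id)),
    eldercare_schema())
  r1 <- pmc_evaluate(ones)
  expect_equal(r1$pmc_index, 9.00)
  expect_equal(r1$rank, 1L)
})
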