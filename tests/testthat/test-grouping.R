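test_that("ranking sorts by descending mean training confidence", {
  d <- dataset_from_matrices(matrix(1, 3, 1),
                             matrix(c(90, 50, 70), 3, 1))
  r <- rank_by_confidence(d, "Q001")
  expect_equal(r$participant_id, c("P001", "P003", "P002"))

  # mean over two training questions: A (80,40) -> 60, B (70,60) -> 65
  d2 <- dataset_from_matrices(matrix(1, 2, 2),
                              matrix(c(80, 70, 40, 60), 2, 2))
  r2 <- rank_by_confidence(d2, c("Q001", "Q002"))
  expect_equal(r2$participant_id, c("P002", "P001"))
  expect_equal(r2$mean_confidence, c(65, 60))

  expect_error(rank_by_confidence(d, "QX"), "unknown question")
  expect_error(rank_by_confidence(d, character()), "non-empty")
})

test_that("pure ties break uniformly at random, reproducibly under tie_seed", {
  d <- dataset_from_matrices(matrix(1, 6, 1), matrix(42, 6, 1))
  r1 <- rank_by_confidence(d, "Q001", tie_seed = 7)
  r2 <- rank_by_confidence(d, "Q001", tie_seed = 7)
  expect_identical(r1$participant_id, r2$participant_id)
  expect_setequal(r1$participant_id, participants(d))
  firsts <- vapply(1:30, function(s)
    rank_by_confidence(d, "Q001", tie_seed = s)$participant_id[1],
    character(1))
  expect_gt(length(unique(firsts)), 1L)
})

test_that("stride selection reproduces the canonical rank positions", {
  d <- dataset_from_matrices(matrix(1, 150, 1),
                             matrix(seq(100, 1, length.out = 150), 150, 1))
  r <- rank_by_confidence(d, "Q001")
  ranks_of <- function(ids) match(ids, r$participant_id)

  hi <- select_members(r, selection_scheme("highest", "stride", 3))
  expect_equal(ranks_of(hi), 1:3)
  hi15 <- select_members(r, selection_scheme("highest", "stride", 15))
  expect_equal(ranks_of(hi15), 1:15)
  higher <- select_members(r, selection_scheme("higher", "stride", 15))
  expect_equal(ranks_of(higher), seq(1, 71, by = 5))
  mixed <- select_members(r, selection_scheme("mixed", "stride", 15))
  expect_equal(ranks_of(mixed), seq(1, 141, by = 10))
})

test_that("random selection samples within the category pool", {
  d <- dataset_from_matrices(matrix(1, 149, 1),
                             matrix(seq(100, 1, length.out = 149), 149, 1))
  r <- rank_by_confidence(d, "Q001")
  # odd N: above-median pool is ranks 1..75
  for (s in 1:10) {
    got <- select_members(r, selection_scheme("higher", "random", 15),
                          rng_seed = s)
    ranks <- match(got, r$participant_id)
    expect_length(unique(got), 15L)
    expect_true(all(ranks >= 1 & ranks <= 75))
  }
  got1 <- select_members(r, selection_scheme("mixed", "random", 15), rng_seed = 3)
  got2 <- select_members(r, selection_scheme("mixed", "random", 15), rng_seed = 3)
  expect_identical(got1, got2)
  # highest is deterministic in both modes
  expect_equal(match(select_members(r, selection_scheme("highest", "random", 3)),
                     r$participant_id), 1:3)
  expect_error(select_members(r, selection_scheme("higher", "stride", 80)),
               "pool")
})

test_that("majority vote follows the strict majority and flags ties", {
  expect_equal(majority_vote(c("A", "A", "A", "B", "B")), "A")
  expect_equal(majority_vote("A"), "A")
  expect_error(majority_vote(c("A", "B")), "tie")
  t1 <- majority_vote(c("A", "B"), tie_seed = 11)
  expect_identical(t1, majority_vote(c("A", "B"), tie_seed = 11))
  expect_true(t1 %in% c("A", "B"))
  expect_equal(majority_vote(c(1, 1, 0)), 1)
})

test_that("weighted confidence vote sums ratings per alternative", {
  v <- weighted_confidence_vote(c("A", "A", "A", "B", "B"),
                                c(20, 30, 40, 80, 90))
  expect_equal(v$choice, "B")
  expect_equal(v$winning_sum, 170)
  u <- weighted_confidence_vote(rep("A", 4), c(1, 2, 3, 4))
  expect_equal(u$choice, "A")
  expect_equal(u$winning_sum, 10)
  expect_error(weighted_confidence_vote(c("A", "B"), c(10, 10)), "tie")
  expect_error(weighted_confidence_vote(c("A", "B"), c(-1, 5)), ">= 0")
})

test_that("weighted vote with equal confidences agrees with strict majority", {
  for (s in 1:20) {
    set.seed(s)
    m <- sample(c(3, 5, 7), 1)
    choices <- sample(c("A", "B"), m, replace = TRUE)
    if (length(unique(choices)) == 1 ||
        sum(choices == "A") * 2 == m) next
    v <- weighted_confidence_vote(choices, rep(10, m))
    expect_equal(v$choice, majority_vote(choices))
  }
})

test_that("transmission chain adopts the first choice then thresholded updates", {
  expect_equal(transmission_chain(c("A", "B", "A"), c(NA, 80, 30), 50), "B")
  expect_equal(transmission_chain(c("A", "B", "B"), c(10, 20, 30), 50), "A")
  expect_equal(transmission_chain("B", 5, 50), "B")
  expect_error(transmission_chain(character(), numeric(), 50), "non-empty")
})

test_that("accordance rate counts matching positions", {
  x <- c(1, 0, 0, 0, 1, 1, 1, 0, 1)
  y <- c(1, 1, 0, 1, 1, 0, 1, 0, 0)
  expect_equal(accordance_rate(x, y), 5 / 9)
  expect_equal(accordance_rate(x, x), 1)
  expect_equal(accordance_rate(x, 1 - x), 0)
  expect_error(accordance_rate(x, y[-1]), "length")
})

test_that("accordance is symmetric and complements normalized Hamming distance", {
  for (s in 1:10) {
    set.seed(100 + s)
    n <- sample(5:40, 1)
    x <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, 0.5)
    expect_equal(accordance_rate(x, y), accordance_rate(y, x))
    expect_equal(accordance_rate(x, y), 1 - sum(x != y) / n)
  }
})

test_that("group accuracy scores each question by the aggregation rule", {
  # all 3 members correct on all 5 questions
  d <- dataset_from_matrices(matrix(1, 3, 5))
  expect_equal(group_accuracy(d, participants(d), questions(d), "majority"), 1)

  # per-question correctness (1,1,0) then (1,0,0): majority right then wrong
  d2 <- dataset_from_matrices(cbind(c(1, 1, 0), c(1, 0, 0)))
  expect_equal(group_accuracy(d2, participants(d2), questions(d2), "majority"),
               0.5)

  # weighted: wrong members hold the confidence mass on Q1
  d3 <- dataset_from_matrices(cbind(c(1, 1, 0), c(1, 0, 0)),
                              cbind(c(10, 10, 95), c(40, 10, 10)))
  expect_equal(group_accuracy(d3, participants(d3), questions(d3), "weighted"),
               0.5)

  # chain with threshold 50: only the last, correct member updates on Q1
  d4 <- dataset_from_matrices(cbind(c(0, 0, 1), c(1, 1, 1)),
                              cbind(c(90, 20, 80), c(50, 50, 50)))
  expect_equal(group_accuracy(d4, participants(d4), questions(d4), "chain"), 1)

  expect_error(group_accuracy(d2, "P009", questions(d2)), "participant")
  expect_error(group_accuracy(d2, participants(d2), "Q999"), "question")
})

test_that("a group of identical members scores the individual accuracy", {
  set.seed(8)
  row <- rbinom(40, 1, 0.7)
  d <- dataset_from_matrices(matrix(rep(row, each = 5), 5))
  acc <- group_accuracy(d, participants(d), questions(d), "majority")
  expect_equal(acc, mean(row))
})

test_that("majority-rule group accuracy matches the Condorcet binomial oracle", {
  d <- iid_dataset(15, 200, p = 0.6, seed = 123)
  acc <- group_accuracy(d, participants(d), questions(d), "majority")
  expected <- condorcet_oracle(15, 0.6)
  se <- sqrt(expected * (1 - expected) / 200)
  expect_lt(abs(acc - expected), 3 * se)
})

test_that("pairwise accordance of independent responders matches pq+(1-p)(1-q)", {
  set.seed(9)
  n <- 3000
  p <- 0.7; q <- 0.55
  x <- rbinom(n, 1, p)
  y <- rbinom(n, 1, q)
  expected <- p * q + (1 - p) * (1 - q)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(accordance_rate(x, y) - expected), 3 * se)
})
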