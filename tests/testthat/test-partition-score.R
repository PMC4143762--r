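test_that("partition score reproduces hand-computed values", {
  expect_equal(partitionScore(c(1, 2, 3, 4), c("A", "A", "B", "B")), 1.2)
  # all subjects in one level: every level mean is the grand mean
  expect_equal(partitionScore(rnorm(10), rep("x", 10)), 0)
})

test_that("singleton partitions score (n-1)/n for distinct phenotypes", {
  for (n in c(2, 4, 7, 19)) {
    y <- sample(seq_len(n) * 1.7)
    expect_equal(partitionScore(y, seq_len(n)), (n - 1) / n)
  }
})

test_that("partition score matches the naive double-loop oracle", {
  set.seed(421)
  for (i in 1:120) {
    inst <- randomInstance()
    got <- partitionScore(inst$y, inst$labels)
    want <- naivePartitionScore(inst$y, inst$labels)
    expect_lt(abs(got - want) / max(abs(want), 1e-300), 1e-12)
    expect_gte(got, 0)
  }
})

test_that("score is invariant under affine phenotype transforms and label renaming", {
  set.seed(99)
  for (i in 1:50) {
    inst <- randomInstance()
    base <- partitionScore(inst$y, inst$labels)
    a <- runif(1, 0.1, 10) * sample(c(-1, 1), 1)
    b <- runif(1, -100, 100)
    expect_lt(abs(partitionScore(a * inst$y + b, inst$labels) - base), 1e-10)
    renamed <- match(inst$labels, sample(unique(inst$labels)))
    expect_equal(partitionScore(inst$y, renamed), base)
  }
})

test_that("variance convention rescales the score by a constant factor", {
  set.seed(5)
  inst <- randomInstance(n = 20)
  n <- 20
  # ml variance is smaller by (n-1)/n, so the score grows by n/(n-1)
  expect_equal(partitionScore(inst$y, inst$labels, varMethod = "ml"),
               partitionScore(inst$y, inst$labels) * n / (n - 1))
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(partitionScore(rep(3, 5), c(1, 1, 2, 2, 2)), "constant")
  expect_error(partitionScore(numeric(0), character(0)), "at least 2")
  expect_error(partitionScore(c(1, NA, 3), c(1, 2, 3)), "missing")
  expect_error(partitionScore(1:4, 1:3), "same length")
})

test_that("joint/marginal decomposition matches brute force on a 2x2 design", {
  # two subjects per cell, cell means 0/1/1/0, zero within-cell variance
  g <- rep(c(0, 0, 1, 1), each = 2)
  e <- rep(c(0, 1, 0, 1), each = 2)
  y <- rep(c(0, 1, 1, 0), each = 2)
  s <- gxeScores(y, g, e)
  expect_equal(scoreG(s), 0)
  expect_equal(scoreE(s), 0)
  expect_equal(scoreTotal(s), 1.75)
  expect_equal(scoreGxE(s), 1.75)
  expect_equal(sum(cellCounts(s)), 8)
  expect_equal(nUsed(s), 8L)
})

test_that("interaction score is exactly total minus the larger marginal", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(6:40, 1)
    y <- rnorm(n)
    g <- sample(0:2, n, replace = TRUE)
    e <- sample(0:2, n, replace = TRUE)
    s <- gxeScores(y, g, e)
    expect_identical(scoreGxE(s), scoreTotal(s) - max(scoreG(s), scoreE(s)))
    jt <- interaction(factor(g), factor(e), drop = TRUE)
    expect_equal(scoreTotal(s), naivePartitionScore(y, as.character(jt)),
                 tolerance = 1e-12)
    expect_equal(scoreG(s), naivePartitionScore(y, g), tolerance = 1e-12)
    expect_equal(scoreE(s), naivePartitionScore(y, e), tolerance = 1e-12)
  }
})

test_that("a constant environment collapses the decomposition", {
  set.seed(8)
  y <- rnorm(25)
  g <- sample(0:2, 25, replace = TRUE)
  s <- gxeScores(y, g, rep(1, 25))
  expect_equal(scoreE(s), 0)
  expect_equal(scoreTotal(s), scoreG(s))
  expect_equal(scoreGxE(s), 0)
})

test_that("cell means equal to the grand mean zero every score", {
  g <- rep(c(0, 0, 1, 1), each = 2)
  e <- rep(c(0, 1, 0, 1), each = 2)
  y <- rep(c(-1, 1), 4)
  s <- gxeScores(y, g, e)
  expect_equal(scoreTotal(s), 0)
  expect_equal(scoreG(s), 0)
  expect_equal(scoreE(s), 0)
  expect_equal(scoreGxE(s), 0)
})

test_that("complete-case filtering drops subjects missing any of the triple", {
  y <- c(1, 2, NA, 4, 5, 6)
  g <- c(0, NA, 1, 1, 2, 0)
  e <- c(0, 1, 1, NA, 0, 1)
  s <- gxeScores(y, g, e)
  expect_equal(nUsed(s), 3L)
  expect_equal(sum(cellCounts(s)), 3)
})

test_that("all subjects in one joint cell return zero scores, not an error", {
  s <- gxeScores(rep(2.5, 6), rep(1, 6), rep(0, 6))
  expect_equal(scoreTotal(s), 0)
  expect_equal(scoreGxE(s), 0)
  # constant phenotype across several cells is still an error
  expect_error(gxeScores(rep(2.5, 6), c(0, 0, 0, 1, 1, 1), rep(0, 6)),
               "constant")
})

test_that("empty genotype classes are skipped, not scored", {
  set.seed(12)
  y <- rnorm(30)
  g <- sample(0:1, 30, replace = TRUE)   # no homozygous-minor subjects
  e <- sample(0:2, 30, replace = TRUE)
  s <- gxeScores(y, g, e)
  expect_equal(scoreG(s), naivePartitionScore(y, g), tolerance = 1e-12)
  expect_true(is.finite(scoreGxE(s)))
  expect_equal(dim(cellCounts(s)), c(2L, 3L))
})
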