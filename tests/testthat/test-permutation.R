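test_that("pedigree decomposition has zero-sum residuals and reconstructs means", {
  set.seed(10)
  y <- rnorm(40, mean = 100, sd = 15)
  ped <- sample(sprintf("f%d", 1:6), 40, replace = TRUE)
  d <- pedigreeResiduals(y, ped)
  for (p in unique(ped)) {
    expect_lt(abs(sum(d$residuals[ped == p])) / max(abs(y)), 1e-9)
    expect_equal(unname(d$pedMeans[p]), mean(y[ped == p]))
  }
  expect_equal(d$fitted + d$residuals, y)
})

test_that("global permutation preserves the phenotype multiset", {
  set.seed(2)
  y <- rnorm(25)
  expect_equal(sort(permuteGlobal(y)), sort(y))
  expect_equal(permuteGlobal(3.14), 3.14)
})

test_that("global permutation is uniform over arrangements", {
  set.seed(123)
  draws <- replicate(10000, paste(permuteGlobal(c(1, 2, 3)), collapse = ""))
  freq <- table(draws) / 10000
  expect_equal(length(freq), 6L)
  se <- sqrt((1 / 6) * (5 / 6) / 10000)
  expect_true(all(abs(freq - 1 / 6) <= 3 * se))
})

test_that("local permutation never crosses pedigree boundaries", {
  set.seed(4)
  ped <- c(1, 1, 2, 2)
  out <- permuteLocal(c(1, 2, 3, 4), ped)
  expect_setequal(out[1:2], c(1, 2))
  expect_setequal(out[3:4], c(3, 4))
  for (i in 1:20) {
    y <- rnorm(30)
    pp <- sample(sprintf("f%d", 1:5), 30, replace = TRUE)
    out <- permuteLocal(y, pp)
    for (p in unique(pp)) {
      expect_equal(sort(out[pp == p]), sort(y[pp == p]))
      expect_identical(mean(out[pp == p]), mean(out[pp == p]))
    }
  }
  # singleton pedigrees: nothing can move
  expect_equal(permuteLocal(c(5, 6, 7), c("a", "b", "c")), c(5, 6, 7))
})

test_that("residual permutation reattaches shuffled residuals to pedigree means", {
  set.seed(6)
  y <- c(1, 3, 10, 14)
  ped <- c(1, 1, 2, 2)
  d <- pedigreeResiduals(y, ped)
  expect_equal(d$fitted, c(2, 2, 12, 12))
  expect_equal(d$residuals, c(-1, 1, -2, 2))
  for (i in 1:20) {
    out <- permuteResidual(y, ped)
    expect_equal(sort(out - d$fitted), sort(d$residuals))
    expect_equal(sum(out), sum(y))
  }
  # the hand-enumerated rearrangement (2, -2, 1, -1) is a reachable output
  expect_equal(c(2, 2, 12, 12) + c(2, -2, 1, -1), c(4, 0, 13, 11))
  # singleton pedigrees: all residuals are zero
  expect_equal(permuteResidual(c(5, 6, 7), c("a", "b", "c")), c(5, 6, 7))
})

test_that("residual permutation preserves the grand sum on random inputs", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    y <- rnorm(n, 50, 20)
    ped <- sample(sprintf("f%d", 1:7), n, replace = TRUE)
    out <- permuteResidual(y, ped)
    expect_lt(abs(sum(out) - sum(y)) / abs(sum(y)), 1e-9)
  }
})

test_that("permutation p-values use the add-one estimator and its bounds", {
  set.seed(20)
  y <- rnorm(30)
  g <- sample(0:2, 30, replace = TRUE)
  statFn <- function(yy) scoreGxE(gxeScores(yy, g, rep(0:2, 10)))
  # observed far above anything attainable
  p <- permutationPValue(1e9, statFn, y, scheme = "global", B = 999, seed = 1)
  expect_equal(p, 1 / 1000)
  # observed below every permuted statistic
  p <- permutationPValue(-1e9, statFn, y, scheme = "global", B = 99, seed = 1)
  expect_equal(p, 1)
  # reproducibility and range
  p1 <- permutationPValue(0.5, statFn, y, scheme = "global", B = 199, seed = 42)
  p2 <- permutationPValue(0.5, statFn, y, scheme = "global", B = 199, seed = 42)
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 200)
  expect_lte(p1, 1)
})

test_that("vectorized engine agrees with the generic path draw-for-draw", {
  set.seed(30)
  n <- 50
  y <- rnorm(n)
  g <- sample(0:2, n, replace = TRUE)
  e <- sample(0:2, n, replace = TRUE)
  ped <- rep(1:5, each = 10)
  res <- pbiTest(y, g, e, pedigree = ped, schemes = c("global", "residual"),
                 B = 199, seed = 77)
  obs <- scoreGxE(gxeScores(y, g, e))
  statFn <- function(yy) scoreGxE(gxeScores(yy, g, e))
  # global and residual schemes consume the RNG stream in the same order
  pG <- permutationPValue(obs, statFn, y, ped, "global", B = 199,
                          seed = pbiScan:::deriveSeed(77, "global"))
  pR <- permutationPValue(obs, statFn, y, ped, "residual", B = 199,
                          seed = pbiScan:::deriveSeed(77, "residual"))
  expect_identical(unname(res$p["global"]), pG)
  expect_identical(unname(res$p["residual"]), pR)
})

test_that("degenerate pedigree structures collapse the schemes as expected", {
  set.seed(40)
  n <- 40
  y <- rnorm(n)
  g <- sample(0:2, n, replace = TRUE)
  e <- sample(0:2, n, replace = TRUE)
  # singleton pedigrees: local and residual permutation are the identity,
  # so every permuted statistic ties the observed one and p is exactly 1
  res <- pbiTest(y, g, e, pedigree = seq_len(n), B = 199, seed = 5)
  expect_equal(unname(res$p["local"]), 1)
  expect_equal(unname(res$p["residual"]), 1)
  # one pedigree spanning all subjects: the three schemes generate the
  # same permuted phenotypes draw-for-draw, hence identical p-values
  obs <- scoreGxE(gxeScores(y, g, e))
  statFn <- function(yy) scoreGxE(gxeScores(yy, g, e))
  ped1 <- rep(1, n)
  ps <- vapply(c("global", "local", "residual"), function(sc) {
    permutationPValue(obs, statFn, y, ped1, sc, B = 199, seed = 31)
  }, numeric(1))
  expect_equal(unname(ps["local"]), unname(ps["global"]))
  expect_equal(unname(ps["residual"]), unname(ps["global"]))
})

test_that("per-test seed derivation is deterministic and order-free", {
  s1 <- pbiScan:::deriveSeed(7, 12, "env_age", "global")
  s2 <- pbiScan:::deriveSeed(7, 12, "env_age", "global")
  s3 <- pbiScan:::deriveSeed(7, 13, "env_age", "global")
  expect_identical(s1, s2)
  expect_false(s1 == s3)
  expect_true(s1 >= 1 && s1 < 2^31)
})

test_that("pbiTest is reproducible and scheme-order invariant", {
  set.seed(50)
  n <- 60
  y <- rnorm(n)
  g <- sample(0:2, n, replace = TRUE)
  e <- sample(0:2, n, replace = TRUE)
  ped <- rep(1:6, each = 10)
  a <- pbiTest(y, g, e, ped, schemes = c("global", "local", "residual"),
               B = 99, seed = 13)
  b <- pbiTest(y, g, e, ped, schemes = c("residual", "global", "local"),
               B = 99, seed = 13)
  expect_identical(a$p[c("global", "local", "residual")],
                   b$p[c("global", "local", "residual")])
})
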