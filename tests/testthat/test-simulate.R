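test_that("identical configs generate identical cohorts", {
  cfg <- simConfig(nPedigrees = 5, pedigreeSize = c(3, 12),
                   nSnps = 4, model = "linear_gxe", seed = 66)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(subjectTable(a), subjectTable(b))
  expect_identical(dosage(a), dosage(b))
  expect_identical(causalSnp(a), causalSnp(b))
})

test_that("genotypes follow Hardy-Weinberg proportions at the configured MAF", {
  coh <- simulateCohort(simConfig(nPedigrees = 400, pedigreeSize = 25,
                                  maf = 0.3, model = "null", seed = 17))
  n <- 10000
  freq <- tabulate(dosage(coh)[1, ] + 1L, 3L) / n
  expected <- c(0.49, 0.42, 0.09)
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(freq - expected) <= 3 * se))
})

test_that("the crossing model is pure interaction: marginals vanish, I_GxE is large", {
  coh <- simulateCohort(simConfig(model = "crossing_gxe", sigmaFam = 0,
                                  sigmaE = 1e-3, seed = 23))
  s <- subjectTable(coh)
  g <- dosage(coh)[causalSnp(coh), ]
  sco <- gxeScores(s$y, g, s$env)
  expect_gt(scoreGxE(sco), 10)
  # marginal scores reflect only cell-count sampling noise
  expect_lt(scoreG(sco), scoreGxE(sco) / 10)
  expect_lt(scoreE(sco), scoreGxE(sco) / 10)
})

test_that("crossing cell means are non-monotone and opposite between genotypes", {
  M <- pbiScan:::.crossingTable(0.3, 0.5)
  # expected marginals vanish exactly
  w <- c(0.49, 0.42, 0.09)
  expect_equal(as.numeric(w %*% M), rep(0, 3), tolerance = 1e-12)
  expect_equal(rowMeans(M), rep(0, 3), tolerance = 1e-12)
  # genotype 1: down then up; genotype 0: up then down
  expect_lt(M[2, 2], M[2, 1]); expect_lt(M[2, 2], M[2, 3])
  expect_gt(M[1, 2], M[1, 1]); expect_gt(M[1, 2], M[1, 3])
})

test_that("sibship genotypes and family environment cluster within pedigrees", {
  cfg <- simConfig(nPedigrees = 50, pedigreeSize = 10, nSnps = 1,
                   genoModel = "sibship", envModel = "family", seed = 31)
  coh <- simulateCohort(cfg)
  s <- subjectTable(coh)
  g <- dosage(coh)[1, ]
  withinVar <- mean(tapply(g, s$pedigree_id, var))
  expect_lt(withinVar, var(g))   # genotype variance partly between families
  concord <- mean(tapply(s$env, s$pedigree_id,
                         function(v) max(table(v)) / length(v)))
  expect_gt(concord, 0.6)        # most members share the pedigree base level
  # i.i.d. environment has no such concordance
  cfg2 <- simConfig(nPedigrees = 50, pedigreeSize = 10, seed = 31)
  s2 <- subjectTable(simulateCohort(cfg2))
  concord2 <- mean(tapply(s2$env, s2$pedigree_id,
                          function(v) max(table(v)) / length(v)))
  expect_lt(concord2, concord)
})

test_that("uncentred bilinear interactions are marginal-dominated: I_GxE < 0", {
  # the n_i^2 weighting dilutes a class split across cells, so interaction
  # structure that merely accompanies strong induced marginals drives the
  # interaction score negative — a documented blind spot of the statistic
  coh <- simulateCohort(simConfig(model = "linear_gxe", centerGxE = FALSE,
                                  betaGE = 1, sigmaFam = 0, seed = 44))
  s <- subjectTable(coh)
  g <- dosage(coh)[1, ]
  expect_lt(scoreGxE(gxeScores(s$y, g, s$env)), 0)
  # double-centring the same model family isolates pure interaction
  coh2 <- simulateCohort(simConfig(model = "linear_gxe", betaG = 0,
                                   betaE = 0, betaGE = 1, sigmaFam = 0,
                                   seed = 44))
  s2 <- subjectTable(coh2)
  expect_gt(scoreGxE(gxeScores(s2$y, dosage(coh2)[1, ], s2$env)), 1)
})

test_that("invalid configurations fail before any sampling", {
  expect_error(simConfig(maf = 0.7))
  expect_error(simConfig(maf = 0))
  expect_error(simConfig(sigmaE = -1))
  expect_error(simConfig(model = "epistasis"))
  expect_error(simConfig(nSnps = 2, causalIndex = 3))
  expect_error(simulateCohort(list(nPedigrees = 2)), "simConfig")
})

test_that("power experiment is reproducible and reports Monte-Carlo error", {
  cfg <- simConfig(nPedigrees = 5, pedigreeSize = 10, model = "crossing_gxe",
                   crossingD = 1, seed = 1)
  a <- powerExperiment(cfg, schemes = "global", B = 49, replicates = 30,
                       seed = 8)
  b <- powerExperiment(cfg, schemes = "global", B = 49, replicates = 30,
                       seed = 8)
  expect_identical(a, b)
  expect_true(all(a$rate >= 0 & a$rate <= 1))
  expect_equal(a$mcse, sqrt(a$rate * (1 - a$rate) / 30))
  expect_setequal(a$method, c("pbi_global", "lrm"))
})
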