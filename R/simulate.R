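#' @include AllClasses.R permutation.R
NULL

.simModels <- c("null", "marginal_g", "additive", "linear_gxe", "crossing_gxe")

#' Simulation configuration for pedigree cohorts
#'
#' Validates and freezes the parameters of the synthetic-cohort generator.
#' Defaults describe the package's reference study condition: 20 pedigrees
#' of 25 subjects (n = 500), minor allele frequency 0.3, an exchangeable
#' within-pedigree random intercept with standard deviation `sigmaFam`
#' (trait units), residual noise `sigmaE = 1`, and a uniformly distributed
#' three-level environment.
#'
#' Phenotype models (effects act through the causal SNP's dosage `G` and
#' the environment level `E`):
#' \describe{
#'   \item{null}{no genetic or environmental term.}
#'   \item{marginal_g}{`betaG * G`.}
#'   \item{additive}{`betaG * G + betaE * E`.}
#'   \item{linear_gxe}{additive plus a bilinear interaction term. With
#'     `centerGxE = TRUE` (default) the term is
#'     `betaGE * (G - E[G]) * (E - E[E])` — double-centred at the
#'     population means, so `betaGE` controls *pure* linear interaction
#'     strength with no induced marginal effects. Centring only shifts the
#'     intercept and additive coefficients of the equivalent
#'     `b0 + b1 G + b2 E + b3 GxE` form (b3 is `betaGE` either way);
#'     `centerGxE = FALSE` gives the raw `betaGE * G * E` term, whose
#'     induced marginal effects dominate the joint structure under the
#'     partition score's cell-size weighting (the interaction score is then
#'     negative: the score is deliberately blind to interactions explicable
#'     by marginals).}
#'   \item{crossing_gxe}{a 3 x 3 cell-mean table whose environment profile
#'     is non-monotone and of opposite shape between genotype classes.
#'     The default table is `crossingD * a_g * v_e` with
#'     `v = (-1, 2, -1)` and `a = (1, -1, (w1 - w0)/w2)` where `w` are the
#'     Hardy-Weinberg genotype frequencies at the configured MAF — so both
#'     expected marginal means are exactly zero across levels: a *pure*
#'     interaction that a linear interaction term cannot see. For genotype
#'     class 1 the phenotype first decreases then increases over the
#'     environment levels; for class 0 it first increases then decreases.}
#' }
#'
#' Genotype models: `"iid"` draws every subject's dosage independently as
#' Binomial(2, maf) (Hardy-Weinberg proportions); `"sibship"` draws two
#' Hardy-Weinberg parents per pedigree and transmits one allele from each,
#' so genotypes are correlated within pedigrees as in real family data —
#' the condition under which global permutation loses validity while local
#' and residual permutation retain it.
#'
#' @param nPedigrees number of pedigrees.
#' @param pedigreeSize subjects per pedigree: a single size or a
#'   `c(min, max)` range sampled uniformly per pedigree.
#' @param nSnps number of SNPs to simulate.
#' @param maf minor allele frequency in (0, 0.5].
#' @param sigmaFam between-pedigree standard deviation (trait units).
#' @param sigmaE residual standard deviation (trait units).
#' @param mu grand mean (trait units).
#' @param model phenotype model, one of
#'   `"null"`, `"marginal_g"`, `"additive"`, `"linear_gxe"`, `"crossing_gxe"`.
#' @param betaG,betaE,betaGE effect sizes for the parametric models.
#' @param centerGxE centre the bilinear interaction term at the population
#'   means of G and E (see the linear_gxe model description).
#' @param crossingD half-range of the crossing cell-mean table.
#' @param cellMeans optional explicit 3 x 3 matrix (genotype x environment)
#'   overriding the default crossing table.
#' @param envFreq length-3 positive weights for environment levels 0/1/2.
#' @param genoModel `"iid"` or `"sibship"`.
#' @param envModel `"iid"` draws every subject's environment level
#'   independently from `envFreq`; `"family"` draws one base level per
#'   pedigree and each member adopts it with probability `envRho`
#'   (otherwise an independent draw), emulating covariates such as age
#'   band, medication use or smoking that cluster within families.
#' @param envRho adoption probability for the family environment model.
#' @param causalIndex which simulated SNP carries the effect (ignored under
#'   the null model).
#' @param seed integer seed; identical configs generate identical cohorts.
#' @return a validated list of class `"pbiSimConfig"`.
#' @seealso [simulateCohort()]
#' @export
simConfig <- function(nPedigrees = 20L, pedigreeSize = 25L, nSnps = 1L,
                      maf = 0.3, sigmaFam = 0.5, sigmaE = 1, mu = 0,
                      model = c("null", "marginal_g", "additive",
                                "linear_gxe", "crossing_gxe"),
                      betaG = 0.3, betaE = 0.3, betaGE = 0.5,
                      centerGxE = TRUE,
                      crossingD = 0.5, cellMeans = NULL,
                      envFreq = c(1, 1, 1) / 3,
                      genoModel = c("iid", "sibship"),
                      envModel = c("iid", "family"), envRho = 0.8,
                      causalIndex = 1L, seed = 1L) {
  model <- match.arg(model)
  genoModel <- match.arg(genoModel)
  envModel <- match.arg(envModel)
  stopifnot(nPedigrees >= 1L, nSnps >= 1L,
            length(pedigreeSize) %in% 1:2, all(pedigreeSize >= 1L),
            maf > 0, maf <= 0.5, sigmaFam >= 0, sigmaE >= 0,
            length(envFreq) == 3L, all(envFreq > 0),
            envRho >= 0, envRho <= 1,
            causalIndex >= 1L, causalIndex <= nSnps)
  if (!is.null(cellMeans)) {
    cellMeans <- as.matrix(cellMeans)
    stopifnot(identical(dim(cellMeans), c(3L, 3L)))
  }
  structure(list(nPedigrees = as.integer(nPedigrees),
                 pedigreeSize = as.integer(pedigreeSize),
                 nSnps = as.integer(nSnps), maf = maf,
                 sigmaFam = sigmaFam, sigmaE = sigmaE, mu = mu,
                 model = model, betaG = betaG, betaE = betaE,
                 betaGE = betaGE, centerGxE = isTRUE(centerGxE),
                 crossingD = crossingD,
                 cellMeans = cellMeans, envFreq = envFreq / sum(envFreq),
                 genoModel = genoModel, envModel = envModel, envRho = envRho,
                 causalIndex = as.integer(causalIndex),
                 seed = as.integer(seed)),
            class = "pbiSimConfig")
}

# default pure-interaction cell-mean table (see simConfig docs)
.crossingTable <- function(maf, d) {
  w <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  a <- c(1, -1, (w[2] - w[1]) / w[3])
  v <- c(-1, 2, -1)
  d * outer(a, v)
}

#' Simulate a pedigree cohort with genotypes, environment, and phenotype
#'
#' Draws a cohort under a [simConfig()]: pedigree sizes, genotypes
#' (Hardy-Weinberg, i.i.d. or sibship-correlated), a categorical
#' environment, a shared normal pedigree intercept, and the phenotype
#' \deqn{y = \mu + a_{ped} + f(G, E) + \epsilon}
#' with `f` given by the configured model and independent
#' N(0, sigmaE^2) noise. The generator is fully seeded: identical configs
#' produce identical cohorts.
#'
#' @param config a `"pbiSimConfig"` from [simConfig()].
#' @return a [SimCohort-class].
#' @examples
#' coh <- simulateCohort(simConfig(nPedigrees = 5, pedigreeSize = 8,
#'                                 model = "crossing_gxe", seed = 42))
#' coh
#' @export
simulateCohort <- function(config) {
  if (!inherits(config, "pbiSimConfig")) {
    stop("'config' must come from simConfig()")
  }
  cfg <- config
  withSeed(cfg$seed, {
    sizes <- if (length(cfg$pedigreeSize) == 1L) {
      rep(cfg$pedigreeSize, cfg$nPedigrees)
    } else {
      sample(seq(cfg$pedigreeSize[1], cfg$pedigreeSize[2]),
             cfg$nPedigrees, replace = TRUE)
    }
    n <- sum(sizes)
    pedId <- rep(sprintf("ped%03d", seq_len(cfg$nPedigrees)), sizes)
    subjId <- sprintf("s%05d", seq_len(n))

    gmat <- matrix(0L, cfg$nSnps, n)
    if (cfg$genoModel == "iid") {
      gmat[] <- stats::rbinom(cfg$nSnps * n, 2L, cfg$maf)
    } else {
      # two HWE parents per pedigree; members are siblings: one allele
      # transmitted from each parent per SNP
      offs <- cumsum(c(0L, sizes))
      for (p in seq_len(cfg$nPedigrees)) {
        k <- sizes[p]
        cols <- offs[p] + seq_len(k)
        gf <- stats::rbinom(cfg$nSnps, 2L, cfg$maf)
        gm <- stats::rbinom(cfg$nSnps, 2L, cfg$maf)
        a1 <- matrix(stats::rbinom(cfg$nSnps * k, 1L, gf / 2), cfg$nSnps, k)
        a2 <- matrix(stats::rbinom(cfg$nSnps * k, 1L, gm / 2), cfg$nSnps, k)
        gmat[, cols] <- a1 + a2
      }
    }
    colnames(gmat) <- subjId

    env <- sample(0:2, n, replace = TRUE, prob = cfg$envFreq)
    if (cfg$envModel == "family") {
      pedBase <- sample(0:2, cfg$nPedigrees, replace = TRUE, prob = cfg$envFreq)
      adopt <- stats::rbinom(n, 1L, cfg$envRho) == 1L
      env[adopt] <- rep(pedBase, sizes)[adopt]
    }
    famEff <- rep(stats::rnorm(cfg$nPedigrees, 0, cfg$sigmaFam), sizes)

    causal <- if (cfg$model == "null") NA_integer_ else cfg$causalIndex
    g <- if (is.na(causal)) integer(n) else gmat[causal, ]
    eff <- switch(cfg$model,
      null = numeric(n),
      marginal_g = cfg$betaG * g,
      additive = cfg$betaG * g + cfg$betaE * env,
      linear_gxe = {
        gC <- if (cfg$centerGxE) g - 2 * cfg$maf else g
        eC <- if (cfg$centerGxE) env - sum(cfg$envFreq * (0:2)) else env
        cfg$betaG * g + cfg$betaE * env + cfg$betaGE * gC * eC
      },
      crossing_gxe = {
        M <- if (is.null(cfg$cellMeans)) {
          .crossingTable(cfg$maf, cfg$crossingD)
        } else cfg$cellMeans
        M[cbind(g + 1L, env + 1L)]
      }
    )
    y <- cfg$mu + famEff + eff + stats::rnorm(n, 0, cfg$sigmaE)

    info <- data.frame(snp_id = sprintf("snp%05d", seq_len(cfg$nSnps)),
                       chrom = "3", pos = 1000L * seq_len(cfg$nSnps),
                       ref = "A", alt = "B", stringsAsFactors = FALSE)
    subjects <- data.frame(subject_id = subjId, pedigree_id = pedId,
                           env = env, y = y, stringsAsFactors = FALSE)
    methods::new("SimCohort",
                 subjects = subjects,
                 genotypes = genotypeMatrix(gmat, info),
                 causal = causal,
                 config = unclass(cfg))
  })
}
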