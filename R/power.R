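#' @include simulate.R scan.R
NULL

#' Type-I error and power experiment over simulated cohorts
#'
#' For each configuration, simulates `replicates` independent cohorts,
#' tests the causal SNP (or the first SNP under the null model) with the
#' partition interaction test under each requested permutation scheme and
#' with the linear-model comparator, and reports the fraction of
#' replicates with p <= alpha together with its Monte-Carlo standard
#' error \eqn{\sqrt{\hat p (1 - \hat p) / R}}. Under a null configuration
#' the reported fraction is the empirical type-I error; under a signal
#' configuration it is power. Fully seeded: the r-th replicate of the
#' c-th configuration has its own stream derived from `seed`, so results
#' are reproducible and order-independent.
#'
#' @param configs a single [simConfig()] or a (optionally named) list of them.
#' @param schemes permutation schemes for the partition test.
#' @param B permutations per test.
#' @param replicates simulated cohorts per configuration.
#' @param alpha rejection level.
#' @param seed integer base seed.
#' @param withLrm also run the linear-model comparator.
#' @return data.frame with one row per configuration x method:
#'   `config`, `model`, `method`, `rejections`, `replicates`, `rate`,
#'   `mcse`.
#' @examples
#' powerExperiment(simConfig(nPedigrees = 5, pedigreeSize = 10,
#'                           model = "crossing_gxe"),
#'                 schemes = "global", B = 49, replicates = 20, seed = 9)
#' @export
powerExperiment <- function(configs, schemes = c("global", "local", "residual"),
                            B = 199L, replicates = 200L, alpha = 0.05,
                            seed = 1L, withLrm = TRUE) {
  if (inherits(configs, "pbiSimConfig")) configs <- list(configs)
  if (is.null(names(configs))) {
    names(configs) <- vapply(configs, function(cf) cf$model, character(1))
    names(configs) <- make.unique(names(configs))
  }
  schemes <- match.arg(schemes, .schemes, several.ok = TRUE)
  methodsRun <- c(paste0("pbi_", schemes), if (withLrm) "lrm")
  out <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    if (!inherits(cfg, "pbiSimConfig")) stop("configs must come from simConfig()")
    hits <- stats::setNames(integer(length(methodsRun)), methodsRun)
    for (r in seq_len(replicates)) {
      repSeed <- deriveSeed(seed, names(configs)[ci], r)
      cfgR <- cfg
      cfgR$seed <- repSeed
      class(cfgR) <- "pbiSimConfig"
      coh <- simulateCohort(cfgR)
      s <- subjectTable(coh)
      snp <- if (is.na(causalSnp(coh))) 1L else causalSnp(coh)
      g <- dosage(coh)[snp, ]
      res <- pbiTest(s$y, g, s$env, pedigree = s$pedigree_id,
                     schemes = schemes, B = B,
                     seed = deriveSeed(repSeed, "perm"))
      for (sc in schemes) {
        m <- paste0("pbi_", sc)
        hits[m] <- hits[m] + (res$p[[sc]] <= alpha)
      }
      if (withLrm) {
        p3 <- lrmInteractionTest(s$y, g, s$env)$p3
        hits["lrm"] <- hits["lrm"] + (!is.na(p3) && p3 <= alpha)
      }
    }
    rate <- hits / replicates
    out[[ci]] <- data.frame(config = names(configs)[ci], model = cfg$model,
                            method = methodsRun,
                            rejections = unname(hits),
                            replicates = replicates,
                            rate = unname(rate),
                            mcse = unname(sqrt(rate * (1 - rate) / replicates)),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Exact binomial band for a Monte-Carlo rejection rate
#'
#' The central probability interval of Binomial(R, alpha)/R: a simulated
#' rejection rate outside this band is evidence (at the stated coverage)
#' against the nominal level.
#'
#' @param replicates number of Monte-Carlo replicates R.
#' @param alpha nominal rejection probability.
#' @param coverage interval coverage (default 0.99).
#' @return named numeric `c(lower, upper)` on the rate scale.
#' @export
binomialBand <- function(replicates, alpha = 0.05, coverage = 0.99) {
  lo <- (1 - coverage) / 2
  c(lower = stats::qbinom(lo, replicates, alpha) / replicates,
    upper = stats::qbinom(1 - lo, replicates, alpha) / replicates)
}
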