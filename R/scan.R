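#' @include permutation.R lrm.R
NULL

#' Bonferroni-corrected per-test significance threshold
#'
#' Familywise error control by dividing the significance level by the
#' number of tests. The conventional genome-scan usage divides by the
#' number of SNPs (e.g. 0.05 over the 62,915 chromosome-3 SNPs of a dense
#' scan gives 7.9e-7); [runScan()] optionally applies the stricter
#' full-grid correction over SNP x environment x outcome combinations.
#'
#' @param nTests positive integer, number of tests.
#' @param alpha familywise level in (0, 1).
#' @return the per-test threshold `alpha / nTests`.
#' @examples
#' bonferroniThreshold(62915)  # 7.947e-07
#' @export
bonferroniThreshold <- function(nTests, alpha = 0.05) {
  if (length(nTests) != 1L || !is.finite(nTests) || nTests < 1 ||
      nTests != round(nTests)) {
    stop("'nTests' must be a positive integer")
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie in (0, 1)")
  }
  alpha / nTests
}

#' Scan SNP x environment x outcome combinations for GxE interaction
#'
#' Drives the genome scan: for every SNP in the genotype matrix, every
#' requested environment factor, and every requested outcome, computes the
#' partition interaction scores, the permutation p-value under each
#' requested scheme, and the linear-model comparator p-value — all on the
#' identical complete-case subject set per triple. Subjects are aligned
#' between genotypes and the subject table by id, never by position.
#'
#' Per-triple guards (the statistic is defined but a permutation p-value
#' would be meaningless): fewer than `minN` complete cases, or a factor
#' with a single observed level on both margins, produce a flagged row
#' with `NA` p-values; a monomorphic SNP likewise. SNPs with minor-allele
#' count below 5 are still tested but flagged `"low_mac"`. The flag column
#' is `"ok"` for clean rows and a comma-separated list of reasons
#' otherwise.
#'
#' The per-test permutation stream is derived deterministically from
#' `(seed, SNP index, environment, scheme)`, so output is reproducible
#' regardless of evaluation order or parallel chunking.
#'
#' @param genotypes a [GenotypeMatrix-class] (minor-allele dosages).
#' @param subjects per-subject data.frame containing `subject_id`,
#'   `pedigree_id`, the environment label columns and the outcome columns
#'   (e.g. the output of [buildSubjectTable()] or [subjectTable()]).
#' @param envs character vector of environment column names in `subjects`.
#' @param outcomes character vector of outcome column names in `subjects`.
#' @param schemes permutation schemes to run (subset of global/local/
#'   residual); `character(0)` skips permutation p-values (scores only).
#' @param B permutations per scheme per test.
#' @param seed integer base seed.
#' @param alpha familywise level for the reported threshold attribute.
#' @param correction `"per_snp"` (divide alpha by #SNPs, the scan
#'   convention) or `"full_grid"` (divide by #SNPs x #envs x #outcomes).
#' @param minN minimum complete-case count for a testable triple.
#' @param adaptive early stopping for permutations, see [pbiTest()].
#' @param lrmEnv how the comparator codes E: `"discrete"` uses the same
#'   0/1/2 label the partition test sees (default); `"raw"` looks up the
#'   raw covariate column named by `rawCols[env]`.
#' @param rawCols named character vector mapping environment label columns
#'   to raw covariate columns (only used when `lrmEnv = "raw"`).
#' @return data.frame with one row per (SNP, env, outcome): `snp_id`,
#'   `chrom`, `pos`, `env`, `outcome`, `n_used`, `I_T`, `I_G`, `I_E`,
#'   `I_GxE`, one `p_<scheme>` column per requested scheme, `p_lrm`,
#'   `flag`; the per-test Bonferroni threshold is attached as attribute
#'   `"threshold"`.
#' @examples
#' coh <- simulateCohort(simConfig(nPedigrees = 4, pedigreeSize = 10,
#'                                 nSnps = 2, seed = 5))
#' runScan(genotypes(coh), subjectTable(coh), "env", "y",
#'         schemes = "global", B = 99, seed = 5)
#' @export
runScan <- function(genotypes, subjects, envs, outcomes,
                    schemes = c("global", "local", "residual"),
                    B = 999L, seed = 1L, alpha = 0.05,
                    correction = c("per_snp", "full_grid"),
                    minN = 10L, adaptive = FALSE,
                    lrmEnv = c("discrete", "raw"), rawCols = NULL) {
  correction <- match.arg(correction)
  lrmEnv <- match.arg(lrmEnv)
  if (length(schemes)) {
    schemes <- match.arg(schemes, .schemes, several.ok = TRUE)
  }
  stopifnot(methods::is(genotypes, "GenotypeMatrix"))
  need <- c("subject_id", "pedigree_id", envs, outcomes)
  miss <- setdiff(need, names(subjects))
  if (length(miss)) stop("subject table lacks columns: ", paste(miss, collapse = ", "))
  if (lrmEnv == "raw") {
    if (is.null(rawCols) || !all(envs %in% names(rawCols))) {
      stop("lrmEnv = 'raw' needs 'rawCols' naming a raw column for every env")
    }
    miss <- setdiff(unname(rawCols[envs]), names(subjects))
    if (length(miss)) stop("subject table lacks raw columns: ", paste(miss, collapse = ", "))
  }

  gm <- dosage(genotypes)
  sid <- as.character(subjects$subject_id)
  if (anyDuplicated(sid)) stop("duplicate subject ids in subject table")
  common <- intersect(colnames(gm), sid)
  orphans <- c(setdiff(colnames(gm), sid), setdiff(sid, colnames(gm)))
  if (length(common) == 0L) {
    stop("no subject ids shared between genotypes and subject table; ",
         "offenders: ", paste(utils::head(orphans, 10), collapse = ", "))
  }
  if (length(orphans)) {
    warning(length(orphans), " subject id(s) present on one side only were dropped: ",
            paste(utils::head(orphans, 5), collapse = ", "),
            if (length(orphans) > 5) ", ..." else "")
  }
  gm <- gm[, common, drop = FALSE]
  subjects <- subjects[match(common, sid), , drop = FALSE]
  ped <- subjects$pedigree_id
  info <- snpInfo(genotypes)

  nT <- switch(correction,
               per_snp = nrow(gm),
               full_grid = nrow(gm) * length(envs) * length(outcomes))
  thr <- bonferroniThreshold(max(1L, nT), alpha)

  rows <- vector("list", nrow(gm) * length(envs) * length(outcomes))
  k <- 0L
  for (s in seq_len(nrow(gm))) {
    gRow <- gm[s, ]
    for (env in envs) {
      eCol <- subjects[[env]]
      for (outc in outcomes) {
        k <- k + 1L
        yCol <- subjects[[outc]]
        rows[[k]] <- .scanOne(y = yCol, g = gRow, e = eCol, ped = ped,
                              snp = info[s, ], snpIdx = s, env = env,
                              outcome = outc, schemes = schemes, B = B,
                              seed = seed, minN = minN, adaptive = adaptive,
                              eRaw = if (lrmEnv == "raw")
                                subjects[[rawCols[[env]]]] else NULL)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

.scanOne <- function(y, g, e, ped, snp, snpIdx, env, outcome,
                     schemes, B, seed, minN, adaptive, eRaw = NULL) {
  base <- data.frame(snp_id = snp$snp_id, chrom = snp$chrom, pos = snp$pos,
                     env = env, outcome = outcome, n_used = 0L,
                     I_T = NA_real_, I_G = NA_real_, I_E = NA_real_,
                     I_GxE = NA_real_, stringsAsFactors = FALSE)
  for (sc in schemes) base[[paste0("p_", sc)]] <- NA_real_
  base$p_lrm <- NA_real_
  base$flag <- "ok"

  ok <- !(is.na(y) | is.na(g) | is.na(e) | is.na(ped))
  n <- sum(ok)
  base$n_used <- n
  flags <- character(0)
  if (n < minN) flags <- c(flags, "low_n")
  yv <- y[ok]; gv <- g[ok]; ev <- e[ok]; pv <- ped[ok]
  if (n >= 2L) {
    # with a single-level margin I_GxE is identically 0 on every permutation
    if (length(unique(gv)) < 2L || length(unique(ev)) < 2L) {
      flags <- c(flags, "degenerate_margins")
    }
    if (stats::var(yv) == 0) flags <- c(flags, "constant_y")
  } else {
    flags <- c(flags, "degenerate_margins")
  }
  if (length(flags)) {
    base$flag <- paste(flags, collapse = ",")
    return(base)
  }
  mac <- min(sum(gv), sum(2L - gv))
  if (mac < 5L) flags <- c(flags, "low_mac")

  if (length(schemes)) {
    res <- pbiTest(yv, gv, ev, pedigree = pv, schemes = schemes, B = B,
                   seed = deriveSeed(seed, snpIdx, env, outcome),
                   adaptive = adaptive)
    sco <- res$scores
    for (sc in schemes) base[[paste0("p_", sc)]] <- unname(res$p[sc])
  } else {
    sco <- gxeScores(yv, gv, ev)
  }
  base$I_T <- scoreTotal(sco); base$I_G <- scoreG(sco)
  base$I_E <- scoreE(sco); base$I_GxE <- scoreGxE(sco)

  lrm <- lrmInteractionTest(yv, gv, if (is.null(eRaw)) ev else eRaw[ok])
  base$p_lrm <- lrm$p3
  if (lrm$flag != "ok") flags <- c(flags, paste0("lrm_", lrm$flag))
  base$flag <- if (length(flags)) paste(flags, collapse = ",") else "ok"
  base
}
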