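#' @include partition-score.R
NULL

#' Decompose phenotypes into pedigree means and residuals
#'
#' For subject j in pedigree i with phenotype \eqn{y_{ij}}, computes the
#' pedigree mean \eqn{\bar y_{i\cdot}} and the residual
#' \eqn{e_{ij} = y_{ij} - \bar y_{i\cdot}}. Residuals sum to zero within
#' every pedigree by construction; this is the decomposition the residual
#' permutation scheme reattaches after shuffling.
#'
#' @param y numeric phenotype vector.
#' @param pedigree parallel vector of pedigree ids.
#' @return list with `fitted` (per-subject pedigree mean), `residuals`
#'   (per-subject residual), and `pedMeans` (named per-pedigree means).
#' @export
pedigreeResiduals <- function(y, pedigree) {
  if (length(y) != length(pedigree)) stop("'y' and 'pedigree' must align")
  if (anyNA(y) || anyNA(pedigree)) stop("missing values not allowed here")
  f <- factor(pedigree)
  m <- rowsum(y, f)[, 1L] / tabulate(f, nlevels(f))
  fitted <- m[as.integer(f)]
  list(fitted = unname(fitted), residuals = unname(y - fitted),
       pedMeans = stats::setNames(m, levels(f)))
}

#' Permute a phenotype vector under the three family-aware schemes
#'
#' Three ways of generating a null phenotype vector for family data:
#' \describe{
#'   \item{global}{a uniformly random rearrangement over all subjects;
#'     assumes full exchangeability and ignores pedigree structure.}
#'   \item{local}{values shuffled within each pedigree only; per-pedigree
#'     value multisets (hence per-pedigree means) are preserved exactly.}
#'   \item{residual}{pedigree-mean-centred residuals are shuffled over all
#'     subjects and reattached to the pedigree means:
#'     \eqn{y^*_{ij} = \bar y_{i\cdot} + e^*_{ij}}. The grand sum is
#'     preserved exactly (residuals sum to zero overall); assumes residuals
#'     share one distribution across pedigrees.}
#' }
#' Local and residual permutation respect the decomposition
#' \eqn{y_{ij} = \bar y_{i\cdot} + \epsilon_{ij}} and so remain valid when
#' phenotypes are correlated within pedigrees. Only the phenotype is ever
#' permuted; genotype and environment labels stay fixed.
#'
#' These functions draw from R's current RNG stream; seed with
#' [set.seed()] for reproducibility.
#'
#' @param y numeric phenotype vector.
#' @param pedigree pedigree ids parallel to `y` (required for local and
#'   residual schemes).
#' @return a permuted phenotype vector of the same length.
#' @examples
#' set.seed(7)
#' permuteLocal(c(1, 2, 3, 4), c("f1", "f1", "f2", "f2"))
#' @name permute-schemes
NULL

#' @rdname permute-schemes
#' @export
permuteGlobal <- function(y) {
  if (length(y) == 0L) stop("empty phenotype vector")
  y[sample.int(length(y))]
}

#' @rdname permute-schemes
#' @export
permuteLocal <- function(y, pedigree) {
  if (length(y) != length(pedigree)) stop("'y' and 'pedigree' must align")
  idx <- seq_along(y)
  for (grp in split(idx, pedigree)) {
    if (length(grp) > 1L) idx[grp] <- grp[sample.int(length(grp))]
  }
  y[idx]
}

#' @rdname permute-schemes
#' @export
permuteResidual <- function(y, pedigree) {
  d <- pedigreeResiduals(y, pedigree)
  d$fitted + d$residuals[sample.int(length(y))]
}

.schemes <- c("global", "local", "residual")

# deterministic 31-bit stream seed from a base seed plus context tokens,
# so every (SNP, environment, scheme) test has its own reproducible stream
# regardless of evaluation order
deriveSeed <- function(seed, ...) {
  M <- 2147483647
  h <- as.numeric(seed) %% M
  for (tok in list(...)) {
    for (cp in utf8ToInt(paste0(as.character(tok), "|"))) {
      h <- (h * 31 + cp) %% M
    }
  }
  as.integer(max(1, h))
}

# n x B matrix of permutation indices for global/local, applied to y for
# residual; one column per permutation draw
.permIndexMatrix <- function(n, B, scheme, pedF) {
  if (scheme == "local") {
    grps <- split(seq_len(n), pedF)
    out <- matrix(seq_len(n), n, B)
    for (grp in grps) {
      k <- length(grp)
      if (k > 1L) {
        out[grp, ] <- vapply(seq_len(B), function(b) grp[sample.int(k)],
                             integer(k))
      }
    }
    out
  } else {
    vapply(seq_len(B), function(b) sample.int(n), integer(n))
  }
}

# Vectorized null distribution of (IT, IG, IE, IGxE) under one scheme.
# Y columns are permuted phenotype vectors; factors and cell counts fixed.
.statColumns <- function(Y, gf, ef, jf, varUnbiased = TRUE) {
  n <- nrow(Y)
  m <- colMeans(Y)
  ss <- colSums(Y * Y) - n * m * m
  s2 <- ss / if (varUnbiased) (n - 1) else n
  bad <- s2 <= 0
  oneFactor <- function(f) {
    f <- droplevels(f)
    cnt <- tabulate(f, nbins = nlevels(f))
    S <- rowsum(Y, f)                     # observed-level x B group sums
    S <- S[match(levels(f), rownames(S)), , drop = FALSE]
    D <- sweep(S / cnt, 2L, m)            # level means minus grand mean
    colSums(cnt^2 * D * D) / (n * s2)
  }
  IT <- oneFactor(jf)
  IG <- oneFactor(gf)
  IE <- oneFactor(ef)
  IGxE <- IT - pmax(IG, IE)
  if (any(bad)) IT[bad] <- IG[bad] <- IE[bad] <- IGxE[bad] <- Inf
  list(IT = IT, IG = IG, IE = IE, IGxE = IGxE, degenerate = bad)
}

# run expr with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Permutation p-value for an arbitrary statistic
#'
#' Generic permutation engine: permutes the phenotype under the requested
#' scheme, recomputes a user-supplied statistic on each permuted vector
#' (genotype and environment labels held fixed inside `statFn`), and
#' returns the add-one p-value
#' \deqn{p = \frac{1 + \#\{b : T_b \ge T_{obs}\}}{1 + B},}
#' which is never zero and never anti-conservative; ties count as
#' exceedances. If `statFn` fails on a permuted vector (e.g. a degenerate
#' variance) the draw is retried once and otherwise counted as an
#' exceedance, with a warning.
#'
#' @param observed the statistic on the observed phenotype vector.
#' @param statFn function of one argument (a phenotype vector) returning a
#'   single number; must be deterministic.
#' @param y observed phenotype vector.
#' @param pedigree pedigree ids (needed for local/residual schemes).
#' @param scheme `"global"`, `"local"` or `"residual"`.
#' @param B number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @return p-value in `[1/(B+1), 1]`.
#' @seealso [pbiTest()] for the fast path specialised to the partition
#'   interaction score.
#' @export
permutationPValue <- function(observed, statFn, y, pedigree = NULL,
                              scheme = c("global", "local", "residual"),
                              B = 999L, seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(B >= 1L, is.finite(observed))
  if (scheme != "global" && is.null(pedigree)) {
    stop("'pedigree' is required for the ", scheme, " scheme")
  }
  draw <- switch(scheme,
    global = function() permuteGlobal(y),
    local = function() permuteLocal(y, pedigree),
    residual = function() permuteResidual(y, pedigree)
  )
  run <- function() {
    r <- 0L
    for (b in seq_len(B)) {
      stat <- tryCatch(statFn(draw()), error = function(cnd) {
        tryCatch(statFn(draw()), error = function(cnd2) {
          warning("statistic failed twice on permuted data; ",
                  "draw counted as an exceedance: ", conditionMessage(cnd2))
          Inf
        })
      })
      if (stat >= observed) r <- r + 1L
    }
    (1 + r) / (1 + B)
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

#' Partition-based interaction test with permutation p-values
#'
#' The single-test front end: computes the interaction score
#' \eqn{I_{G\times E}} for one SNP-environment-phenotype triple and its
#' permutation p-value under each requested scheme, using a vectorized
#' engine (group sums over permutation blocks) that matches
#' [permutationPValue()] draw-for-draw in distribution. The per-scheme
#' permutation stream is derived deterministically from `seed` and the
#' scheme name, so results are reproducible and scheme-order independent.
#'
#' With `adaptive = TRUE` the engine stops early once 50 permuted
#' statistics have reached the observed value (the p-value is then
#' estimated from the draws made); this bounds desk-scale scan time but is
#' off by default.
#'
#' @param y,g,e phenotype, genotype, and environment vectors (missing
#'   values dropped jointly).
#' @param pedigree pedigree ids (required for local/residual schemes).
#' @param schemes character subset of `c("global", "local", "residual")`.
#' @param B permutations per scheme.
#' @param seed integer base seed.
#' @param adaptive stop a scheme early after 50 exceedances.
#' @param chunk permutations evaluated per vectorized block.
#' @param varMethod variance convention, see [partitionScore()].
#' @return list with `scores` (a [GxEScores-class]) and `p` (named numeric
#'   vector of p-values per requested scheme).
#' @examples
#' set.seed(2)
#' g <- sample(0:2, 60, TRUE); e <- sample(0:2, 60, TRUE)
#' y <- rnorm(60) + (g == 1) * (e == 1)
#' pbiTest(y, g, e, schemes = "global", B = 199, seed = 11)$p
#' @export
pbiTest <- function(y, g, e, pedigree = NULL,
                    schemes = c("global", "local", "residual"),
                    B = 999L, seed = 1L, adaptive = FALSE, chunk = 2000L,
                    varMethod = c("unbiased", "ml")) {
  varMethod <- match.arg(varMethod)
  schemes <- match.arg(schemes, .schemes, several.ok = TRUE)
  stopifnot(B >= 1L)
  ok <- !(is.na(y) | is.na(g) | is.na(e))
  if (!is.null(pedigree)) {
    if (length(pedigree) != length(y)) stop("'pedigree' must align with 'y'")
    ok <- ok & !is.na(pedigree)
    pedigree <- pedigree[ok]
  } else if (any(schemes != "global")) {
    stop("'pedigree' is required for local/residual schemes")
  }
  obs <- gxeScores(y[ok], g[ok], e[ok], varMethod = varMethod)
  y <- y[ok]
  n <- length(y)
  gf <- factor(g[ok]); ef <- factor(e[ok])
  jf <- interaction(gf, ef, drop = FALSE, lex.order = TRUE)
  pedF <- if (!is.null(pedigree)) factor(pedigree) else NULL
  dec <- if (!is.null(pedF)) pedigreeResiduals(y, pedF) else NULL
  unb <- varMethod == "unbiased"
  target <- obs@IGxE
  pvals <- stats::setNames(numeric(length(schemes)), schemes)
  for (sc in schemes) {
    pvals[sc] <- withSeed(deriveSeed(seed, sc), {
      r <- 0L; done <- 0L; degen <- FALSE
      while (done < B) {
        b <- min(chunk, B - done)
        Y <- if (sc == "residual") {
          P <- .permIndexMatrix(n, b, "global", pedF)
          dec$fitted + matrix(dec$residuals[P], n, b)
        } else {
          P <- .permIndexMatrix(n, b, sc, pedF)
          matrix(y[P], n, b)
        }
        st <- .statColumns(Y, gf, ef, jf, varUnbiased = unb)
        if (any(st$degenerate)) degen <- TRUE
        r <- r + sum(st$IGxE >= target)
        done <- done + b
        if (adaptive && r >= 50L) break
      }
      if (degen) warning("degenerate permuted phenotype counted as exceedance")
      (1 + r) / (1 + done)
    })
  }
  list(scores = obs, p = pvals)
}
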