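#' @include AllClasses.R
NULL

#' Partition-based association score
#'
#' Scores the association between a quantitative phenotype and a categorical
#' partition of the subjects. For a partition with levels \eqn{i} of size
#' \eqn{n_i}, level means \eqn{\bar Y_i}, grand mean \eqn{\bar Y} and
#' phenotype variance \eqn{s_y^2}, the score is
#' \deqn{I = \sum_i \frac{n_i}{n} \cdot \frac{(\bar Y_i - \bar Y)^2}{s_y^2 / n_i}}
#' summed over the levels actually observed (empty levels contribute
#' nothing). The score is nonnegative, zero when every level mean equals the
#' grand mean, and invariant under affine transformations of the phenotype
#' and under renaming of the partition levels. When every subject is its own
#' level and the phenotype values are distinct, the score equals
#' \eqn{(n-1)/n} under the unbiased variance convention.
#'
#' The score has no analytic p-value here; significance is assessed by
#' permutation (see [pbiTest()]).
#'
#' @param y numeric vector of phenotype values.
#' @param labels parallel vector (any atomic type or factor) of partition
#'   assignments; `NA` labels are not allowed (filter first).
#' @param varMethod variance convention for \eqn{s_y^2}: `"unbiased"`
#'   (denominator n-1, the default) or `"ml"` (denominator n). The choice
#'   rescales every score by the constant factor (n-1)/n and therefore
#'   cancels in permutation p-values.
#' @return a single nonnegative number.
#' @examples
#' partitionScore(c(1, 2, 3, 4), c("A", "A", "B", "B"))  # 1.2
#' @export
partitionScore <- function(y, labels, varMethod = c("unbiased", "ml")) {
  varMethod <- match.arg(varMethod)
  if (length(y) != length(labels)) {
    stop("'y' and 'labels' must have the same length")
  }
  if (anyNA(y) || anyNA(labels)) {
    stop("missing values in 'y' or 'labels'; apply complete-case filtering first")
  }
  n <- length(y)
  if (n < 2L) stop("need at least 2 subjects to score a partition")
  f <- factor(labels)
  ybar <- mean(y)
  s2 <- sum((y - ybar)^2) / if (varMethod == "unbiased") (n - 1) else n
  if (s2 <= 0) {
    stop("degenerate input: phenotype is constant (zero variance)")
  }
  .scoreFromFactor(y, f, ybar, s2, n)
}

# core evaluation: sum_i n_i^2 (ybar_i - ybar)^2 / (n s2), empty levels skipped
.scoreFromFactor <- function(y, f, ybar, s2, n) {
  f <- droplevels(f)
  cnt <- tabulate(f, nbins = nlevels(f))
  sums <- rowsum(y, f)
  sums <- sums[match(levels(f), rownames(sums)), 1L]
  means <- sums / cnt
  sum(cnt^2 * (means - ybar)^2) / (n * s2)
}

#' Joint, marginal, and interaction scores for a genotype-environment pair
#'
#' Computes the partition-based decomposition for one SNP, one environmental
#' factor, and one phenotype. The total score \eqn{I_T} scores the joint
#' partition formed by crossing the observed genotype levels with the
#' observed environment levels (up to 3 x 3 = 9 cells); \eqn{I_G} and
#' \eqn{I_E} score each margin alone; the interaction score is
#' \deqn{I_{G \times E} = I_T - \max(I_G, I_E).}
#' A large positive \eqn{I_{G\times E}} indicates that the joint partition
#' explains phenotype variation well beyond either factor alone, i.e. an
#' interaction of any functional form — including non-monotone "crossing"
#' patterns invisible to a linear interaction term. The value may be
#' negative and is reported as-is.
#'
#' Subjects missing any of the three values are dropped (complete-case per
#' triple); levels with no subjects contribute nothing, so binary factors
#' and SNPs with fewer than three observed genotype classes are handled
#' uniformly.
#'
#' @param y numeric phenotype vector.
#' @param g genotype levels per subject (typically minor-allele dosage 0/1/2).
#' @param e environment levels per subject (typically discretized 0/1/2).
#' @param varMethod variance convention, see [partitionScore()].
#' @return a [GxEScores-class] object.
#' @examples
#' set.seed(1)
#' g <- sample(0:2, 40, TRUE); e <- sample(0:2, 40, TRUE)
#' gxeScores(rnorm(40) + g * (e == 1), g, e)
#' @export
gxeScores <- function(y, g, e, varMethod = c("unbiased", "ml")) {
  varMethod <- match.arg(varMethod)
  if (length(y) != length(g) || length(y) != length(e)) {
    stop("'y', 'g' and 'e' must have the same length")
  }
  ok <- !(is.na(y) | is.na(g) | is.na(e))
  y <- y[ok]; g <- g[ok]; e <- e[ok]
  n <- length(y)
  if (n < 2L) stop("fewer than 2 complete cases")
  gf <- factor(g)
  ef <- factor(e)
  ybar <- mean(y)
  s2 <- sum((y - ybar)^2) / if (varMethod == "unbiased") (n - 1) else n
  tab <- table(g = gf, e = ef)
  if (s2 <= 0) {
    if (sum(tab > 0L) == 1L) {
      # all subjects in one joint cell: every score is 0 by definition
      return(methods::new("GxEScores", IT = 0, IG = 0, IE = 0, IGxE = 0,
                          cellCounts = tab, nUsed = n))
    }
    stop("degenerate input: phenotype is constant (zero variance)")
  }
  jf <- interaction(gf, ef, drop = FALSE, lex.order = TRUE)
  IT <- .scoreFromFactor(y, jf, ybar, s2, n)
  IG <- .scoreFromFactor(y, gf, ybar, s2, n)
  IE <- .scoreFromFactor(y, ef, ybar, s2, n)
  methods::new("GxEScores",
               IT = IT, IG = IG, IE = IE, IGxE = IT - max(IG, IE),
               cellCounts = tab, nUsed = n)
}
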