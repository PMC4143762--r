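#' @include partition-score.R
NULL

#' Linear regression model comparator for GxE interaction
#'
#' Ordinary least-squares fit of the classical interaction model
#' \deqn{y = \beta_0 + \beta_1 G + \beta_2 E + \beta_3 G \times E + \epsilon}
#' with genotype dosage and environment level entered as numeric scores.
#' The interaction is tested by the two-sided t-test on \eqn{\beta_3}: if
#' \eqn{\beta_3 = 0}, the conditional SNP effect is constant across
#' environment levels. The fit assumes a *linear* interaction; non-monotone
#' (crossing) interaction patterns project onto \eqn{\beta_3 \approx 0} and
#' are invisible to this test — the contrast the partition score is built
#' to expose. Plain OLS is used: family structure is not modelled.
#'
#' Subjects missing any of the three values are dropped, so the comparator
#' uses the identical complete-case set as [gxeScores()] for the same
#' triple.
#'
#' @param y numeric phenotype vector.
#' @param g genotype dosage (0/1/2) treated as numeric.
#' @param e environment level treated as a numeric score.
#' @return list with `beta` (named coefficients b0..b3), `se3`, `p3`
#'   (two-sided p-value for the interaction coefficient), `nUsed`, and
#'   `flag` (`"ok"` or `"rank_deficient"`; in the latter case `p3` is NA).
#' @examples
#' set.seed(3)
#' g <- sample(0:2, 50, TRUE); e <- sample(0:2, 50, TRUE)
#' lrmInteractionTest(1 + 0.5 * g * e + rnorm(50), g, e)$p3
#' @export
lrmInteractionTest <- function(y, g, e) {
  ok <- !(is.na(y) | is.na(g) | is.na(e))
  y <- y[ok]; g <- as.numeric(g[ok]); e <- as.numeric(e[ok])
  n <- length(y)
  empty <- list(beta = stats::setNames(rep(NA_real_, 4),
                                       c("b0", "b1", "b2", "b3")),
                se3 = NA_real_, p3 = NA_real_, nUsed = n,
                flag = "rank_deficient")
  if (n < 5L) {
    empty$flag <- "low_n"
    return(empty)
  }
  X <- cbind(1, g, e, g * e)
  if (qr(X)$rank < 4L || n <= 4L) return(empty)
  fit <- stats::lm(y ~ g + e + g:e)
  cf <- stats::coef(summary(fit))
  list(beta = stats::setNames(unname(cf[, 1L]), c("b0", "b1", "b2", "b3")),
       se3 = cf[4L, 2L],
       p3 = cf[4L, 4L],
       nUsed = n,
       flag = "ok")
}
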