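# Independent oracles, deliberately naive: explicit loops, no shared code
# with the package's implementation.

# double-loop evaluation of the partition score
naivePartitionScore <- function(y, labels, unbiased = TRUE) {
  n <- length(y)
  ybar <- 0
  for (v in y) ybar <- ybar + v
  ybar <- ybar / n
  ss <- 0
  for (v in y) ss <- ss + (v - ybar)^2
  s2 <- ss / if (unbiased) (n - 1) else n
  total <- 0
  for (lev in unique(labels)) {
    ni <- 0
    si <- 0
    for (j in seq_len(n)) {
      if (labels[j] == lev) {
        ni <- ni + 1
        si <- si + y[j]
      }
    }
    if (ni >= 1) {
      mi <- si / ni
      total <- total + (ni / n) * (mi - ybar)^2 / (s2 / ni)
    }
  }
  total
}

# textbook OLS of y on [1, g, e, g*e] via normal equations; two-sided t-test
# for the interaction coefficient
naiveOlsInteraction <- function(y, g, e) {
  X <- cbind(1, g, e, g * e)
  n <- nrow(X)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- n - 4
  sigma2 <- sum(res^2) / df
  covb <- sigma2 * solve(XtX)
  se3 <- sqrt(covb[4, 4])
  t3 <- beta[4] / se3
  list(beta = as.numeric(beta), se3 = se3,
       p3 = 2 * pt(abs(t3), df, lower.tail = FALSE))
}

# small random scored instance for property loops
randomInstance <- function(n = NULL, nLevels = NULL) {
  if (is.null(n)) n <- sample(4:30, 1)
  if (is.null(nLevels)) nLevels <- sample(2:5, 1)
  list(y = rnorm(n), labels = sample(letters[seq_len(nLevels)], n, replace = TRUE))
}
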