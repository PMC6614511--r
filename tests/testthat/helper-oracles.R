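# Independent brute-force oracles used to cross-check the implementation.

# Simes combination by explicit minimization over all order statistics
simesBrute <- function(p) {
  m <- length(p)
  sp <- sort(p)
  best <- Inf
  for (i in seq_len(m)) best <- min(best, m * sp[i] / i)
  min(1, best)
}

# BH rejection set from the explicit step-up definition:
# largest i with p(i) <= i q / m, reject everything at or below it
bhRejectBrute <- function(p, q) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  k <- 0
  for (i in seq_len(m)) if (sp[i] <= i * q / m) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# classical Spearman formula, valid for tie-free data
spearmanClassical <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# externally studentized residuals by literal leave-one-out refitting
looStudentized <- function(y, covDf) {
  X <- cbind(1, as.matrix(covDf))
  n <- length(y)
  t <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    fit <- lm.fit(Xi, y[-i])
    df <- nrow(Xi) - ncol(Xi)
    s2 <- sum(fit$residuals^2) / df
    xtxinv <- solve(crossprod(Xi))
    pred <- sum(X[i, ] * fit$coefficients)
    t[i] <- (y[i] - pred) /
      sqrt(s2 * (1 + drop(t(X[i, ]) %*% xtxinv %*% X[i, ])))
  }
  t
}

# partial Spearman via a separate construction (lm residuals of ranks)
partialSpearmanOracle <- function(x, y, covDf) {
  rx <- resid(lm(rank(x) ~ ., data = covDf))
  ry <- resid(lm(rank(y) ~ ., data = covDf))
  cor(rx, ry)
}

makeCovariates <- function(n) {
  data.frame(age = runif(n, 30, 80), gender = rbinom(n, 1, 0.5))
}

sampleSkewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}
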