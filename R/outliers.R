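#' @include utils.R
NULL

#' Detect outliers by the Bonferroni studentized-residual rule
#'
#' Regresses the variable on the covariates (ordinary least squares over
#' complete cases), computes externally studentized residuals (leave-one-out
#' variance), converts each to a two-sided t-tail p-value on n - k - 2
#' degrees of freedom (k covariates), Bonferroni-corrects by the number of
#' cases used, and flags cells whose corrected p-value is strictly smaller
#' than `cutoffNumerator / n`. Detection is a single pass; flagged cells are
#' intended to be set missing for that variable only (as done by
#' [preprocessCohort()]), never to drop whole subjects.
#'
#' @param x Numeric vector (one variable across subjects).
#' @param covariates `data.frame` of numeric covariates (typically `age` and
#'   `gender`), one row per subject; a `subject_id` column is carried through
#'   to the report if present.
#' @param cutoffNumerator Numerator c of the cutoff c/n (default 4).
#' @return A `data.frame` with one row per flagged cell (`subject`,
#'   `subject_id` when available, `studentized_residual`, `bonferroni_p`),
#'   with attributes `cutoff_used` (= c/n) and `n_used`.
#' @examples
#' cov <- data.frame(age = seq(30, 79, length.out = 50),
#'                   gender = rep(0:1, 25))
#' y <- 0.05 * cov$age + rnorm(50, sd = 0.5)
#' y[7] <- y[7] + 8   # gross error
#' detectOutliers(y, cov)
#' @export
detectOutliers <- function(x, covariates, cutoffNumerator = 4) {
  covariates <- as.data.frame(covariates)
  ids <- if ("subject_id" %in% names(covariates)) {
    as.character(covariates$subject_id)
  } else {
    as.character(seq_along(x))
  }
  cv <- covariates[, setdiff(names(covariates), "subject_id"), drop = FALSE]
  k <- ncol(cv)
  ok <- stats::complete.cases(x, cv)
  n <- sum(ok)
  if (n < k + 3) {
    stop("input error: need at least ", k + 3, " complete cases, got ", n)
  }
  X <- cbind(1, as.matrix(cv[ok, , drop = FALSE]))
  if (qr(X)$rank < ncol(X)) {
    stop("regression-rank error: covariates are collinear or constant")
  }
  df <- n - k - 2 # residual df of the leave-one-out fit
  if (df < 1) stop("input error: not enough cases for studentized residuals")
  dat <- data.frame(.y = x[ok], cv[ok, , drop = FALSE])
  fit <- stats::lm(.y ~ ., data = dat)
  t <- stats::rstudent(fit)
  # NaN means the leave-one-out variance estimate collapsed to zero (or went
  # negative by rounding): a nonzero residual is then infinitely outlying,
  # a zero residual is not outlying at all
  nan <- is.nan(t)
  if (any(nan)) {
    e <- stats::residuals(fit)
    tol <- sqrt(.Machine$double.eps) * max(abs(dat$.y - mean(dat$.y)), 1)
    t[nan] <- ifelse(abs(e[nan]) > tol, Inf, 0)
  }
  p <- 2 * stats::pt(-abs(t), df = df)
  p[is.infinite(t)] <- 0
  bonf <- pmin(1, n * p)
  cutoff <- cutoffNumerator / n
  flag <- bonf < cutoff
  idx <- which(ok)[flag]
  out <- data.frame(subject = idx,
                    subject_id = ids[idx],
                    studentized_residual = t[flag],
                    bonferroni_p = bonf[flag],
                    stringsAsFactors = FALSE)
  out <- out[order(out$subject), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff_used") <- cutoff
  attr(out, "n_used") <- n
  out
}
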