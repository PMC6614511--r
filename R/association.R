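#' @include AllClasses.R
NULL

#' Partial Spearman correlation adjusted for covariates
#'
#' Ranks `x` and `y` (average ranks for ties) over their pairwise-complete
#' cases, residualizes both rank vectors on an intercept plus the covariates
#' by least squares, and correlates the residuals. The p-value comes from the
#' t statistic `rho * sqrt((n - k - 2) / (1 - rho^2))` on `n - k - 2` degrees
#' of freedom (two-sided), with k the number of covariates. With no
#' covariates this reduces exactly to the ordinary Spearman rank correlation.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates `data.frame` of numeric covariates (or `NULL` for the
#'   unadjusted Spearman correlation); a `subject_id` column is ignored.
#' @return A list with `rho`, `p_value`, `n_used` and `df`.
#' @examples
#' age <- runif(80, 30, 80)
#' x <- age / 10 + rnorm(80)
#' y <- age / 10 + rnorm(80)
#' partialSpearman(x, y, data.frame(age = age))$rho # near 0
#' partialSpearman(x, y, NULL)$rho                  # confounded, > 0
#' @export
partialSpearman <- function(x, y, covariates = NULL) {
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    covariates <- covariates[, setdiff(names(covariates), "subject_id"),
                             drop = FALSE]
    if (!ncol(covariates)) covariates <- NULL
  }
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  ok <- if (is.null(covariates)) {
    stats::complete.cases(x, y)
  } else {
    stats::complete.cases(x, y, covariates)
  }
  n <- sum(ok)
  if (n < k + 3) {
    stop("input error: need at least ", k + 3,
         " pairwise-complete cases, got ", n)
  }
  rx <- rank(x[ok])
  ry <- rank(y[ok])
  Z <- if (is.null(covariates)) {
    matrix(1, n, 1)
  } else {
    cbind(1, as.matrix(covariates[ok, , drop = FALSE]))
  }
  qz <- qr(Z)
  ex <- qr.resid(qz, rx)
  ey <- qr.resid(qz, ry)
  # ranks are O(n), so residual sds far below 1 can only be rounding noise
  # from projecting a constant (or covariate-determined) rank vector
  if (stats::sd(ex) < 1e-8 * n || stats::sd(ey) < 1e-8 * n) {
    stop("degenerate-correlation error: zero residual variance after ",
         "covariate adjustment")
  }
  rho <- stats::cor(ex, ey)
  rho <- max(-1, min(1, rho))
  df <- n - k - 2
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  list(rho = rho, p_value = p, n_used = n, df = df)
}

#' Cross-block matrix of covariate-adjusted Spearman correlations
#'
#' One [partialSpearman()] call per (cognitive variable, motor variable)
#' pair, each over that pair's pairwise-complete cases, adjusted for the
#' cohort's covariates (age and gender). Pairs with too few complete cases
#' or degenerate residual variance are marked untestable and propagated with
#' `rho = NA`, `p = 1` (with a warning), which keeps hypothesis-family sizes
#' constant and is conservative.
#'
#' @param x A (typically preprocessed) \linkS4class{CohortExperiment} with
#'   both blocks nonempty.
#' @return A `data.frame` with one row per pair: `cognitive_id`,
#'   `cognitive_domain`, `motor_id`, `motor_domain`, `rho`, `p`, `n_used`,
#'   `untestable`.
#' @examples
#' ce <- simulateCohort(scenarioConfig("signal", nSubjects = 80))
#' head(associationMatrix(ce))
#' @export
associationMatrix <- function(x) {
  meta <- variableMeta(x)
  vals <- cohortValues(x)
  cov <- covariateData(x)
  cog <- meta[meta$block == "cognitive", , drop = FALSE]
  mot <- meta[meta$block == "motor", , drop = FALSE]
  if (!nrow(cog) || !nrow(mot)) {
    stop("empty-analysis error: both a cognitive and a motor block are ",
         "required after exclusions")
  }
  grid <- expand.grid(ci = seq_len(nrow(cog)), mi = seq_len(nrow(mot)))
  nUntestable <- 0L
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ci <- grid$ci[i]
    mi <- grid$mi[i]
    res <- tryCatch(
      partialSpearman(vals[cog$variable_id[ci], ],
                      vals[mot$variable_id[mi], ], cov),
      error = function(e) NULL
    )
    if (is.null(res)) {
      nUntestable <<- nUntestable + 1L
      res <- list(rho = NA_real_, p_value = 1, n_used = NA_integer_)
    }
    data.frame(cognitive_id = cog$variable_id[ci],
               cognitive_domain = cog$domain[ci],
               motor_id = mot$variable_id[mi],
               motor_domain = mot$domain[mi],
               rho = res$rho, p = res$p_value, n_used = res$n_used,
               untestable = is.na(res$rho),
               stringsAsFactors = FALSE)
  })
  if (nUntestable > 0L) {
    warning(nUntestable, " untestable pair(s) propagated with p = 1")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
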