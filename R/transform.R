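#' @include utils.R
NULL

.TRANSFORM_CATALOG <- c("identity", "log-shift", "sqrt-shift", "reciprocal",
                        "box-cox", "rank-inverse-normal")

#' Describe a non-linear transformation
#'
#' A member of the fixed transformation catalog: identity, log(x + s),
#' sqrt(x + s), 1/(x + s) (order-reversing), Box-Cox with profile-likelihood
#' lambda, and rank-based inverse normal with Blom offsets. Shifts make the
#' input strictly positive where the transform requires it. When
#' `orderReversing` is `TRUE` the transformed values are multiplied by -1,
#' so that a decreasing catalog member (the reciprocal) preserves the
#' original ordering of the data.
#'
#' @param name Catalog tag, one of `"identity"`, `"log-shift"`,
#'   `"sqrt-shift"`, `"reciprocal"`, `"box-cox"`, `"rank-inverse-normal"`.
#' @param shift Additive shift s applied before the transform (default 0).
#' @param lambda Box-Cox exponent (only used by `"box-cox"`).
#' @param orderReversing Multiply the transformed values by -1. Defaults to
#'   `TRUE` for the reciprocal, which is monotone decreasing, and `FALSE`
#'   otherwise.
#' @return A list of class `"TransformSpec"`.
#' @examples
#' applyTransform(c(1, 2, 3), transformSpec("identity",
#'                                          orderReversing = TRUE))
#' @export
transformSpec <- function(name, shift = 0, lambda = NA_real_,
                          orderReversing = (name == "reciprocal")) {
  name <- match.arg(name, .TRANSFORM_CATALOG)
  structure(list(name = name, shift = shift, lambda = lambda,
                 orderReversing = isTRUE(orderReversing)),
            class = "TransformSpec")
}

#' @export
print.TransformSpec <- function(x, ...) {
  cat("TransformSpec:", x$name,
      if (x$shift != 0) sprintf("(shift %.4g)", x$shift) else "",
      if (!is.na(x$lambda)) sprintf("(lambda %.3g)", x$lambda) else "",
      if (x$orderReversing) "[order-reversing: output multiplied by -1]"
      else "", "\n")
  invisible(x)
}

# shift that makes all non-missing values strictly positive, 0 when already so
.autoShift <- function(x, strict = TRUE) {
  m <- min(x, na.rm = TRUE)
  if (strict) {
    if (m > 0) 0 else 1 - m
  } else {
    if (m >= 0) 0 else 1 - m
  }
}

#' Apply a transformation specification to a numeric vector
#'
#' Missing cells stay missing. The transform must be defined on the whole
#' (shifted) input domain or an error naming the problem is raised.
#'
#' @param x Numeric vector.
#' @param spec A `TransformSpec` from [transformSpec()].
#' @return Transformed numeric vector, negated when the spec is
#'   order-reversing.
#' @export
applyTransform <- function(x, spec) {
  stopifnot(inherits(spec, "TransformSpec"))
  xs <- x + spec$shift
  ok <- !is.na(xs)
  out <- switch(spec$name,
    identity = x,
    "log-shift" = {
      if (any(xs[ok] <= 0)) {
        stop("transform-domain error: log requires strictly positive ",
             "(shifted) values")
      }
      log(xs)
    },
    "sqrt-shift" = {
      if (any(xs[ok] < 0)) {
        stop("transform-domain error: sqrt requires non-negative ",
             "(shifted) values")
      }
      sqrt(xs)
    },
    reciprocal = {
      if (any(xs[ok] == 0)) {
        stop("transform-domain error: reciprocal requires non-zero ",
             "(shifted) values")
      }
      1 / xs
    },
    "box-cox" = {
      if (any(xs[ok] <= 0)) {
        stop("transform-domain error: Box-Cox requires strictly positive ",
             "(shifted) values")
      }
      lam <- spec$lambda
      if (is.na(lam)) stop("transform-domain error: Box-Cox needs lambda")
      if (abs(lam) < 1e-8) log(xs) else (xs^lam - 1) / lam
    },
    "rank-inverse-normal" = {
      r <- rank(x, na.last = "keep")
      nOk <- sum(!is.na(x))
      stats::qnorm((r - 3 / 8) / (nOk + 1 / 4))
    }
  )
  if (spec$orderReversing) -out else out
}

# Box-Cox profile log-likelihood on a coarse lambda grid
.boxCoxLambda <- function(y, grid = seq(-2, 2, by = 0.25)) {
  y <- y[!is.na(y)]
  n <- length(y)
  slog <- sum(log(y))
  ll <- vapply(grid, function(lam) {
    z <- if (abs(lam) < 1e-8) log(y) else (y^lam - 1) / lam
    v <- mean((z - mean(z))^2)
    if (!is.finite(v) || v <= 0) return(-Inf)
    -n / 2 * log(v) + (lam - 1) * slog
  }, numeric(1))
  grid[which.max(ll)]
}

# Shapiro-Wilk W as the normality score; -Inf for unusable candidates
.normalityScore <- function(z) {
  z <- z[!is.na(z) & is.finite(z)]
  n <- length(z)
  if (n < 3 || stats::sd(z) == 0) return(-Inf)
  if (n > 5000) z <- z[round(seq(1, n, length.out = 5000))]
  tryCatch(unname(stats::shapiro.test(z)$statistic), error = function(e) -Inf)
}

#' Select the catalog transformation maximizing a normality score
#'
#' Evaluates every catalog member (with automatic shifts s = 1 - min(x)
#' where positivity is required, and profile-likelihood lambda for Box-Cox)
#' and returns the one with the largest Shapiro-Wilk W statistic; ties are
#' broken by catalog order. The choice is deterministic given the data.
#'
#' @param x Numeric vector with at least 3 non-missing values.
#' @return A `TransformSpec` with attribute `"score"` (the winning W).
#' @export
selectTransform <- function(x) {
  if (sum(!is.na(x)) < 3) {
    stop("input error: need at least 3 non-missing values to select a ",
         "transformation")
  }
  sPos <- .autoShift(x, strict = TRUE)
  sNon <- .autoShift(x, strict = FALSE)
  candidates <- list(
    transformSpec("identity"),
    transformSpec("log-shift", shift = sPos),
    transformSpec("sqrt-shift", shift = sNon),
    transformSpec("reciprocal", shift = sPos),
    transformSpec("box-cox", shift = sPos,
                  lambda = .boxCoxLambda(x + sPos)),
    transformSpec("rank-inverse-normal")
  )
  scores <- vapply(candidates, function(sp) {
    z <- tryCatch(applyTransform(x, sp), error = function(e) NULL)
    if (is.null(z)) -Inf else .normalityScore(z)
  }, numeric(1))
  best <- candidates[[which.max(scores)]]
  attr(best, "score") <- max(scores)
  best
}

#' Transform a variable, automatically or by override
#'
#' The workhorse used per variable during preprocessing. With an override it
#' is applied verbatim; otherwise the catalog member chosen by
#' [selectTransform()] is used. Order-reversing members have their output
#' multiplied by -1, so monotone members preserve — and order-reversing ones
#' exactly preserve, after negation — the rank order of the input.
#'
#' @param x Numeric vector.
#' @param override `NULL` for automatic selection, a `TransformSpec`, or a
#'   catalog tag (shift and lambda then chosen automatically).
#' @return A list with `values` (transformed vector) and `spec` (the
#'   `TransformSpec` applied).
#' @examples
#' autoTransform(rexp(50))$spec
#' @export
autoTransform <- function(x, override = NULL) {
  spec <- if (is.null(override)) {
    selectTransform(x)
  } else if (inherits(override, "TransformSpec")) {
    override
  } else if (is.character(override) && length(override) == 1L) {
    name <- match.arg(override, .TRANSFORM_CATALOG)
    sh <- switch(name,
      identity = 0,
      "rank-inverse-normal" = 0,
      "sqrt-shift" = .autoShift(x, strict = FALSE),
      .autoShift(x, strict = TRUE)
    )
    lam <- if (name == "box-cox") .boxCoxLambda(x + sh) else NA_real_
    transformSpec(name, shift = sh, lambda = lam)
  } else {
    stop("input error: override must be NULL, a TransformSpec or a catalog ",
         "tag")
  }
  list(values = applyTransform(x, spec), spec = spec)
}
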