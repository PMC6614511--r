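#' @include utils.R
NULL

#' Limited-range exclusion rule
#'
#' Computes the modal proportion of a variable — the fraction of non-missing
#' observations equal to its most frequent value — and excludes the variable
#' when that proportion reaches the threshold (inclusive: a variable where
#' 80% of participants share one value is excluded at the default 0.80).
#' An all-missing variable is excluded with modal proportion reported as 1.
#'
#' @param x Numeric vector.
#' @param threshold Modal-proportion threshold (default 0.80).
#' @return A list with `modal_proportion`, `threshold` and `excluded`.
#' @examples
#' limitedRangeFilter(c(rep(0, 8), 1, 2))$excluded   # TRUE: 0.8 >= 0.8
#' limitedRangeFilter(c(rep(0, 98), rnorm(26)))$excluded # FALSE: 98/124
#' @export
limitedRangeFilter <- function(x, threshold = 0.80) {
  if (!.isProb(threshold, open.lower = TRUE)) {
    stop("input error: threshold must lie in (0, 1]")
  }
  x <- x[!is.na(x)]
  if (!length(x)) {
    return(list(modal_proportion = 1, threshold = threshold, excluded = TRUE))
  }
  prop <- max(table(x)) / length(x)
  list(modal_proportion = unname(prop), threshold = threshold,
       excluded = unname(prop >= threshold))
}
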