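#' @include AllClasses.R transform.R outliers.R rangefilter.R
NULL

#' Construct a pipeline configuration
#'
#' @param screeningAlpha Simes screening level (strict inequality; default
#'   0.05).
#' @param bhQ Within-family BH FDR level (default 0.05).
#' @param outlierCutoffNumerator Numerator of the Bonferroni outlier cutoff
#'   c/n (default 4).
#' @param rangeFilterThreshold Modal-proportion exclusion threshold (default
#'   0.80).
#' @param selectionAdjustedBH Scale the within-family BH level by the
#'   fraction of families selected (default `FALSE`; the plain procedure
#'   applies BH at `bhQ` inside every selected family).
#' @param transformSelection `"auto"` (default) or `"none"`.
#' @return A validated \linkS4class{PipelineConfig}.
#' @examples
#' pipelineConfig()
#' @export
pipelineConfig <- function(screeningAlpha = 0.05,
                           bhQ = 0.05,
                           outlierCutoffNumerator = 4,
                           rangeFilterThreshold = 0.80,
                           selectionAdjustedBH = FALSE,
                           transformSelection = c("auto", "none")) {
  obj <- methods::new("PipelineConfig",
    screeningAlpha = as.numeric(screeningAlpha),
    bhQ = as.numeric(bhQ),
    outlierCutoffNumerator = as.numeric(outlierCutoffNumerator),
    rangeFilterThreshold = as.numeric(rangeFilterThreshold),
    selectionAdjustedBH = isTRUE(selectionAdjustedBH),
    transformSelection = match.arg(transformSelection)
  )
  methods::validObject(obj)
  obj
}

#' Preprocess a cohort: transform, remove outliers, exclude limited-range
#' variables
#'
#' Applies the three preprocessing rules in order, per variable:
#' \enumerate{
#'   \item non-linear transformation — the `rowData$transform` override when
#'     present, otherwise the catalog member maximizing the Shapiro-Wilk
#'     statistic ([selectTransform()]); order-reversing members are
#'     multiplied by -1;
#'   \item covariate-adjusted outlier removal — cells whose Bonferroni
#'     p-value for the externally studentized residual (regression on age
#'     and gender) is strictly below c/n are set missing for that variable
#'     only ([detectOutliers()]);
#'   \item limited-range exclusion — variables whose modal proportion
#'     reaches the threshold are dropped ([limitedRangeFilter()]).
#' }
#'
#' @param x A \linkS4class{CohortExperiment}.
#' @param config A \linkS4class{PipelineConfig}.
#' @return A list with `experiment` (the preprocessed cohort, excluded
#'   variables removed), `transforms` (chosen spec per variable),
#'   `outliers` (flagged cells) and `exclusions` (modal proportion and
#'   decision for every variable).
#' @examples
#' ce <- simulateCohort(scenarioConfig("null", nSubjects = 60))
#' pre <- preprocessCohort(ce)
#' pre$exclusions
#' @export
preprocessCohort <- function(x, config = pipelineConfig()) {
  methods::validObject(config)
  vals <- cohortValues(x)
  meta <- variableMeta(x)
  cov <- covariateData(x)
  covAdj <- cov[, setdiff(names(cov), "subject_id"), drop = FALSE]

  transforms <- vector("list", nrow(vals))
  outliers <- list()
  for (v in seq_len(nrow(vals))) {
    id <- meta$variable_id[v]
    override <- meta$transform[v]
    if (!is.null(override) && !is.na(override) && nzchar(override)) {
      tr <- autoTransform(vals[v, ], override = override)
    } else if (config@transformSelection == "none") {
      tr <- autoTransform(vals[v, ], override = transformSpec("identity"))
    } else {
      tr <- autoTransform(vals[v, ])
    }
    y <- tr$values
    transforms[[v]] <- data.frame(
      variable_id = id, transform = tr$spec$name, shift = tr$spec$shift,
      lambda = tr$spec$lambda, order_reversing = tr$spec$orderReversing,
      stringsAsFactors = FALSE
    )
    rep <- detectOutliers(y, cov,
                          cutoffNumerator = config@outlierCutoffNumerator)
    if (nrow(rep)) {
      y[rep$subject] <- NA_real_
      outliers[[id]] <- data.frame(
        variable_id = id, rep,
        cutoff_used = attr(rep, "cutoff_used"),
        stringsAsFactors = FALSE
      )
    }
    vals[v, ] <- y
  }
  transforms <- do.call(rbind, transforms)
  outliers <- if (length(outliers)) {
    out <- do.call(rbind, outliers)
    rownames(out) <- NULL
    out
  } else {
    data.frame(variable_id = character(0), subject = integer(0),
               subject_id = character(0), studentized_residual = numeric(0),
               bonferroni_p = numeric(0), cutoff_used = numeric(0))
  }

  excl <- lapply(seq_len(nrow(vals)), function(v) {
    f <- limitedRangeFilter(vals[v, ], threshold = config@rangeFilterThreshold)
    data.frame(variable_id = meta$variable_id[v],
               modal_proportion = f$modal_proportion,
               threshold = f$threshold, excluded = f$excluded,
               stringsAsFactors = FALSE)
  })
  exclusions <- do.call(rbind, excl)

  keep <- !exclusions$excluded
  meta2 <- meta[keep, , drop = FALSE]
  ce2 <- CohortExperiment(vals[keep, , drop = FALSE], meta2, cov,
                          truth = truthSet(x),
                          generatorConfig =
                            S4Vectors::metadata(x)$generatorConfig)
  list(experiment = ce2, transforms = transforms, outliers = outliers,
       exclusions = exclusions)
}
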