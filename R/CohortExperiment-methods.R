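#' @include AllClasses.R
NULL

#' Construct a CohortExperiment from its three tables
#'
#' @param values Numeric matrix, variables as rows and subjects as columns
#'   (a subjects-by-variables matrix is transposed when its column names
#'   match `meta$variable_id` and its row names do not).
#' @param meta `data.frame` with columns `variable_id`, `block` (`"cognitive"`
#'   or `"motor"`), `domain`, `direction` and optionally `transform`
#'   (a transformation-catalog tag overriding automatic selection, `NA` for
#'   automatic).
#' @param covariates `data.frame` with columns `subject_id` (optional),
#'   `age` and `gender` (0 = male, 1 = female), one row per subject.
#' @param truth Optional \linkS4class{TruthSet} stored in `metadata()`.
#' @param generatorConfig Optional \linkS4class{GeneratorConfig} stored in
#'   `metadata()`.
#' @return A \linkS4class{CohortExperiment}.
#' @examples
#' vals <- matrix(rnorm(40), nrow = 4,
#'                dimnames = list(paste0("v", 1:4), paste0("S", 1:10)))
#' meta <- data.frame(variable_id = paste0("v", 1:4),
#'                    block = rep(c("cognitive", "motor"), each = 2),
#'                    domain = c("executive", "executive", "pace", "pace"),
#'                    direction = "higher")
#' cov <- data.frame(age = runif(10, 30, 80), gender = rep(0:1, 5))
#' ce <- CohortExperiment(vals, meta, cov)
#' @export
CohortExperiment <- function(values, meta, covariates, truth = NULL,
                             generatorConfig = NULL) {
  meta <- as.data.frame(meta)
  covariates <- as.data.frame(covariates)
  if (!"transform" %in% names(meta)) meta$transform <- NA_character_
  values <- as.matrix(values)
  if (!is.null(colnames(values)) &&
      all(meta$variable_id %in% colnames(values)) &&
      !all(meta$variable_id %in% rownames(values))) {
    values <- t(values)
  }
  if (is.null(rownames(values))) rownames(values) <- meta$variable_id
  values <- values[meta$variable_id, , drop = FALSE]
  if (!"subject_id" %in% names(covariates)) {
    covariates$subject_id <- if (!is.null(colnames(values))) {
      colnames(values)
    } else {
      sprintf("S%03d", seq_len(ncol(values)))
    }
  }
  covariates$subject_id <- as.character(covariates$subject_id)
  colnames(values) <- covariates$subject_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values),
    rowData = S4Vectors::DataFrame(meta, row.names = meta$variable_id),
    colData = S4Vectors::DataFrame(covariates,
                                   row.names = covariates$subject_id)
  )
  md <- list()
  if (!is.null(truth)) md$truth <- truth
  if (!is.null(generatorConfig)) md$generatorConfig <- generatorConfig
  S4Vectors::metadata(se) <- md
  methods::new("CohortExperiment", se)
}

#' @rdname cohortValues
#' @export
setMethod("cohortValues", "CohortExperiment", function(x, ...) {
  SummarizedExperiment::assay(x, "values")
})

#' @rdname cohortValues
#' @export
setMethod("variableMeta", "CohortExperiment", function(x, ...) {
  as.data.frame(SummarizedExperiment::rowData(x))
})

#' @rdname cohortValues
#' @export
setMethod("covariateData", "CohortExperiment", function(x, ...) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cd[, intersect(c("subject_id", "age", "gender"), names(cd)), drop = FALSE]
})

#' @rdname cohortValues
#' @export
setMethod("truthSet", "CohortExperiment", function(x, ...) {
  S4Vectors::metadata(x)$truth
})

setMethod("show", "CohortExperiment", function(object) {
  meta <- variableMeta(object)
  cat("CohortExperiment:", ncol(object), "subjects,",
      sum(meta$block == "cognitive"), "cognitive and",
      sum(meta$block == "motor"), "motor variables\n")
  cat("  cognitive domains:",
      paste(unique(meta$domain[meta$block == "cognitive"]), collapse = ", "),
      "\n  motor domains:    ",
      paste(unique(meta$domain[meta$block == "motor"]), collapse = ", "), "\n")
  if (!is.null(truthSet(object))) {
    cat("  ground truth attached (synthetic cohort)\n")
  }
})

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:", nrow(object@plantedLinks), "planted link(s),",
      nrow(object@injectedOutliers), "injected outlier cell(s),",
      length(object@degenerateVariables), "degenerate variable(s)\n")
  if (nrow(object@plantedLinks)) {
    print(object@plantedLinks, row.names = FALSE)
  }
})

setMethod("show", "AssociationReport", function(object) {
  fl <- object@familyLog
  cat("AssociationReport:", nrow(fl), "hypothesis families,",
      sum(fl$selected), "selected (Simes p <",
      object@config@screeningAlpha, ")\n")
  cat("  ", nrow(object@associations),
      "association(s) at within-family BH level", object@effectiveQ, "\n")
  if (nrow(object@associations)) {
    print(object@associations[, c("cognitive_domain", "cognitive_id",
                                  "motor_domain", "motor_id", "rho",
                                  "adjusted_p")],
          row.names = FALSE, digits = 3)
  }
})

setMethod("show", "OperatingCharacteristics", function(object) {
  cat("OperatingCharacteristics over", object@nReplicates, "replicates\n")
  cat(sprintf("  family selection rate: %.4f (SE %.4f)\n",
              object@familySelectionRate,
              object@monteCarloSE["familySelectionRate"]))
  cat(sprintf("  empirical FDR:         %.4f (SE %.4f)\n",
              object@empiricalFdr, object@monteCarloSE["empiricalFdr"]))
  if (!is.na(object@power)) {
    cat(sprintf("  power:                 %.4f (SE %.4f)\n",
                object@power, object@monteCarloSE["power"]))
    cat(sprintf("  complete recovery:     %.4f\n",
                object@completeRecoveryRate))
  }
  cat(sprintf("  replicates w/o report: %.4f\n", object@noRejectionFraction))
})

#' @rdname reportTable
#' @export
setMethod("reportTable", "AssociationReport", function(x, ...) x@associations)

#' @rdname reportTable
#' @export
setMethod("familyLog", "AssociationReport", function(x, ...) x@familyLog)

#' @rdname reportTable
#' @export
setMethod("memberLog", "AssociationReport", function(x, ...) x@memberLog)
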