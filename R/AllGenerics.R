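#' @include utils.R
NULL

#' Extract the subjects-by-variables value matrix
#'
#' @param x A \linkS4class{CohortExperiment}.
#' @param ... Further arguments (unused).
#' @return For `cohortValues`, a numeric matrix with variables as rows and
#'   subjects as columns (missing cells are `NA`).
#' @export
setGeneric("cohortValues", function(x, ...) standardGeneric("cohortValues"))

#' @rdname cohortValues
#' @return For `variableMeta`, a `data.frame` with one row per variable
#'   (columns `variable_id`, `block`, `domain`, `direction`, `transform`).
#' @export
setGeneric("variableMeta", function(x, ...) standardGeneric("variableMeta"))

#' @rdname cohortValues
#' @return For `covariateData`, a `data.frame` of per-subject adjustment
#'   covariates (`age` in years, `gender` coded 0 = male, 1 = female).
#' @export
setGeneric("covariateData", function(x, ...) standardGeneric("covariateData"))

#' @rdname cohortValues
#' @return For `truthSet`, the \linkS4class{TruthSet} attached by the
#'   generator, or `NULL` for cohorts read from disk.
#' @export
setGeneric("truthSet", function(x, ...) standardGeneric("truthSet"))

#' Accessors for association reports
#'
#' @param x An \linkS4class{AssociationReport}.
#' @param ... Further arguments (unused).
#' @return `reportTable`: the selected associations (one row per rejected
#'   member of a selected family); `familyLog`: one row per hypothesis family
#'   with its Simes p-value and selection flag; `memberLog`: every
#'   cognitive-motor correlation with raw and (where computed) BH-adjusted
#'   p-values.
#' @export
setGeneric("reportTable", function(x, ...) standardGeneric("reportTable"))

#' @rdname reportTable
#' @export
setGeneric("familyLog", function(x, ...) standardGeneric("familyLog"))

#' @rdname reportTable
#' @export
setGeneric("memberLog", function(x, ...) standardGeneric("memberLog"))
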