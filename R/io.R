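#' @include AllClasses.R preprocess.R
NULL

.DOMAIN_VOCAB <- list(cognitive = .COGNITIVE_DOMAINS, motor = .MOTOR_DOMAINS)

#' Read a cohort from its three CSV tables
#'
#' Expects the layout written by [writeCohort()]: a data table (subjects as
#' rows, first column `subject_id`, one column per variable), a variable
#' metadata sidecar (`variable_id`, `block`, `domain`, `direction`, optional
#' `transform`) and a covariate table (`subject_id`, `age`, `gender`).
#' Every data column must have metadata and vice versa; subjects are aligned
#' by id across files; empty fields or the sentinel are parsed as missing.
#' Domains outside the controlled vocabulary are rejected unless
#' `strictDomains = FALSE`.
#'
#' @param dataPath,metaPath,covPath File paths.
#' @param missingSentinel Additional string parsed as missing (default
#'   `"NA"`; empty fields are always missing).
#' @param strictDomains Validate domains against the vocabulary (default
#'   `TRUE`).
#' @return A \linkS4class{CohortExperiment}.
#' @export
readCohort <- function(dataPath, metaPath, covPath, missingSentinel = "NA",
                       strictDomains = TRUE) {
  for (p in c(dataPath, metaPath, covPath)) {
    if (!file.exists(p)) stop("I/O error: file not found: ", p)
  }
  na <- unique(c("", missingSentinel))
  dat <- utils::read.csv(dataPath, check.names = FALSE, na.strings = na,
                         stringsAsFactors = FALSE)
  meta <- utils::read.csv(metaPath, na.strings = na, stringsAsFactors = FALSE)
  cov <- utils::read.csv(covPath, na.strings = na, stringsAsFactors = FALSE)

  if (!"subject_id" %in% names(dat)) {
    stop("schema error: data table needs a subject_id column")
  }
  if (anyDuplicated(dat$subject_id)) {
    stop("schema error: duplicate subject id in data table: ",
         dat$subject_id[duplicated(dat$subject_id)][1])
  }
  need <- c("variable_id", "block", "domain", "direction")
  if (!all(need %in% names(meta))) {
    stop("schema error: metadata needs columns ",
         paste(need, collapse = ", "))
  }
  dataVars <- setdiff(names(dat), "subject_id")
  noMeta <- setdiff(dataVars, meta$variable_id)
  if (length(noMeta)) {
    stop("schema error: data column(s) absent from metadata: ",
         paste(noMeta, collapse = ", "))
  }
  noData <- setdiff(meta$variable_id, dataVars)
  if (length(noData)) {
    stop("schema error: metadata variable(s) absent from data: ",
         paste(noData, collapse = ", "))
  }
  if (!all(meta$block %in% .BLOCKS)) {
    stop("schema error: block must be one of ",
         paste(.BLOCKS, collapse = ", "))
  }
  if (strictDomains) {
    for (b in .BLOCKS) {
      bad <- setdiff(meta$domain[meta$block == b], .DOMAIN_VOCAB[[b]])
      if (length(bad)) {
        stop("schema error: unknown ", b, " domain(s) ",
             paste(bad, collapse = ", "), "; allowed: ",
             paste(.DOMAIN_VOCAB[[b]], collapse = ", "))
      }
    }
  }
  for (v in dataVars) {
    if (!is.numeric(dat[[v]])) {
      bad <- which(!is.na(dat[[v]]) &
                     is.na(suppressWarnings(as.numeric(dat[[v]]))))[1]
      stop("schema error: non-numeric cell at row ", bad, ", column '", v,
           "'")
    }
  }
  if (!all(c("subject_id", "age", "gender") %in% names(cov))) {
    stop("schema error: covariate table needs subject_id, age, gender")
  }
  if (anyDuplicated(cov$subject_id)) {
    stop("schema error: duplicate subject id in covariate table")
  }
  missingCov <- setdiff(dat$subject_id, cov$subject_id)
  if (length(missingCov)) {
    stop("schema error: subject(s) without covariates: ",
         paste(utils::head(missingCov, 5), collapse = ", "))
  }
  cov <- cov[match(dat$subject_id, cov$subject_id), , drop = FALSE]
  vals <- as.matrix(dat[, meta$variable_id, drop = FALSE])
  rownames(vals) <- dat$subject_id
  CohortExperiment(t(vals), meta, cov)
}

#' Write a cohort to CSV (plus ground truth as JSON when present)
#'
#' Writes `data.csv` (subjects as rows), `meta.csv`, `covariates.csv` and —
#' for synthetic cohorts — `truth.json` into `dir`. [readCohort()] reads the
#' result back identically.
#'
#' @param x A \linkS4class{CohortExperiment}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeCohort <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vals <- t(cohortValues(x))
  dat <- data.frame(subject_id = rownames(vals), vals, check.names = FALSE,
                    row.names = NULL)
  paths <- c(data = file.path(dir, "data.csv"),
             meta = file.path(dir, "meta.csv"),
             covariates = file.path(dir, "covariates.csv"))
  utils::write.csv(dat, paths["data"], row.names = FALSE, na = "")
  utils::write.csv(variableMeta(x), paths["meta"], row.names = FALSE,
                   na = "")
  utils::write.csv(covariateData(x), paths["covariates"], row.names = FALSE,
                   na = "")
  truth <- truthSet(x)
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.json"))
    jsonlite::write_json(
      list(planted_links = truth@plantedLinks,
           injected_outliers = truth@injectedOutliers,
           degenerate_variables = truth@degenerateVariables),
      paths["truth"], dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  }
  invisible(paths)
}

.formatP <- function(p, digits = 3, floor = 10^(-digits),
                     useFloor = TRUE) {
  out <- formatC(round(p, digits), format = "f", digits = digits)
  if (useFloor) out[p < floor] <- paste0("<", formatC(floor, format = "f",
                                                      digits = digits))
  out
}

#' Write the association report and its family log
#'
#' The report TSV has columns `cognitive_domain`, `cognitive_measure`,
#' `motor_domain`, `motor_measure`, `rho`, `adjusted_p` in stable order;
#' adjusted p-values are printed to three decimals with values below the
#' floor shown as e.g. `<0.001` (disable with `floorSmall = FALSE`). An empty
#' report yields a header-only file. A companion family log (`*_families.tsv`
#' next to `path`) records every family's Simes p-value and selection flag.
#'
#' @param report An \linkS4class{AssociationReport}.
#' @param path Output TSV path.
#' @param floorSmall Print very small adjusted p-values as `<0.001`
#'   (default `TRUE`).
#' @return Invisibly, the paths written.
#' @export
writeReport <- function(report, path, floorSmall = TRUE) {
  tab <- reportTable(report)
  out <- data.frame(
    cognitive_domain = tab$cognitive_domain,
    cognitive_measure = tab$cognitive_id,
    motor_domain = tab$motor_domain,
    motor_measure = tab$motor_id,
    rho = round(tab$rho, 3),
    adjusted_p = .formatP(tab$adjusted_p, useFloor = floorSmall),
    stringsAsFactors = FALSE
  )
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  famPath <- sub("(\\.[A-Za-z]+)?$", "_families.tsv", path)
  utils::write.table(familyLog(report), famPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(report = path, families = famPath))
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `screening_alpha`, `bh_q`, `outlier_cutoff_numerator`,
#' `range_filter_threshold`, `selection_adjusted_bh`, `transform_selection`.
#' Missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  y <- yaml::read_yaml(path)
  pick <- function(key, default) if (!is.null(y[[key]])) y[[key]] else default
  pipelineConfig(
    screeningAlpha = pick("screening_alpha", 0.05),
    bhQ = pick("bh_q", 0.05),
    outlierCutoffNumerator = pick("outlier_cutoff_numerator", 4),
    rangeFilterThreshold = pick("range_filter_threshold", 0.80),
    selectionAdjustedBH = pick("selection_adjusted_bh", FALSE),
    transformSelection = pick("transform_selection", "auto")
  )
}
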