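#' @include AllClasses.R association.R preprocess.R
NULL

#' Simes combination p-value
#'
#' For m ordered p-values p(1) <= ... <= p(m), returns
#' min over i of m * p(i) / i, capped at 1 — a valid global-null p-value
#' under independence or positive dependence of the members.
#'
#' @param p Nonempty numeric vector of p-values in (0, 1\].
#' @return A single probability.
#' @examples
#' simesPvalue(c(0.01, 0.04, 0.03)) # 0.03
#' @export
simesPvalue <- function(p) {
  if (!length(p)) stop("input error: empty p-value list")
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("input error: p-values must lie in (0, 1]")
  }
  m <- length(p)
  sp <- sort(p)
  min(1, min(m * sp / seq_len(m)))
}

#' Group the correlation matrix into hypothesis families
#'
#' One family per (motor variable, cognitive domain): its members are the
#' correlations between that motor variable and every kept cognitive variable
#' of the domain, so the family count equals the number of motor variables
#' times the number of cognitive domains, and every matrix entry belongs to
#' exactly one family.
#'
#' @param assoc The pair table from [associationMatrix()].
#' @param meta Optional variable metadata used to validate domains.
#' @return A list with `members` (the pair table plus `family_id`) and
#'   `families` (`family_id`, `motor_id`, `motor_domain`,
#'   `cognitive_domain`, `m`, `simes_p`).
#' @export
groupHypotheses <- function(assoc, meta = NULL) {
  if (!is.null(meta)) {
    known <- meta$variable_id[!is.na(meta$domain) & nzchar(meta$domain)]
    bad <- setdiff(unique(c(assoc$cognitive_id, assoc$motor_id)), known)
    if (length(bad)) {
      stop("metadata error: variable(s) without a domain: ",
           paste(bad, collapse = ", "))
    }
  }
  if (any(is.na(assoc$cognitive_domain)) || any(is.na(assoc$motor_domain))) {
    stop("metadata error: variable with unknown domain in the pair table")
  }
  assoc$family_id <- paste(assoc$motor_id, assoc$cognitive_domain, sep = "|")
  fams <- unique(assoc[, c("family_id", "motor_id", "motor_domain",
                           "cognitive_domain")])
  fams$m <- as.integer(table(assoc$family_id)[fams$family_id])
  fams$simes_p <- vapply(fams$family_id, function(f) {
    simesPvalue(assoc$p[assoc$family_id == f])
  }, numeric(1))
  rownames(fams) <- NULL
  list(members = assoc, families = fams)
}

#' Screen hypothesis families by their Simes p-value
#'
#' A family is selected when its Simes p-value is strictly smaller than
#' `alpha`; the flag is recorded for every family.
#'
#' @param families The `families` table from [groupHypotheses()].
#' @param alpha Screening level (default 0.05).
#' @return The table with a logical `selected` column.
#' @export
screenFamilies <- function(families, alpha = 0.05) {
  families$selected <- families$simes_p < alpha
  families
}

#' Within-family Benjamini-Hochberg adjustment
#'
#' Standard BH step-up on a selected family's member p-values only: the
#' adjusted p-value of the i-th order statistic is
#' min over j >= i of m * p(j) / j (monotone-enforced, capped at 1), so that
#' "adjusted p <= q" holds exactly for the step-up rejection set.
#'
#' @param p Numeric vector of the family's member p-values.
#' @param q FDR level (default 0.05); rejection is inclusive (adjusted
#'   p <= q).
#' @return A list with `adjusted_p` and logical `rejected`.
#' @examples
#' bhWithinFamily(c(0.01, 0.02, 0.20)) # adjusted 0.03, 0.03, 0.20
#' @export
bhWithinFamily <- function(p, q = 0.05) {
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted_p = adj, rejected = adj <= q)
}

#' Run the full two-stage association pipeline
#'
#' Executes, in order: per-variable transformation, covariate-adjusted
#' outlier removal, limited-range exclusion, the cognitive-by-motor partial
#' Spearman matrix, hypothesis-family construction, Simes screening at
#' `screeningAlpha`, and within-family BH at `bhQ` inside each selected
#' family separately. The report lists every rejected member of a selected
#' family, sorted by cognitive domain then motor domain; the family and
#' member logs keep all Simes and raw/adjusted p-values for auditing.
#'
#' @param x A \linkS4class{CohortExperiment}.
#' @param config A \linkS4class{PipelineConfig}.
#' @return An \linkS4class{AssociationReport}.
#' @examples
#' ce <- simulateCohort(scenarioConfig("signal", nSubjects = 120))
#' rep <- runPipeline(ce)
#' reportTable(rep)
#' @export
runPipeline <- function(x, config = pipelineConfig()) {
  pre <- preprocessCohort(x, config)
  ce <- pre$experiment
  metaKept <- variableMeta(ce)
  if (!sum(metaKept$block == "cognitive") || !sum(metaKept$block == "motor")) {
    stop("empty-analysis error: all variables of one block were excluded")
  }
  assoc <- associationMatrix(ce)
  grp <- groupHypotheses(assoc, metaKept)
  fams <- screenFamilies(grp$families, alpha = config@screeningAlpha)
  members <- grp$members
  members$selected <- fams$selected[match(members$family_id, fams$family_id)]
  members$adjusted_p <- NA_real_
  members$rejected <- FALSE

  qEff <- config@bhQ
  if (config@selectionAdjustedBH && nrow(fams)) {
    qEff <- config@bhQ * sum(fams$selected) / nrow(fams)
  }
  for (f in fams$family_id[fams$selected]) {
    i <- which(members$family_id == f)
    # stable order by p then variable id; cannot change the rejection set
    i <- i[order(members$p[i], members$cognitive_id[i])]
    bh <- bhWithinFamily(members$p[i], q = qEff)
    members$adjusted_p[i] <- bh$adjusted_p
    members$rejected[i] <- bh$rejected
  }

  rep <- members[members$rejected, c("cognitive_domain", "cognitive_id",
                                     "motor_domain", "motor_id", "rho", "p",
                                     "adjusted_p", "n_used"), drop = FALSE]
  # mirror the report layout: cognitive domain blocks, motor domain within
  cogOrder <- unique(metaKept$domain[metaKept$block == "cognitive"])
  motOrder <- unique(metaKept$domain[metaKept$block == "motor"])
  rep <- rep[order(match(rep$cognitive_domain, cogOrder),
                   match(rep$motor_domain, motOrder),
                   rep$motor_id, rep$adjusted_p), , drop = FALSE]
  rownames(rep) <- NULL

  obj <- methods::new("AssociationReport",
    associations = rep,
    familyLog = fams,
    memberLog = members,
    exclusions = pre$exclusions,
    outliers = pre$outliers,
    transforms = pre$transforms,
    config = config,
    effectiveQ = qEff,
    nSubjects = ncol(ce)
  )
  methods::validObject(obj)
  obj
}
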