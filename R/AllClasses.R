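#' @include AllGenerics.R utils.R
NULL

#' Configuration for the synthetic cohort generator
#'
#' Holds the study conditions emulated by [simulateCohort()]: cohort size and
#' demographics, the variable inventory (one row per cognitive or motor
#' variable with block, domain, direction and marginal-distortion tag),
#' standardized covariate effects that confound both blocks, planted
#' cross-block links, outlier contamination, degenerate (near-constant)
#' variables and optional missingness. Build instances with
#' [generatorConfig()] or [scenarioConfig()].
#'
#' @slot nSubjects Integer cohort size (at least 10).
#' @slot ageRange Numeric length-2, admissible age range in years.
#' @slot ageMean,ageSD Mean and SD of the (truncated Gaussian) age draw.
#' @slot propFemale Fraction of subjects with gender code 1 (female).
#' @slot inventory `data.frame` with columns `variable_id`, `block`,
#'   `domain`, `direction` (`"higher"`/`"lower"` = better), `mean`, `sd`
#'   (target scale; `NA` leaves the latent scale), `distortion`.
#' @slot plantedLinks `data.frame` with columns `cognitive_id`, `motor_id`,
#'   `rho` (target partial Spearman magnitude, in \[0, 1)).
#' @slot ageEffectCog,ageEffectMotor Standardized slope per decade of age on
#'   the latent (higher-is-better) scale of each block.
#' @slot genderEffect Standardized latent mean shift for gender code 1.
#' @slot outlierContamination Fraction of data cells whose residual component
#'   is displaced.
#' @slot outlierMagnitude Displacement size in residual standard deviations
#'   (default 6).
#' @slot nDegenerateVars Number of near-constant variables appended to the
#'   motor block.
#' @slot degenerateProp Fraction of identical values in a degenerate variable
#'   (in (0, 1\]).
#' @slot missingFraction Fraction of cells set missing completely at random.
#' @slot seed Integer seed making generation deterministic.
#' @export
setClass("GeneratorConfig",
  slots = c(
    nSubjects = "integer",
    ageRange = "numeric",
    ageMean = "numeric",
    ageSD = "numeric",
    propFemale = "numeric",
    inventory = "data.frame",
    plantedLinks = "data.frame",
    ageEffectCog = "numeric",
    ageEffectMotor = "numeric",
    genderEffect = "numeric",
    outlierContamination = "numeric",
    outlierMagnitude = "numeric",
    nDegenerateVars = "integer",
    degenerateProp = "numeric",
    missingFraction = "numeric",
    seed = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  errs <- character(0)
  inv <- object@inventory
  if (!.isCount(object@nSubjects) || object@nSubjects < 10L) {
    errs <- c(errs, "nSubjects: must be a count >= 10")
  }
  if (length(object@ageRange) != 2L || !all(is.finite(object@ageRange)) ||
      object@ageRange[1] >= object@ageRange[2]) {
    errs <- c(errs, "ageRange: must be (low, high) with low < high")
  }
  if (!.isProb(object@propFemale)) {
    errs <- c(errs, "propFemale: must lie in [0, 1]")
  }
  need <- c("variable_id", "block", "domain", "direction", "mean", "sd",
            "distortion")
  if (!all(need %in% names(inv))) {
    errs <- c(errs, paste0("inventory: missing column(s) ",
                           paste(setdiff(need, names(inv)), collapse = ", ")))
  } else {
    if (anyDuplicated(inv$variable_id)) {
      errs <- c(errs, "inventory: duplicated variable_id")
    }
    if (!all(inv$block %in% .BLOCKS)) {
      errs <- c(errs, "inventory: block must be 'cognitive' or 'motor'")
    }
    if (!all(inv$direction %in% c("higher", "lower"))) {
      errs <- c(errs, "inventory: direction must be 'higher' or 'lower'")
    }
    if (!all(inv$distortion %in% .DISTORTIONS)) {
      errs <- c(errs, paste0("inventory: distortion must be one of ",
                             paste(.DISTORTIONS, collapse = ", ")))
    }
    pl <- object@plantedLinks
    if (nrow(pl)) {
      if (!all(c("cognitive_id", "motor_id", "rho") %in% names(pl))) {
        errs <- c(errs,
                  "plantedLinks: needs columns cognitive_id, motor_id, rho")
      } else {
        cog <- inv$variable_id[inv$block == "cognitive"]
        mot <- inv$variable_id[inv$block == "motor"]
        if (!all(pl$cognitive_id %in% cog) || !all(pl$motor_id %in% mot)) {
          errs <- c(errs, "plantedLinks: ids must reference declared cognitive/motor variables")
        }
        if (!all(pl$rho >= 0 & pl$rho < 1)) {
          errs <- c(errs, "plantedLinks: rho magnitudes must lie in [0, 1)")
        } else {
          # each variable's summed latent-factor loadings must leave residual
          # variance strictly positive
          load <- c(tapply(.spearmanToPearson(pl$rho), pl$cognitive_id, sum),
                    tapply(.spearmanToPearson(pl$rho), pl$motor_id, sum))
          if (any(load >= 1)) {
            errs <- c(errs, "plantedLinks: summed link strength per variable must stay below 1")
          }
        }
      }
    }
  }
  if (!.isProb(object@outlierContamination, open.upper = TRUE)) {
    errs <- c(errs, "outlierContamination: must lie in [0, 1)")
  }
  if (!is.finite(object@outlierMagnitude) || object@outlierMagnitude <= 0) {
    errs <- c(errs, "outlierMagnitude: must be positive")
  }
  if (!.isCount(object@nDegenerateVars)) {
    errs <- c(errs, "nDegenerateVars: must be a count")
  }
  if (!.isProb(object@degenerateProp, open.lower = TRUE)) {
    errs <- c(errs, "degenerateProp: must lie in (0, 1]")
  }
  if (!.isProb(object@missingFraction, open.upper = TRUE)) {
    errs <- c(errs, "missingFraction: must lie in [0, 1)")
  }
  if (length(errs)) paste(errs, collapse = "; ") else TRUE
})

#' Ground truth emitted alongside a synthetic cohort
#'
#' Records what the generator planted so downstream discoveries can be
#' scored: the cross-block links, the cells whose residuals were displaced,
#' and the near-constant variables.
#'
#' @slot plantedLinks `data.frame` (`cognitive_id`, `motor_id`, `rho`,
#'   `expected_sign` on the observed scale).
#' @slot injectedOutliers `data.frame` (`subject_id`, `variable_id`).
#' @slot degenerateVariables Character vector of variable ids.
#' @export
setClass("TruthSet",
  slots = c(
    plantedLinks = "data.frame",
    injectedOutliers = "data.frame",
    degenerateVariables = "character"
  )
)

#' Container for a cohort of cognitive and mobility measurements
#'
#' A thin extension of \linkS4class{SummarizedExperiment}: the single assay
#' `"values"` holds the variables-by-subjects numeric matrix, `rowData`
#' carries the per-variable metadata (`variable_id`, `block`, `domain`,
#' `direction`, `transform` override) and `colData` the per-subject
#' adjustment covariates (`subject_id`, `age`, `gender`). Cohorts produced by
#' [simulateCohort()] additionally carry a \linkS4class{TruthSet} and their
#' \linkS4class{GeneratorConfig} in `metadata()`.
#'
#' @export
setClass("CohortExperiment", contains = "SummarizedExperiment")

setValidity("CohortExperiment", function(object) {
  errs <- character(0)
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("variable_id", "block", "domain", "direction") %in% names(rd))) {
    errs <- c(errs, "rowData must contain variable_id, block, domain, direction")
  } else {
    if (!all(rd$block %in% .BLOCKS)) {
      errs <- c(errs, "rowData$block must be 'cognitive' or 'motor'")
    }
    if (anyDuplicated(rd$variable_id)) {
      errs <- c(errs, "rowData$variable_id must be unique")
    }
  }
  if (!all(c("age", "gender") %in% names(cd))) {
    errs <- c(errs, "colData must contain age and gender")
  } else {
    if (!is.numeric(cd$age)) errs <- c(errs, "colData$age must be numeric")
    g <- cd$gender
    if (!all(is.na(g) | g %in% c(0, 1))) {
      errs <- c(errs, "colData$gender must be coded 0/1")
    }
  }
  if (!"values" %in% SummarizedExperiment::assayNames(object)) {
    errs <- c(errs, "assay 'values' is required")
  }
  if (length(errs)) paste(errs, collapse = "; ") else TRUE
})

#' Tuning parameters of the two-stage analysis pipeline
#'
#' @slot screeningAlpha Simes screening level; a family is selected when its
#'   Simes p-value is strictly smaller (default 0.05).
#' @slot bhQ Within-family Benjamini-Hochberg FDR level; rejection when the
#'   adjusted p-value is less than or equal to it (default 0.05).
#' @slot outlierCutoffNumerator Numerator c of the Bonferroni outlier cutoff
#'   c/n (default 4).
#' @slot rangeFilterThreshold Modal-proportion threshold at or above which a
#'   variable is excluded (default 0.80).
#' @slot selectionAdjustedBH If `TRUE`, the within-family BH level is scaled
#'   by (#selected families / #families), the selection-adjusted variant;
#'   default `FALSE` (plain within-family BH).
#' @slot transformSelection `"auto"` to pick each variable's transformation
#'   from the catalog by normality score, `"none"` to keep raw values
#'   (per-variable overrides in `rowData$transform` are always honoured).
#' @export
setClass("PipelineConfig",
  slots = c(
    screeningAlpha = "numeric",
    bhQ = "numeric",
    outlierCutoffNumerator = "numeric",
    rangeFilterThreshold = "numeric",
    selectionAdjustedBH = "logical",
    transformSelection = "character"
  )
)

setValidity("PipelineConfig", function(object) {
  errs <- character(0)
  if (!.isProb(object@screeningAlpha, TRUE, TRUE)) {
    errs <- c(errs, "screeningAlpha: must lie in (0, 1)")
  }
  if (!.isProb(object@bhQ, TRUE, TRUE)) {
    errs <- c(errs, "bhQ: must lie in (0, 1)")
  }
  if (!is.finite(object@outlierCutoffNumerator) ||
      object@outlierCutoffNumerator < 1) {
    errs <- c(errs, "outlierCutoffNumerator: must be >= 1")
  }
  if (!.isProb(object@rangeFilterThreshold, TRUE, FALSE)) {
    errs <- c(errs, "rangeFilterThreshold: must lie in (0, 1]")
  }
  if (!object@transformSelection %in% c("auto", "none")) {
    errs <- c(errs, "transformSelection: must be 'auto' or 'none'")
  }
  if (length(errs)) paste(errs, collapse = "; ") else TRUE
})

#' Result of the two-stage association analysis
#'
#' Produced by [runPipeline()]. The `associations` slot is the headline
#' report (one row per rejected correlation inside a selected family); the
#' logs retain every family's Simes p-value and every member's raw and
#' adjusted p-values, together with the preprocessing reports, so a run is
#' fully auditable.
#'
#' @slot associations Selected associations (`cognitive_domain`,
#'   `cognitive_id`, `motor_domain`, `motor_id`, `rho`, `p`, `adjusted_p`,
#'   `n_used`).
#' @slot familyLog One row per hypothesis family (`family_id`, `motor_id`,
#'   `motor_domain`, `cognitive_domain`, `m`, `simes_p`, `selected`).
#' @slot memberLog All correlations with family keys and adjusted p-values
#'   (`NA` where the family was not selected).
#' @slot exclusions Limited-range filter report (all variables).
#' @slot outliers Flagged cells (`variable_id`, `subject_id`,
#'   `studentized_residual`, `bonferroni_p`, `cutoff_used`).
#' @slot transforms Chosen transformation per variable.
#' @slot config The \linkS4class{PipelineConfig} used.
#' @slot effectiveQ The within-family rejection threshold actually applied.
#' @slot nSubjects Number of subjects analysed.
#' @export
setClass("AssociationReport",
  slots = c(
    associations = "data.frame",
    familyLog = "data.frame",
    memberLog = "data.frame",
    exclusions = "data.frame",
    outliers = "data.frame",
    transforms = "data.frame",
    config = "PipelineConfig",
    effectiveQ = "numeric",
    nSubjects = "integer"
  )
)

setValidity("AssociationReport", function(object) {
  a <- object@associations
  if (nrow(a)) {
    if (any(a$adjusted_p > object@effectiveQ + 1e-12)) {
      return("all reported rows must satisfy adjusted_p <= effective BH level")
    }
    key <- paste(a$motor_id, a$cognitive_domain)
    fl <- object@familyLog
    sel <- paste(fl$motor_id, fl$cognitive_domain)[fl$selected]
    if (!all(key %in% sel)) {
      return("all reported rows must belong to a selected family")
    }
  }
  TRUE
})

#' Monte-Carlo operating characteristics of the pipeline
#'
#' Produced by [estimateOperatingCharacteristics()]. All rates lie in
#' \[0, 1\]; `monteCarloSE` holds sqrt(r (1 - r) / nReplicates) for each
#' rate r.
#'
#' @slot nReplicates Number of replicates.
#' @slot familySelectionRate Fraction of (family, replicate) pairs selected
#'   at the screening stage.
#' @slot perFamilyRate Per-family selection rates.
#' @slot empiricalFdr Mean per-replicate false discovery proportion among
#'   all reported pairs (replicates without rejections contribute 0).
#' @slot withinFamilyFdr Mean (over replicates and selected families) of the
#'   within-family false discovery proportion.
#' @slot power Mean fraction of planted links reported (NA when no links).
#' @slot completeRecoveryRate Fraction of replicates reporting every planted
#'   link.
#' @slot exactRecoveryRate Fraction of replicates whose report equals the
#'   planted set exactly.
#' @slot noRejectionFraction Fraction of replicates with an empty report.
#' @slot monteCarloSE Named numeric vector of binomial standard errors.
#' @export
setClass("OperatingCharacteristics",
  slots = c(
    nReplicates = "integer",
    familySelectionRate = "numeric",
    perFamilyRate = "data.frame",
    empiricalFdr = "numeric",
    withinFamilyFdr = "numeric",
    power = "numeric",
    completeRecoveryRate = "numeric",
    exactRecoveryRate = "numeric",
    noRejectionFraction = "numeric",
    monteCarloSE = "numeric"
  )
)

setValidity("OperatingCharacteristics", function(object) {
  rates <- c(object@familySelectionRate, object@empiricalFdr,
             object@withinFamilyFdr, object@noRejectionFraction)
  rates <- rates[!is.na(rates)]
  if (length(rates) && any(rates < 0 | rates > 1)) {
    return("all rates must lie in [0, 1]")
  }
  TRUE
})
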