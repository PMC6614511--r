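#' @include AllClasses.R
NULL

#' Default cognitive/mobility variable inventory
#'
#' The built-in inventory of 30 cognitive variables (four domains: executive,
#' speed, memory, language) and 21 mobility variables (six domains:
#' variability, transition, turn, asymmetry, rhythm, pace) with the published
#' scale (mean, SD), a direction tag (whether higher values reflect better
#' performance) and a marginal-distortion tag used by the generator to mimic
#' non-Gaussian score distributions.
#'
#' @return A `data.frame` with columns `variable_id`, `label`, `block`,
#'   `domain`, `direction`, `mean`, `sd`, `distortion`.
#' @examples
#' inv <- defaultVariableInventory()
#' table(inv$block, inv$domain)
#' @export
defaultVariableInventory <- function() {
  path <- system.file("extdata", "variable_inventory.csv", package = "cogmob",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.synthInventory <- function(domains, block) {
  do.call(rbind, lapply(names(domains), function(d) {
    k <- domains[[d]]
    data.frame(
      variable_id = paste0(d, "_", seq_len(k)),
      label = paste0(d, " variable ", seq_len(k)),
      block = block,
      domain = d,
      direction = "higher",
      mean = NA_real_,
      sd = NA_real_,
      distortion = "identity",
      stringsAsFactors = FALSE
    )
  }))
}

.defaultPlantedLinks <- function() {
  data.frame(
    cognitive_id = c("waisr_vocabulary", "waisr_ds", "paper_folding"),
    motor_id = c("dt_stride_length", "dt_step_regularity",
                 "turn_yaw_duration"),
    rho = c(0.35, 0.30, 0.30),
    stringsAsFactors = FALSE
  )
}

#' Configure the synthetic cohort generator
#'
#' With all arguments at their defaults the generator emulates the reference
#' study conditions: 124 subjects aged 27-80 (mean 61.51, SD 11.90), 56.5%
#' female, the full default variable inventory on its published scales, mild
#' age/gender confounding of both blocks, three planted cross-block links of
#' modest strength, 1% outlier contamination and one near-constant variable.
#'
#' @param nSubjects Cohort size (>= 10).
#' @param ageRange,ageMean,ageSD Truncated-Gaussian age model (years).
#' @param propFemale Fraction of subjects coded gender = 1 (female).
#' @param cognitiveDomains,motorDomains Either `NULL` (use
#'   [defaultVariableInventory()]) or named integer vectors mapping domain
#'   name to number of variables, e.g. `c(executive = 3)`. Supplying either
#'   switches to a synthetic inventory on the latent scale.
#' @param plantedLinks `data.frame` with columns `cognitive_id`, `motor_id`,
#'   `rho`: the target partial Spearman correlation (given age and gender)
#'   of each planted pair, on the latent higher-is-better scale. `NULL`
#'   means three default links for the default inventory and none for a
#'   custom one.
#' @param marginalDistortions Named character vector mapping variable ids to
#'   a distortion tag (`identity`, `exponential`, `heavy-tail`, `bounded`);
#'   overrides the inventory. All distortions are strictly increasing, so
#'   rank-based statistics are unaffected.
#' @param ageEffectCog,ageEffectMotor Standardized latent slope per decade of
#'   age for each block (negative: older subjects perform worse).
#' @param genderEffect Standardized latent shift for gender = 1.
#' @param outlierContamination Fraction of cells whose residual component is
#'   displaced by `outlierMagnitude` residual standard deviations.
#' @param outlierMagnitude Displacement size (default 6 SD).
#' @param nDegenerateVars Near-constant variables appended to the motor
#'   block (default 1 for the default inventory, 0 for custom inventories).
#' @param degenerateProp Fraction of identical values in each degenerate
#'   variable; exactly `round(degenerateProp * nSubjects)` cells share the
#'   modal value.
#' @param missingFraction Fraction of cells dropped completely at random
#'   (default 0: complete data).
#' @param seed Integer seed used by [simulateCohort()].
#' @return A validated \linkS4class{GeneratorConfig}.
#' @examples
#' cfg <- generatorConfig(nSubjects = 60,
#'                        cognitiveDomains = c(executive = 3),
#'                        motorDomains = c(pace = 2),
#'                        plantedLinks = data.frame(
#'                          cognitive_id = "executive_1",
#'                          motor_id = "pace_1", rho = 0.5))
#' @export
generatorConfig <- function(nSubjects = 124,
                            ageRange = c(27, 80),
                            ageMean = 61.51,
                            ageSD = 11.90,
                            propFemale = 0.565,
                            cognitiveDomains = NULL,
                            motorDomains = NULL,
                            plantedLinks = NULL,
                            marginalDistortions = NULL,
                            ageEffectCog = -0.35,
                            ageEffectMotor = -0.30,
                            genderEffect = 0.2,
                            outlierContamination = 0.01,
                            outlierMagnitude = 6,
                            nDegenerateVars = NULL,
                            degenerateProp = 0.85,
                            missingFraction = 0,
                            seed = 1L) {
  custom <- !is.null(cognitiveDomains) || !is.null(motorDomains)
  if (custom) {
    if (is.null(cognitiveDomains) || is.null(motorDomains)) {
      stop("configuration error: cognitiveDomains and motorDomains must be ",
           "supplied together")
    }
    inv <- rbind(.synthInventory(cognitiveDomains, "cognitive"),
                 .synthInventory(motorDomains, "motor"))
    if (is.null(plantedLinks)) {
      plantedLinks <- data.frame(cognitive_id = character(0),
                                 motor_id = character(0), rho = numeric(0))
    }
    if (is.null(nDegenerateVars)) nDegenerateVars <- 0L
  } else {
    inv <- defaultVariableInventory()
    if (is.null(plantedLinks)) plantedLinks <- .defaultPlantedLinks()
    if (is.null(nDegenerateVars)) nDegenerateVars <- 1L
  }
  if (!is.null(marginalDistortions)) {
    bad <- setdiff(names(marginalDistortions), inv$variable_id)
    if (length(bad)) {
      stop("configuration error: marginalDistortions names unknown: ",
           paste(bad, collapse = ", "))
    }
    inv$distortion[match(names(marginalDistortions), inv$variable_id)] <-
      unname(marginalDistortions)
  }
  obj <- methods::new(
    "GeneratorConfig",
    nSubjects = as.integer(nSubjects),
    ageRange = as.numeric(ageRange),
    ageMean = as.numeric(ageMean),
    ageSD = as.numeric(ageSD),
    propFemale = as.numeric(propFemale),
    inventory = inv,
    plantedLinks = as.data.frame(plantedLinks),
    ageEffectCog = as.numeric(ageEffectCog),
    ageEffectMotor = as.numeric(ageEffectMotor),
    genderEffect = as.numeric(genderEffect),
    outlierContamination = as.numeric(outlierContamination),
    outlierMagnitude = as.numeric(outlierMagnitude),
    nDegenerateVars = as.integer(nDegenerateVars),
    degenerateProp = as.numeric(degenerateProp),
    missingFraction = as.numeric(missingFraction),
    seed = as.integer(seed)
  )
  methods::validObject(obj)
  obj
}

#' Preset generator configurations used in validation studies
#'
#' Three fixed scenarios exercising the pipeline's operating
#' characteristics:
#' \describe{
#'   \item{`"null"`}{124 subjects, one cognitive domain (3 executive
#'     variables) by 3 pace variables, no planted links: every hypothesis
#'     family is null, for checking the Simes screening level.}
#'   \item{`"signal"`}{500 subjects, one cognitive domain (2 executive
#'     variables) by 2 pace variables with one 0.5 link per motor variable:
#'     both families carry a strong member and are selected with probability
#'     near 1, the regime in which within-family BH controls the FDR of the
#'     report.}
#'   \item{`"power"`}{500 subjects, executive (3) and language (2) domains by
#'     3 pace variables, three 0.5 links pairing each pace variable with one
#'     executive variable; the language families are pure null. Used to
#'     measure recovery of the planted pairs.}
#' }
#' All three keep the generator defaults for contamination (1%) and include
#' non-Gaussian marginals on some variables; signal strengths are on the
#' partial Spearman scale.
#'
#' @param scenario One of `"null"`, `"signal"`, `"power"`.
#' @param nSubjects Optional override of the scenario's cohort size.
#' @param seed Integer seed stored in the configuration.
#' @return A \linkS4class{GeneratorConfig}.
#' @examples
#' scenarioConfig("signal")
#' @export
scenarioConfig <- function(scenario = c("null", "signal", "power"),
                           nSubjects = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  switch(scenario,
    null = generatorConfig(
      nSubjects = if (is.null(nSubjects)) 124 else nSubjects,
      cognitiveDomains = c(executive = 3L),
      motorDomains = c(pace = 3L),
      marginalDistortions = c(pace_1 = "exponential",
                              executive_1 = "bounded"),
      seed = seed
    ),
    signal = generatorConfig(
      nSubjects = if (is.null(nSubjects)) 500 else nSubjects,
      cognitiveDomains = c(executive = 2L),
      motorDomains = c(pace = 2L),
      plantedLinks = data.frame(
        cognitive_id = c("executive_1", "executive_2"),
        motor_id = c("pace_1", "pace_2"),
        rho = c(0.5, 0.5)
      ),
      marginalDistortions = c(pace_1 = "exponential",
                              executive_1 = "bounded"),
      seed = seed
    ),
    power = generatorConfig(
      nSubjects = if (is.null(nSubjects)) 500 else nSubjects,
      cognitiveDomains = c(executive = 3L, language = 2L),
      motorDomains = c(pace = 3L),
      plantedLinks = data.frame(
        cognitive_id = c("executive_1", "executive_2", "executive_3"),
        motor_id = c("pace_1", "pace_2", "pace_3"),
        rho = c(0.5, 0.5, 0.5)
      ),
      marginalDistortions = c(pace_1 = "exponential",
                              executive_1 = "bounded"),
      seed = seed
    )
  )
}

.distort <- function(x, tag) {
  switch(tag,
    identity = x,
    exponential = exp(x),
    `heavy-tail` = stats::qt(pmin(pmax(stats::pnorm(x), 1e-12), 1 - 1e-12),
                             df = 3),
    bounded = stats::plogis(x),
    stop("configuration error: unknown distortion tag '", tag, "'")
  )
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws ages from a truncated Gaussian and gender from a Bernoulli, builds a
#' latent higher-is-better score per variable as (age effect) + (gender
#' effect) + residual, induces each planted cross-block link through a shared
#' standardized latent factor whose loadings are calibrated (via Greiner's
#' relation) so the population partial Spearman correlation given age and
#' gender equals the configured value, then flips lower-is-better variables,
#' applies strictly increasing marginal distortions, rescales inventory
#' variables to their published mean/SD, displaces contaminated cells'
#' residuals by at least `outlierMagnitude` residual SD, appends near-constant
#' variables and optionally masks cells at random. Non-planted cross-block
#' pairs are conditionally independent given the covariates.
#'
#' Generation is fully determined by the seed: identical configurations and
#' seeds give bit-identical cohorts.
#'
#' @param config A \linkS4class{GeneratorConfig}.
#' @param seed Optional seed overriding `config@seed`.
#' @return A \linkS4class{CohortExperiment} whose `metadata()` holds the
#'   \linkS4class{TruthSet} and the configuration.
#' @examples
#' ce <- simulateCohort(scenarioConfig("signal", nSubjects = 50))
#' ce
#' truthSet(ce)
#' @export
simulateCohort <- function(config, seed = NULL) {
  methods::validObject(config)
  if (is.null(seed)) seed <- config@seed
  .withSeed(seed, function() .generateCohort(config))
}

.generateCohort <- function(config) {
  n <- config@nSubjects
  inv <- config@inventory
  V <- nrow(inv)
  subjectId <- sprintf("S%0*d", nchar(as.character(n)), seq_len(n))

  age <- numeric(0)
  while (length(age) < n) {
    draw <- stats::rnorm(n, config@ageMean, config@ageSD)
    age <- c(age,
             draw[draw >= config@ageRange[1] & draw <= config@ageRange[2]])
  }
  age <- round(age[seq_len(n)], 1)
  gender <- stats::rbinom(n, 1L, config@propFemale)
  ageZ <- (age - config@ageMean) / 10

  pl <- config@plantedLinks
  L <- nrow(pl)
  Z <- if (L) matrix(stats::rnorm(n * L), n, L) else matrix(0, n, 0)
  loading <- if (L) sqrt(.spearmanToPearson(pl$rho)) else numeric(0)

  # standardized residual component per variable; planted links share factors
  E <- matrix(NA_real_, n, V)
  for (v in seq_len(V)) {
    id <- inv$variable_id[v]
    ls <- if (L) which(pl$cognitive_id == id | pl$motor_id == id) else
      integer(0)
    lam <- loading[ls]
    E[, v] <- drop(Z[, ls, drop = FALSE] %*% lam) +
      sqrt(max(0, 1 - sum(lam^2))) * stats::rnorm(n)
  }

  # residual displacement: contaminated cells become >= magnitude residual SD
  nOut <- round(config@outlierContamination * n * V)
  outCells <- integer(0)
  if (nOut > 0) {
    outCells <- sample.int(n * V, nOut)
    E[outCells] <- sample(c(-1, 1), nOut, replace = TRUE) *
      config@outlierMagnitude
  }

  beta <- ifelse(inv$block == "cognitive", config@ageEffectCog,
                 config@ageEffectMotor)
  X <- matrix(NA_real_, n, V)
  for (v in seq_len(V)) {
    x <- beta[v] * ageZ + config@genderEffect * gender + E[, v]
    if (inv$direction[v] == "lower") x <- -x
    d <- .distort(x, inv$distortion[v])
    if (!is.na(inv$mean[v]) && !is.na(inv$sd[v])) {
      s <- stats::sd(d)
      if (s > 0) d <- inv$mean[v] + inv$sd[v] * (d - mean(d)) / s
    }
    X[, v] <- d
  }

  # degenerate (near-constant) variables appended to the motor block
  D <- config@nDegenerateVars
  degIds <- character(0)
  if (D > 0) {
    motorDomain <- inv$domain[inv$block == "motor"][1]
    if (is.na(motorDomain)) motorDomain <- .MOTOR_DOMAINS[1]
    degIds <- paste0("degenerate_", seq_len(D))
    k <- round(config@degenerateProp * n)
    degCols <- matrix(NA_real_, n, D)
    for (j in seq_len(D)) {
      vals <- numeric(n)
      modal <- sample.int(n, k)
      vals[-modal] <- sample(seq_len(n - k))
      degCols[, j] <- vals
    }
    X <- cbind(X, degCols)
    inv <- rbind(inv, data.frame(
      variable_id = degIds, label = degIds, block = "motor",
      domain = motorDomain, direction = "higher",
      mean = NA_real_, sd = NA_real_, distortion = "identity",
      stringsAsFactors = FALSE
    ))
  }
  colnames(X) <- inv$variable_id

  if (config@missingFraction > 0) {
    drop <- sample.int(length(X), round(config@missingFraction * length(X)))
    X[drop] <- NA_real_
  }

  dirSign <- ifelse(inv$direction == "higher", 1L, -1L)
  names(dirSign) <- inv$variable_id
  truthLinks <- pl
  if (L) {
    truthLinks$expected_sign <- dirSign[pl$cognitive_id] *
      dirSign[pl$motor_id] * ifelse(pl$rho > 0, 1L, 0L)
  } else {
    truthLinks <- data.frame(cognitive_id = character(0),
                             motor_id = character(0), rho = numeric(0),
                             expected_sign = integer(0))
  }
  outTruth <- if (length(outCells)) {
    data.frame(subject_id = subjectId[(outCells - 1L) %% n + 1L],
               variable_id = inv$variable_id[(outCells - 1L) %/% n + 1L],
               stringsAsFactors = FALSE)
  } else {
    data.frame(subject_id = character(0), variable_id = character(0))
  }
  truth <- methods::new("TruthSet",
                        plantedLinks = truthLinks,
                        injectedOutliers = outTruth,
                        degenerateVariables = degIds)

  meta <- data.frame(variable_id = inv$variable_id, block = inv$block,
                     domain = inv$domain, direction = inv$direction,
                     transform = NA_character_, stringsAsFactors = FALSE)
  cov <- data.frame(subject_id = subjectId, age = age, gender = gender,
                    stringsAsFactors = FALSE)
  CohortExperiment(t(X), meta, cov, truth = truth, generatorConfig = config)
}

#' Summarize a cohort
#'
#' Per-variable mean, SD, minimum and maximum over non-missing values, plus
#' covariate summaries, in the layout of a demographics/measures table. With
#' a single subject the SD is reported as missing.
#'
#' @param x A \linkS4class{CohortExperiment}.
#' @return A list with elements `variables` and `covariates`, both
#'   `data.frame`s.
#' @examples
#' ce <- simulateCohort(scenarioConfig("null", nSubjects = 40))
#' describeCohort(ce)$covariates
#' @export
describeCohort <- function(x) {
  vals <- cohortValues(x)
  if (length(vals) == 0L) stop("input error: empty cohort table")
  meta <- variableMeta(x)
  stat <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(n = 0, mean = NA, sd = NA, min = NA, max = NA))
    c(n = length(v), mean = mean(v),
      sd = if (length(v) > 1) stats::sd(v) else NA_real_,
      min = min(v), max = max(v))
  }
  vs <- t(apply(vals, 1, stat))
  variables <- data.frame(variable_id = meta$variable_id,
                          block = meta$block, domain = meta$domain,
                          vs, row.names = NULL)
  cov <- covariateData(x)
  covariates <- data.frame(
    covariate = c("age", "gender (prop. coded 1)"),
    mean = c(mean(cov$age, na.rm = TRUE), mean(cov$gender, na.rm = TRUE)),
    sd = c(if (nrow(cov) > 1) stats::sd(cov$age) else NA_real_, NA_real_),
    min = c(min(cov$age, na.rm = TRUE), NA_real_),
    max = c(max(cov$age, na.rm = TRUE), NA_real_)
  )
  list(variables = variables, covariates = covariates)
}
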