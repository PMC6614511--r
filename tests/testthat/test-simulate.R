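test_that("invalid generator configurations name the offending field", {
  expect_error(generatorConfig(nSubjects = 5), "nSubjects")
  expect_error(generatorConfig(degenerateProp = 0), "degenerateProp")
  expect_error(generatorConfig(propFemale = 1.5), "propFemale")
  expect_error(generatorConfig(outlierContamination = 1), "outlierContamination")
  expect_error(
    generatorConfig(plantedLinks = data.frame(cognitive_id = "nope",
                                              motor_id = "tug_duration",
                                              rho = 0.3)),
    "plantedLinks")
  expect_error(
    generatorConfig(plantedLinks = data.frame(cognitive_id = "wtar",
                                              motor_id = "tug_duration",
                                              rho = 1)),
    "plantedLinks")
})

test_that("generation is bit-identical given a seed and differs across
           seeds", {
  cfg <- scenarioConfig("signal", nSubjects = 60)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(cohortValues(a), cohortValues(b))
  expect_identical(covariateData(a), covariateData(b))
  expect_identical(truthSet(a)@plantedLinks, truthSet(b)@plantedLinks)
  c <- simulateCohort(cfg, seed = 2026)
  expect_false(identical(cohortValues(a), cohortValues(c)))
  # identical truth structure regardless of the seed
  expect_identical(truthSet(a)@plantedLinks[, c("cognitive_id", "motor_id")],
                   truthSet(c)@plantedLinks[, c("cognitive_id", "motor_id")])
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(11)
  before <- runif(1)
  set.seed(11)
  invisible(simulateCohort(scenarioConfig("null", nSubjects = 30)))
  expect_identical(runif(1), before)
})

test_that("degenerate variables have exactly round(prop * n) identical
           values", {
  ce <- simulateCohort(generatorConfig(degenerateProp = 0.8, seed = 5))
  v <- cohortValues(ce)["degenerate_1", ]
  expect_equal(max(table(v)), round(0.8 * 124)) # 99
  ce2 <- simulateCohort(generatorConfig(seed = 5)) # default 0.85
  v2 <- cohortValues(ce2)["degenerate_1", ]
  expect_equal(max(table(v2)), round(0.85 * 124))
  expect_equal(truthSet(ce2)@degenerateVariables, "degenerate_1")
})

test_that("marginal distortions are monotone: ranks are unchanged", {
  base <- generatorConfig(nSubjects = 80,
                          cognitiveDomains = c(executive = 2),
                          motorDomains = c(pace = 2),
                          outlierContamination = 0, seed = 21)
  dist <- generatorConfig(nSubjects = 80,
                          cognitiveDomains = c(executive = 2),
                          motorDomains = c(pace = 2),
                          marginalDistortions = c(pace_1 = "exponential",
                                                  pace_2 = "heavy-tail",
                                                  executive_1 = "bounded"),
                          outlierContamination = 0, seed = 21)
  a <- cohortValues(simulateCohort(base))
  b <- cohortValues(simulateCohort(dist))
  for (v in rownames(a)) {
    expect_equal(rank(b[v, ]), rank(a[v, ]), info = v)
  }
})

test_that("with no planted links, cross-block partial rank correlations are
           null", {
  cfg <- generatorConfig(nSubjects = 400,
                         cognitiveDomains = c(executive = 3),
                         motorDomains = c(pace = 3),
                         outlierContamination = 0, seed = 31)
  ce <- simulateCohort(cfg)
  vals <- cohortValues(ce)
  cov <- covariateData(ce)[, c("age", "gender")]
  rhos <- sapply(paste0("executive_", 1:3), function(ci) {
    sapply(paste0("pace_", 1:3), function(mi) {
      partialSpearmanOracle(vals[ci, ], vals[mi, ], cov)
    })
  })
  expect_lt(mean(abs(rhos)), 3 / sqrt(400))
})

test_that("a planted link's partial Spearman matches its configured
           magnitude at large n", {
  cfg <- generatorConfig(nSubjects = 2000,
                         cognitiveDomains = c(executive = 2),
                         motorDomains = c(pace = 2),
                         plantedLinks = data.frame(cognitive_id = "executive_1",
                                                   motor_id = "pace_1",
                                                   rho = 0.5),
                         marginalDistortions = c(pace_1 = "exponential"),
                         outlierContamination = 0, seed = 32)
  vals <- cohortValues(simulateCohort(cfg))
  cov <- covariateData(simulateCohort(cfg))[, c("age", "gender")]
  est <- partialSpearmanOracle(vals["executive_1", ], vals["pace_1", ], cov)
  expect_lt(abs(est - 0.5), 0.06)
  null <- partialSpearmanOracle(vals["executive_2", ], vals["pace_2", ], cov)
  expect_lt(abs(null), 0.06)
})

test_that("injected outliers are displaced far enough to be detectable", {
  cfg <- generatorConfig(nSubjects = 124,
                         cognitiveDomains = c(executive = 3),
                         motorDomains = c(pace = 3),
                         outlierContamination = 0.02, seed = 33)
  ce <- simulateCohort(cfg)
  truth <- truthSet(ce)
  expect_equal(nrow(truth@injectedOutliers), round(0.02 * 124 * 6))
  vals <- cohortValues(ce)
  cov <- covariateData(ce)
  inj <- truth@injectedOutliers
  hit <- vapply(seq_len(nrow(inj)), function(i) {
    rep <- detectOutliers(vals[inj$variable_id[i], ], cov)
    inj$subject_id[i] %in% rep$subject_id
  }, logical(1))
  # several injections in one variable can mask each other; in variables
  # with at most two, every injected outlier must be caught
  perVar <- table(inj$variable_id)
  sparse <- perVar[inj$variable_id] <= 2
  expect_true(all(hit[sparse]))
  expect_gte(mean(hit), 2 / 3)
})

test_that("age and gender confound both blocks by construction", {
  cfg <- generatorConfig(nSubjects = 600,
                         cognitiveDomains = c(executive = 1),
                         motorDomains = c(pace = 1),
                         outlierContamination = 0, seed = 34)
  ce <- simulateCohort(cfg)
  vals <- cohortValues(ce)
  cov <- covariateData(ce)
  # no planted link, yet the raw correlation is positive through shared age
  raw <- cor(vals["executive_1", ], vals["pace_1", ], method = "spearman")
  adj <- partialSpearmanOracle(vals["executive_1", ], vals["pace_1", ],
                               cov[, c("age", "gender")])
  expect_gt(raw, 0.1)
  expect_lt(abs(adj), 0.1)
  expect_lt(cor(vals["executive_1", ], cov$age, method = "spearman"), 0)
})

test_that("cohort summaries handle degenerate shapes", {
  meta <- data.frame(variable_id = c("v1", "v2"), block = c("cognitive",
                                                            "motor"),
                     domain = c("executive", "pace"), direction = "higher")
  vals <- rbind(v1 = rep(4, 6), v2 = 1:6)
  cov <- data.frame(age = 40:45, gender = rep(0:1, 3))
  d <- describeCohort(CohortExperiment(vals, meta, cov))
  expect_equal(d$variables$sd[1], 0)
  expect_equal(d$variables$min[1], 4)
  expect_equal(d$variables$max[1], 4)
  one <- describeCohort(CohortExperiment(cbind(S1 = c(v1 = 2, v2 = 3)),
                                         meta,
                                         data.frame(age = 50, gender = 1)))
  expect_true(all(is.na(one$variables$sd)))
  # default cohort ages respect the configured range
  ce <- simulateCohort(generatorConfig(seed = 3))
  dd <- describeCohort(ce)
  expect_gte(dd$covariates$min[1], 27)
  expect_lte(dd$covariates$max[1], 80)
})
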