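test_that("perfect monotone association gives rho = 1 without covariates", {
  x <- c(0.3, 1.2, 2.5, 4.1, 9)
  res <- partialSpearman(x, exp(x))
  expect_equal(res$rho, 1)
  expect_equal(res$n_used, 5)
})

test_that("with no covariates the estimate equals the classical Spearman
           formula on tie-free data", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    x <- sample(n) + runif(n, 0, 0.001)
    y <- sample(n) + runif(n, 0, 0.001)
    res <- partialSpearman(x, y)
    expect_equal(res$rho, spearmanClassical(x, y), tolerance = 1e-12)
    expect_equal(res$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
})

test_that("the statistic is symmetric in its two arguments", {
  set.seed(102)
  cov <- makeCovariates(50)
  x <- rnorm(50) + cov$age / 20
  y <- rnorm(50)
  a <- partialSpearman(x, y, cov)
  b <- partialSpearman(y, x, cov)
  expect_equal(a$rho, b$rho)
  expect_equal(a$p_value, b$p_value)
})

test_that("rho is invariant under increasing transforms and negated under
           decreasing ones", {
  set.seed(103)
  cov <- makeCovariates(60)
  x <- rexp(60) + cov$age / 40
  y <- 0.5 * x + rnorm(60)
  base <- partialSpearman(x, y, cov)
  up <- partialSpearman(log(x + 1), y, cov)
  down <- partialSpearman(-x^3, y, cov)
  expect_equal(up$rho, base$rho, tolerance = 1e-12)
  expect_equal(down$rho, -base$rho, tolerance = 1e-12)
})

test_that("covariate adjustment removes confounded association", {
  set.seed(104)
  n <- 300
  cov <- makeCovariates(n)
  x <- cov$age / 10 + rnorm(n)
  y <- cov$age / 10 + rnorm(n)
  raw <- partialSpearman(x, y)$rho
  adj <- partialSpearman(x, y, cov)
  expect_gt(raw, 0.3)
  expect_lt(abs(adj$rho), 0.15)
  expect_equal(adj$df, n - 4)
})

test_that("degenerate inputs raise errors", {
  cov <- makeCovariates(20)
  expect_error(partialSpearman(rep(1, 20), rnorm(20), cov),
               "degenerate-correlation")
  expect_error(partialSpearman(rnorm(4), rnorm(4), makeCovariates(4)),
               "pairwise-complete")
})

test_that("p-values are uniform under conditional independence", {
  set.seed(105)
  p <- replicate(2000, {
    cov <- makeCovariates(60)
    x <- 0.3 * cov$age / 10 + rnorm(60)
    y <- -0.2 * cov$age / 10 + 0.3 * cov$gender + rnorm(60)
    partialSpearman(x, y, cov)$p_value
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.05)
})

test_that("the pair matrix covers every cognitive-motor pair with
           pairwise-complete cases", {
  set.seed(106)
  cfg <- generatorConfig(nSubjects = 40,
                         cognitiveDomains = c(executive = 2),
                         motorDomains = c(pace = 3),
                         outlierContamination = 0, seed = 41)
  ce <- simulateCohort(cfg)
  m <- associationMatrix(ce)
  expect_equal(nrow(m), 6)
  expect_setequal(unique(m$cognitive_id), c("executive_1", "executive_2"))
  # knock out cells in one variable only; other pairs keep their n
  vals <- cohortValues(ce)
  vals["pace_1", 1:10] <- NA
  ce2 <- CohortExperiment(vals, variableMeta(ce), covariateData(ce))
  m2 <- associationMatrix(ce2)
  expect_equal(unique(m2$n_used[m2$motor_id == "pace_1"]), 30)
  expect_equal(unique(m2$n_used[m2$motor_id != "pace_1"]), 40)
})

test_that("untestable pairs propagate p = 1 with a warning", {
  set.seed(107)
  cfg <- generatorConfig(nSubjects = 30,
                         cognitiveDomains = c(executive = 2),
                         motorDomains = c(pace = 1),
                         outlierContamination = 0, seed = 42)
  ce <- simulateCohort(cfg)
  vals <- cohortValues(ce)
  vals["executive_1", 5:30] <- NA # only 4 complete cases left
  ce2 <- CohortExperiment(vals, variableMeta(ce), covariateData(ce))
  expect_warning(m <- associationMatrix(ce2), "untestable")
  bad <- m[m$cognitive_id == "executive_1", ]
  expect_true(all(bad$untestable))
  expect_true(all(bad$p == 1))
  expect_true(all(is.na(bad$rho)))
})
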