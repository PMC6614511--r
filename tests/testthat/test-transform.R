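test_that("identity and order-reversal behave as specified", {
  x <- c(1, 2, 3)
  expect_equal(applyTransform(x, transformSpec("identity")), c(1, 2, 3))
  expect_equal(applyTransform(x, transformSpec("identity",
                                               orderReversing = TRUE)),
               c(-1, -2, -3))
  # the reciprocal is decreasing, so its default spec negates the output,
  # restoring the original ordering
  sp <- transformSpec("reciprocal")
  expect_true(sp$orderReversing)
  expect_equal(order(applyTransform(x, sp)), order(x))
})

test_that("overrides are applied verbatim and missing cells stay missing", {
  x <- c(5, NA, 7, 20)
  sp <- transformSpec("log-shift", shift = 2)
  out <- autoTransform(x, override = sp)
  expect_identical(out$spec, sp)
  expect_equal(out$values, log(x + 2))
  expect_true(is.na(out$values[2]))
  # a tag-only override picks its shift automatically
  out2 <- autoTransform(c(-1, 0, 3, 8), override = "log-shift")
  expect_equal(out2$spec$shift, 2) # 1 - min
  expect_true(all(is.finite(out2$values)))
})

test_that("log transform of a log-normal sample removes its skewness", {
  set.seed(71)
  x <- exp(rnorm(200))
  y <- applyTransform(x, transformSpec("log-shift", shift = 0))
  expect_lt(abs(sampleSkewness(y)), abs(sampleSkewness(x)) / 2)
})

test_that("transform-domain violations raise informative errors", {
  expect_error(applyTransform(c(-1, 2, 3), transformSpec("log-shift")),
               "transform-domain")
  expect_error(applyTransform(c(-4, 2), transformSpec("sqrt-shift")),
               "transform-domain")
  expect_error(applyTransform(c(0, 1), transformSpec("reciprocal",
                                                     shift = 0,
                                                     orderReversing = TRUE)),
               "transform-domain")
  expect_error(selectTransform(c(1, NA, NA)), "at least 3")
})

test_that("catalog transforms preserve (or exactly reverse) rank order", {
  set.seed(72)
  x <- c(rexp(40), NA, rexp(9))
  specs <- list(transformSpec("identity"),
                transformSpec("log-shift", shift = 1),
                transformSpec("sqrt-shift", shift = 1),
                transformSpec("reciprocal", shift = 1),
                transformSpec("box-cox", shift = 1, lambda = 0.5),
                transformSpec("box-cox", shift = 1, lambda = -1),
                transformSpec("rank-inverse-normal"))
  r0 <- rank(x, na.last = "keep")
  for (sp in specs) {
    y <- applyTransform(x, sp)
    expect_equal(rank(y, na.last = "keep"), r0, info = sp$name)
  }
  # without the negation, the raw reciprocal reverses ranks exactly
  raw <- 1 / (x + 1)
  expect_equal(rank(-raw, na.last = "keep"), r0)
})

test_that("automatic selection is deterministic and normality-driven", {
  set.seed(73)
  x <- rexp(150)
  s1 <- selectTransform(x)
  s2 <- selectTransform(x)
  expect_identical(s1[], s2[])
  tr <- autoTransform(x)
  w_raw <- shapiro.test(x)$statistic
  w_new <- shapiro.test(tr$values)$statistic
  expect_gte(unname(w_new), unname(w_raw))
})

test_that("Spearman correlations are invariant to monotone transforms and
           sign-flipped by order-reversing ones", {
  set.seed(74)
  for (i in 1:5) {
    x <- rexp(60)
    y <- 0.5 * x + rexp(60)
    rho0 <- cor(x, y, method = "spearman")
    tx <- autoTransform(x)$values
    expect_equal(cor(tx, y, method = "spearman"), rho0, tolerance = 1e-12)
    rev <- applyTransform(x, transformSpec("identity", orderReversing = TRUE))
    expect_equal(cor(rev, y, method = "spearman"), -rho0, tolerance = 1e-12)
  }
})
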