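test_that("Simes combination matches hand-computed examples", {
  # sorted: 0.01, 0.03, 0.04 -> min(3*.01/1, 3*.03/2, 3*.04/3) = 0.03
  expect_equal(simesPvalue(c(0.01, 0.04, 0.03)), 0.03)
  # a single p-value passes through unchanged
  expect_equal(simesPvalue(0.2), 0.2)
  # all ones cap at 1
  expect_equal(simesPvalue(rep(1, 5)), 1)
  # dominated by the smallest scaled order statistic
  expect_equal(simesPvalue(c(0.001, 0.9, 0.9, 0.9)), 0.004)
})

test_that("Simes agrees with the brute-force oracle over random instances", {
  set.seed(111)
  for (i in 1:1000) {
    m <- sample(1:6, 1)
    p <- runif(m)^sample(c(1, 3), 1) # mix of uniform and signal-like
    p[p == 0] <- 1e-12
    expect_equal(simesPvalue(p), simesBrute(p), tolerance = 1e-12)
  }
})

test_that("Simes input validation", {
  expect_error(simesPvalue(numeric(0)), "input error")
  expect_error(simesPvalue(c(0.2, NA)), "input error")
  expect_error(simesPvalue(c(0, 0.5)), "input error")
  expect_error(simesPvalue(1.01), "input error")
})

test_that("family screening uses a strict inequality at alpha", {
  fams <- data.frame(family_id = c("a", "b", "c"),
                     simes_p = c(0.049, 0.05, 0.051))
  out <- screenFamilies(fams, alpha = 0.05)
  expect_identical(out$selected, c(TRUE, FALSE, FALSE))
})

test_that("within-family BH matches hand-computed adjusted p-values", {
  bh <- bhWithinFamily(c(0.01, 0.02, 0.20))
  expect_equal(bh$adjusted_p, c(0.03, 0.03, 0.20))
  expect_identical(bh$rejected, c(TRUE, TRUE, FALSE))
  # rejection is inclusive at q
  expect_true(all(bhWithinFamily(c(0.05, 0.025))$rejected))
})

test_that("BH rejections agree with the explicit step-up oracle", {
  set.seed(112)
  for (i in 1:1000) {
    m <- sample(1:6, 1)
    p <- runif(m)^sample(c(1, 2), 1)
    bh <- bhWithinFamily(p, q = 0.05)
    expect_identical(bh$rejected, bhRejectBrute(p, q = 0.05))
  }
})

test_that("shrinking any p-value never shrinks the BH rejection set", {
  set.seed(113)
  for (i in 1:200) {
    p <- runif(sample(2:8, 1))
    j <- sample(length(p), 1)
    p2 <- p
    p2[j] <- p[j] / 2
    r1 <- which(bhWithinFamily(p)$rejected)
    r2 <- which(bhWithinFamily(p2)$rejected)
    expect_true(all(setdiff(r1, j) %in% r2))
  }
})

test_that("families partition the pair table by motor variable and
           cognitive domain", {
  assoc <- data.frame(
    cognitive_id = rep(c("e1", "e2", "m1"), times = 2),
    cognitive_domain = rep(c("executive", "executive", "memory"), times = 2),
    motor_id = rep(c("g1", "g2"), each = 3),
    motor_domain = rep(c("pace", "pace"), each = 3),
    p = c(0.01, 0.04, 0.5, 0.2, 0.9, 0.03),
    stringsAsFactors = FALSE
  )
  grp <- groupHypotheses(assoc)
  expect_equal(nrow(grp$families), 4) # 2 motor vars x 2 cognitive domains
  expect_equal(sum(grp$families$m), nrow(assoc))
  expect_equal(sort(unique(grp$members$family_id)),
               sort(grp$families$family_id))
  f <- grp$families
  expect_equal(f$simes_p[f$family_id == "g1|executive"],
               simesPvalue(c(0.01, 0.04)))
  expect_equal(f$m[f$family_id == "g1|memory"], 1)
})

test_that("variables without a domain raise a metadata error", {
  assoc <- data.frame(cognitive_id = "e1", cognitive_domain = "executive",
                      motor_id = "g1", motor_domain = "pace", p = 0.5)
  meta <- data.frame(variable_id = c("e1", "g1"),
                     domain = c("executive", NA))
  expect_error(groupHypotheses(assoc, meta), "metadata error")
  assoc2 <- assoc
  assoc2$motor_domain <- NA
  expect_error(groupHypotheses(assoc2), "metadata error")
})
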