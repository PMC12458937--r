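# Epistatic coefficient, AUC machinery, reporter normalization and
# hypothesis tests.

test_that("epistatic coefficient matches hand evaluation of the formula", {
  r <- epistaticCoefficient(1e-6, 1e-2, 1e-1, wt_mean_eop = 1e-6)
  expect_equal(epsilon(r), 6 - 2 - 1)
  expect_false(isZeroed(r))

  # exactly multiplicative protection: epsilon 0
  r0 <- epistaticCoefficient(1e-3, 1e-2, 1e-1, wt_mean_eop = 1e-3)
  expect_equal(epsilon(r0), 0)

  # the zeroing rule fires when the wild type shows no real protection
  rz <- epistaticCoefficient(1e-6, 1e-2, 1e-1, wt_mean_eop = 0.5)
  expect_equal(epsilon(rz), 0)
  expect_true(isZeroed(rz))
  expect_equal(rz@rawEpsilon, 3)  # diagnostics keep the would-be value

  # boundary: the rule applies at exactly 1e-2 (>= threshold)
  rb <- epistaticCoefficient(1e-6, 1e-2, 1e-1, wt_mean_eop = 1e-2)
  expect_true(isZeroed(rb))
  rb2 <- epistaticCoefficient(1e-6, 1e-2, 1e-1,
                              wt_mean_eop = 1e-2 - 1e-9)
  expect_false(isZeroed(rb2))

  expect_error(epistaticCoefficient(0, 1e-2, 1e-1, 1e-6), "positive")
})

test_that("for EOPs <= 1 epsilon equals log10(eop_a*eop_b/eop_both)", {
  set.seed(101)
  for (i in 1:200) {
    e <- 10^runif(3, -8, 0)
    r <- epistaticCoefficient(e[1], e[2], e[3], wt_mean_eop = 1e-6)
    expect_equal(epsilon(r), log10(e[2] * e[3] / e[1]),
                 tolerance = 1e-12)
  }
  # strictly increasing as eop_both decreases, others fixed
  eb <- 10^seq(-2, -8, by = -0.5)
  eps <- vapply(eb, function(x)
    epsilon(epistaticCoefficient(x, 1e-2, 1e-1, 1e-6)), numeric(1))
  expect_true(all(diff(eps) > 0))
})

test_that("censored EOP bounds propagate a direction onto epsilon", {
  r <- epistaticCoefficient(1e-6, 1e-2, 1e-1, 1e-6,
                            censored = c(TRUE, FALSE, FALSE))
  expect_equal(r@bound, "ge")
  r2 <- epistaticCoefficient(1e-6, 1e-2, 1e-1, 1e-6,
                             censored = c(FALSE, TRUE, FALSE))
  expect_equal(r2@bound, "le")
})

test_that("baseline subtraction anchors curves at zero and is idempotent", {
  expect_equal(baselineSubtract(rep(0.3, 10)), rep(0, 10))
  expect_equal(baselineSubtract(c(0.1, 0.2, 0.4)), c(0, 0.1, 0.3))
  x <- cumsum(runif(20))
  expect_equal(baselineSubtract(baselineSubtract(x)),
               baselineSubtract(x))
  m <- cbind(c(0.1, 0.2), c(0.3, 0.5))
  expect_equal(baselineSubtract(m), cbind(c(0, 0.1), c(0, 0.2)))
})

test_that("AUC is a trapezoid integral in OD-hours", {
  tm <- seq(0, 60, by = 10)
  expect_equal(areaUnderCurve(rep(0, 7), tm), 0)
  # linear rise 0 -> 1 OD over one hour: triangle, 0.5 OD h
  expect_equal(areaUnderCurve(seq(0, 1, length.out = 7), tm), 0.5)
  # quadratic t^2 on [0, 1] h sampled every 10 min: the trapezoid sum is
  # (1/6) * (55/36 + 1/2), within the h^2 discretization error of 1/3
  tq <- seq(0, 60, by = 10)
  y <- (tq / 60)^2
  a <- areaUnderCurve(y, tq)
  expect_equal(a, (55 / 36 + 1 / 2) / 6, tolerance = 1e-12)
  expect_lt(abs(a - 1 / 3) / (1 / 3), 0.02)
  expect_error(areaUnderCurve(1:5, 1:4), "time points")
  expect_error(areaUnderCurve(1:3, c(1, 1, 2)), "increasing")
})

test_that("AUC is linear in its argument on a shared grid", {
  set.seed(3)
  tm <- seq(0, 540, by = 10)
  f <- runif(length(tm)); g <- runif(length(tm))
  expect_equal(areaUnderCurve(2 * f + 3 * g, tm),
               2 * areaUnderCurve(f, tm) + 3 * areaUnderCurve(g, tm),
               tolerance = 1e-12)
})

test_that("AUC synergy requires strict exceedance of the additive sum", {
  expect_true(isSynergy(callAucSynergy(10, 3, 4)))
  expect_false(isSynergy(callAucSynergy(7, 3, 4)))  # tie is not synergy
  expect_equal(expectedAdditive(callAucSynergy(7, 3, 4)), 7)
})

test_that("reporter normalization divides by OD with a floor", {
  od <- c(0.5, 0.2, 0.001)
  r <- normalizeReporter(od, od, floor_od = 0.01)
  expect_equal(r$value[1:2], c(1, 1))
  expect_true(r$flagged[3])
  expect_equal(r$value[3], 0.001 / 0.01)  # denominator floored
  r2 <- normalizeReporter(2 * od, od, floor_od = 0.01)
  expect_equal(r2$value, 2 * r$value)
  expect_error(normalizeReporter(1:3, 1:2), "lengths differ")
})

test_that("replicate bands are t-intervals with n-1 degrees of freedom", {
  m <- matrix(rep(c(0.1, 0.2), 3), ncol = 3)
  b <- replicateBand(m)
  expect_equal(b$lower, b$mean)  # identical replicates: zero width
  expect_equal(b$upper, b$mean)

  one <- matrix(c(0.1, 0.2, 0.3), nrow = 1)
  b1 <- replicateBand(one)
  expect_equal(b1$mean, 0.2)
  expect_equal(b1$upper - b1$mean, 4.302653 * 0.1 / sqrt(3),
               tolerance = 1e-5)
  expect_error(replicateBand(matrix(1:5, ncol = 1)), ">= 2 replicates")
})

test_that("one-sided Welch test: hand case and the swap identity", {
  r <- oneSidedGreaterTest(c(5, 6, 7), c(1, 2, 3))
  # mean diff 4, se = sqrt(2/3): t = 4.899, one-sided p < 0.01
  expect_equal(r$statistic, 4 / sqrt(2 / 3), tolerance = 1e-6)
  expect_lt(r$p_value, 0.01)
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(6)
    expect_equal(oneSidedGreaterTest(x, y)$p_value +
                   oneSidedGreaterTest(y, x)$p_value, 1,
                 tolerance = 1e-10)
  }
  expect_error(oneSidedGreaterTest(1, c(1, 2)), "n >= 2")
})

test_that("ANOVA F matches the hand-computed decomposition", {
  # small three-group table; F computed from first principles here
  y <- c(6, 8, 4, 5, 3, 4, 8, 12, 9, 11, 13, 8, 13, 14, 17, 12)
  g <- rep(c("ctrl", "t1", "t2"), c(6, 5, 5))
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2)))
  f_hand <- (ssb / 2) / (ssw / (length(y) - 3))
  r <- anovaMultcomp(y, g, control = "ctrl")
  expect_equal(r$f_statistic, f_hand, tolerance = 1e-6)
  expect_equal(r$p_value, pf(f_hand, 2, length(y) - 3, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(r$comparisons$group, c("t1", "t2"))
})

test_that("family-wise adjustment never reports smaller p than raw", {
  set.seed(21)
  y <- rnorm(24, mean = rep(c(0, 0.5, 1, 0.2), each = 6))
  g <- rep(c("ctrl", "a", "b", "c"), each = 6)
  fit <- aov(y2 ~ g2, data = data.frame(y2 = y, g2 = relevel(factor(g),
                                                             "ctrl")))
  mc <- multcomp::glht(fit, linfct = multcomp::mcp(g2 = "Dunnett"))
  p_raw <- summary(mc, test = multcomp::univariate())$test$pvalues
  r <- anovaMultcomp(y, g, control = "ctrl")
  expect_true(all(r$comparisons$p_adj >= p_raw - 1e-10))
  # holm route agrees in direction
  rh <- anovaMultcomp(y, g, control = "ctrl", method = "holm")
  expect_equal(rh$comparisons$group, r$comparisons$group)
})

test_that("near-constant groups yield no significant comparison", {
  set.seed(2)
  y <- 5 + rnorm(12, sd = 1e-3)
  g <- rep(c("ctrl", "a", "b"), each = 4)
  r <- anovaMultcomp(y, g, control = "ctrl")
  expect_false(any(r$comparisons$significant))
  expect_error(anovaMultcomp(y, rep("one", 12), "one"), "two groups")
})

test_that("epsilon recovery: multiplicative plaque assays give |eps| < 0.3", {
  # simulate EOP assays where the double-system strain is exactly
  # multiplicative; the estimated epsilon should be near zero
  ea <- 1e-3; eb <- 1e-2
  ok <- logical(60)
  for (i in seq_along(ok)) {
    cfg <- simConfig(seed = 1000 + i, plaque = list(
      true_titers = c(p = 1e10),
      true_eops = matrix(c(1, ea, eb, ea * eb), 1, 4,
                         dimnames = list("p", c("ref", "A", "B", "AB"))),
      replicates = 3L))
    sim <- simulatePlaqueAssay(cfg)
    tab <- eopTable(sim$assay, reference_strain = "ref")
    e <- setNames(tab$eop, tab$strain)
    r <- epistaticCoefficient(e[["AB"]], e[["A"]], e[["B"]],
                              wt_mean_eop = e[["AB"]])
    ok[i] <- abs(epsilon(r)) < 0.3
  }
  expect_gte(mean(ok), 0.95)
})
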