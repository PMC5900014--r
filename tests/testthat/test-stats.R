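test_that("group summaries follow the mean +/- SEM convention", {
  s <- summarizeGroup(c(1, 1, 1))
  expect_equal(s$mean, 1)
  expect_equal(s$sem, 0)
  s2 <- summarizeGroup(c(1, 2, 3))
  expect_equal(s2$mean, 2)
  expect_equal(s2$sem, 1 / sqrt(3))
  ## SEM is invariant to ordering
  set.seed(1)
  v <- rnorm(20)
  expect_equal(summarizeGroup(v)$sem, summarizeGroup(rev(v))$sem)
  expect_error(summarizeGroup(1), "at least 2")
  s3 <- summarizeGroup(c(1, 2, 3, 4), animals = c("a", "a", "b", "b"),
                       cells = 1:4)
  expect_identical(s3$n_animals, 2L)
  expect_identical(s3$n_cells, 4L)
})

test_that("the omnibus normality test matches an independent reference", {
  ## expected values computed with an independent implementation of the
  ## same K2 statistic (skew + kurtosis transforms), frozen here
  x1 <- sin(1:20)
  r1 <- dagostinoPearsonTest(x1)
  expect_equal(r1$statistic, 8.828599767037225, tolerance = 1e-10)
  expect_equal(r1$p.value, 0.012103024686599694, tolerance = 1e-10)
  x2 <- (1:15)^2
  r2 <- dagostinoPearsonTest(x2)
  expect_equal(r2$statistic, 1.8684783737917758, tolerance = 1e-10)
  expect_equal(r2$p.value, 0.3928846636528542, tolerance = 1e-10)
  x4 <- c(1:9, 30)
  r4 <- dagostinoPearsonTest(x4)
  expect_equal(r4$statistic, 21.51018016740113, tolerance = 1e-10)
  expect_equal(r4$p.value, 2.1336526736526765e-05, tolerance = 1e-9)
  expect_equal(r4$z.skew, 3.4317268690602876, tolerance = 1e-10)
  expect_equal(r4$z.kurt, 3.119844685809024, tolerance = 1e-10)
  expect_error(dagostinoPearsonTest(1:5), "at least 8")
})

test_that("star coding uses strict inequalities at every boundary", {
  expect_identical(starCode(c(0.03, 9e-5, 5e-4, 0.005)),
                   c("*", "****", "***", "**"))
  expect_identical(starCode(0.05), "ns")
  expect_identical(starCode(0.0001), "***")
  expect_identical(starCode(1), "ns")
  expect_error(starCode(1.2), "\\[0, 1\\]")
  expect_error(starCode(-0.1), "\\[0, 1\\]")
})

test_that("identical paired groups report p = 1 with a zero-variance flag", {
  g <- c(1.2, 3.4, 2.2, 5.1, 0.7, 2.9, 3.3, 4.0)
  r <- compareGroups(g, g, paired = TRUE)
  expect_equal(r$p, 1)
  expect_true(r$zero_variance)
  expect_identical(r$stars, "ns")
  expect_error(compareGroups(1:4, 1:5, paired = TRUE), "equal group lengths")
})

test_that("more than two groups dispatch to one-way ANOVA", {
  set.seed(8)
  r <- compareGroups(rnorm(10), rnorm(10), rnorm(10, 3))
  expect_identical(r$test, "one-way ANOVA")
  expect_lt(r$p, 0.01)
  ## matches stats::oneway.test directly
  a <- rnorm(9); b <- rnorm(9, 1); c <- rnorm(9, 2)
  mine <- compareGroups(a, b, c)
  ref <- oneway.test(c(a, b, c) ~ factor(rep(1:3, each = 9)),
                     var.equal = TRUE)
  expect_equal(mine$p, ref$p.value)
})

test_that("small groups skip the normality screen with a flag", {
  r <- compareGroups(c(1, 2, 3), c(4, 5, 7))
  expect_true(r$normality_skipped)
  expect_true(all(is.na(r$normality_p)))
})

test_that("the type-I error of the comparison machinery is ~5% under the null", {
  set.seed(101)
  hits <- 0L
  nRep <- 1000L
  for (i in seq_len(nRep)) {
    r <- compareGroups(rnorm(10), rnorm(10))
    if (r$p < 0.05) hits <- hits + 1L
  }
  rate <- hits / nRep
  se <- sqrt(0.05 * 0.95 / nRep)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("suppression by an NO donor is detected in nearly every replicate", {
  ## generator cohorts at the reported condition rates (0.9 vs 0.14 /s),
  ## 10 cells each; the contrast must reach p < 0.01 almost always
  ctrl <- presetConfig("deanonoate_control", duration = 20)
  drug <- presetConfig("deanonoate", duration = 20)
  hits <- 0L
  nRep <- 40L
  for (r in seq_len(nRep)) {
    cohortFreq <- function(cfg, off) vapply(1:10, function(i)
      nrow(simulateTrains(cfg, seed = off + r * 100L + i)@events) / 20,
      numeric(1))
    fc <- cohortFreq(ctrl, 40000L)
    fd <- cohortFreq(drug, 80000L)
    if (compareGroups(fc, fd)$p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits / nRep, 0.95)
})
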