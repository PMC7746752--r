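test_that("AUC equals the pair-counting concordance oracle exactly", {
  set.seed(31)
  for (i in 1:50) {
    n <- 20
    scores <- round(runif(n), sample(c(1, 2, 7), 1))  # induce some ties
    labels <- c(rep(1, 10), rep(0, 10))[sample(n)]
    r <- rocAuc(scores, labels)
    expect_equal(r@auc, aucOracle(scores, labels), tolerance = 1e-12)
  }
  sep <- rocAuc(c(1:5 / 10, 6:10 / 10), rep(c(0, 1), each = 5))
  expect_equal(sep@auc, 1)
  tied <- rocAuc(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(tied@auc, 0.5)
  expect_error(rocAuc(runif(5), rep(1, 5)), "both classes")
  r2 <- rocAuc(runif(10), rep(c("AD", "CN"), 5))
  expect_s4_class(r2, "ROCResult")
})

test_that("Youden operating point maximises J with lowest-threshold ties", {
  r <- rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  op <- youdenPoint(r)
  oracle <- youdenOracle(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(op@youdenJ, oracle$j)
  expect_equal(op@threshold, oracle$th)

  set.seed(41)
  for (i in 1:20) {
    scores <- round(runif(14), 2)
    labels <- rbinom(14, 1, 0.5)
    if (length(unique(labels)) < 2) next
    r <- rocAuc(scores, labels)
    op <- youdenPoint(r)
    oracle <- youdenOracle(scores, labels)
    expect_equal(op@youdenJ, oracle$j, tolerance = 1e-12)
    expect_equal(op@threshold, oracle$th)
    # accuracy identity at the chosen threshold
    nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
    expect_equal(op@accuracy,
                 (op@sensitivity * nPos + op@specificity * nNeg) /
                   (nPos + nNeg), tolerance = 1e-12)
  }
  perfect <- youdenPoint(rocAuc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)))
  expect_equal(perfect@youdenJ, 1)
  expect_equal(perfect@accuracy, 1)
})

test_that("DeLong comparison: identity, type-I error and variance sanity", {
  set.seed(51)
  scores <- runif(40)
  labels <- rep(c(0, 1), 20)
  r <- rocAuc(scores, labels)
  self <- delongCompare(r, r, paired = TRUE)
  expect_equal(self@statistic, 0)
  expect_equal(self@pValue, 1)
  expect_error(delongCompare(r, rocAuc(runif(10), rep(c(0, 1), 5)),
                             paired = TRUE), "same subjects")

  # type-I error at alpha = 0.05 over 200 independent null comparisons
  set.seed(52)
  rej <- 0
  for (i in 1:200) {
    s1 <- runif(60); s2 <- runif(60)
    l <- rep(c(0, 1), 30)
    z <- delongCompare(rocAuc(s1, l), rocAuc(s2, l), paired = FALSE)
    if (z@pValue < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 200, 0.02)
  expect_lte(rej / 200, 0.09)

  # DeLong variance against a bootstrap oracle at n = 100
  set.seed(53)
  n <- 100
  lab <- rep(c(0, 1), each = n / 2)
  sc <- c(rnorm(n / 2), rnorm(n / 2, 1))
  v <- rocAuc(sc, lab)@aucVariance
  boot <- replicate(1000, {
    i <- c(sample(which(lab == 0), n / 2, TRUE),
           sample(which(lab == 1), n / 2, TRUE))
    rocAuc(sc[i], lab[i])@auc
  })
  expect_lt(abs(v - var(boot)) / var(boot), 0.25)
})

test_that("AUC confidence intervals truncate, cover and contain the point", {
  sep <- rocAuc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(aucConfidenceInterval(sep), c(1, 1))
  set.seed(61)
  r <- rocAuc(runif(30), rep(c(0, 1), 15))
  ci <- aucConfidenceInterval(r)
  expect_lte(ci[1], r@auc)
  expect_gte(ci[2], r@auc)

  # empirical coverage at true AUC 0.8, n = 80, 200 simulations
  mu <- sqrt(2) * qnorm(0.8)
  set.seed(62)
  cover <- 0
  for (i in 1:200) {
    sc <- c(rnorm(40), rnorm(40, mu))
    ci <- aucConfidenceInterval(rocAuc(sc, rep(c(0, 1), each = 40)))
    if (ci[1] <= 0.8 && ci[2] >= 0.8) cover <- cover + 1
  }
  expect_gte(cover / 200, 0.90)
  expect_lte(cover / 200, 0.99)
})

test_that("summary-statistic t-tests reproduce printed cohort statistics", {
  mmse <- ttestFromSummary(23.0, 2.3, 195, 18.4, 5.0, 195)
  expect_equal(round(mmse@statistic, 1), 11.7)
  expect_identical(mmse@df, 388)
  expect_lt(mmse@pValue, 0.001)

  edu <- ttestFromSummary(16.0, 2.7, 195, 11.4, 4.8, 195)
  expect_lt(abs(edu@statistic - 11.6), 0.1)

  ageAD <- ttestFromSummary(74.7, 8.2, 195, 74.5, 8.7, 195)
  expect_equal(round(ageAD@statistic, 1), 0.2)
  ageCN <- ttestFromSummary(74.8, 6.6, 195, 73.9, 6.3, 195)
  expect_equal(round(ageCN@statistic, 1), 1.4)

  same <- ttestFromSummary(5, 1, 10, 5, 1, 10)
  expect_equal(same@statistic, 0)
  expect_equal(same@pValue, 1)
  # equal group sizes: pooled t equals the Welch statistic
  welchDenom <- sqrt(2.3^2 / 195 + 5.0^2 / 195)
  expect_equal(mmse@statistic, (23.0 - 18.4) / welchDenom,
               tolerance = 1e-12)
  expect_error(ttestFromSummary(1, 1, 1, 2, 1, 10), ">= 2")
  expect_error(ttestFromSummary(1, 0, 10, 2, 0, 10), "positive")
})

test_that("paired t-test matches the hand formula and flags degeneracy", {
  d <- c(1, 1, 1, 1, 2)
  tt <- pairedTtest(d + 10, rep(10, 5))
  expect_equal(tt@statistic, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_identical(tt@df, 4)
  swap <- pairedTtest(rep(10, 5), d + 10)
  expect_equal(swap@statistic, -tt@statistic)
  expect_error(pairedTtest(c(1, 2, 3), c(2, 3, 4)), "zero variance")
  expect_error(pairedTtest(1, 2), "length >= 2")
})

test_that("2x2 chi-square matches closed forms and symmetries", {
  sex <- chiSquare2x2(matrix(c(91, 104, 91, 104), 2))
  expect_equal(sex@statistic, 0)
  expect_gt(sex@pValue, 0.99)
  diagT <- chiSquare2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diagT@statistic, 20)
  expect_identical(diagT@df, 1)
  set.seed(71)
  m <- matrix(rpois(4, 20) + 1, 2)
  expect_equal(chiSquare2x2(m)@statistic,
               chiSquare2x2(m[2:1, 2:1])@statistic)
  expect_error(chiSquare2x2(matrix(c(0, 0, 5, 5), 2)), "margins")
  expect_error(chiSquare2x2(matrix(c(1.5, 1, 1, 1), 2)), "integers")
})

test_that("trial aggregation uses the sample standard deviation", {
  ts <- trialSummary(c(0.90, 0.97, 0.95, 0.95, 0.95))
  expect_equal(round(ts[["mean"]], 2), 0.94)
  expect_equal(round(ts[["sd"]], 2), 0.03)
  expect_equal(round(trialSummary(c(0.87, 0.88, 0.88, 0.89, 0.86))[["mean"]],
                     2), 0.88)
  expect_equal(trialSummary(c(0.5, 0.5, 0.5))[["sd"]], 0)
  expect_error(trialSummary(0.5), "at least 2")
})
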