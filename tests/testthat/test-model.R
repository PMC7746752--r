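test_that("feature concatenation and softmax honour the architecture", {
  expect_identical(classifierConfig()$concatDim, 1027L)
  cc <- classifierConfig(featureDim = 16L, inputSize = 16L, nSlices = 15L)
  expect_identical(cc$concatDim, 19L)
  w <- initWeights(cc, seed = 3)
  expect_identical(nrow(w$headW), 2L)
  expect_identical(ncol(w$headW), cc$concatDim)
  set.seed(5)
  x <- array(runif(16 * 16 * 3 * 4), c(16L, 16L, 12L))
  meta <- matrix(runif(12), 3, 4)
  fw <- coronalAD:::forwardBatch(w, cc, x, meta)
  expect_lt(max(abs(colSums(fw$probs) - 1)), 1e-6)
  expect_true(all(fw$probAD >= 0 & fw$probAD <= 1))
  # identical weights, repeated evaluation: no hidden state
  fw2 <- coronalAD:::forwardBatch(w, cc, x, meta)
  expect_identical(fw$probAD, fw2$probAD)
})

test_that("metadata reaches the classifier head", {
  cc <- classifierConfig(featureDim = 16L, inputSize = 16L, nSlices = 15L)
  w <- initWeights(cc, seed = 3)
  s1 <- list(image = matrix(0.5, 16, 16), age_years = 70, sex_code = 1,
             slice_number = 3)
  s2 <- s1; s2$age_years <- 90
  expect_gt(abs(forward(s1, w, cc) - forward(s2, w, cc)), 1e-9)
  s3 <- s1; s3$sex_code <- 0
  expect_gt(abs(forward(s1, w, cc) - forward(s3, w, cc)), 1e-9)
  bad <- list(image = matrix(0.5, 8, 8), age_years = 70, sex_code = 1,
              slice_number = 3)
  expect_error(forward(bad, w, cc), "shape")
})

test_that("batch cross-entropy matches closed forms and the oracle", {
  expect_equal(batchLoss(c(0.5, 0.5, 0.5), c(1, 0, 1)), log(2),
               tolerance = 1e-12)
  expect_equal(batchLoss(c(0.9, 0.2), c(1, 0)),
               -(log(0.9) + log(0.8)) / 2, tolerance = 1e-12)
  expect_equal(round(batchLoss(c(0.9, 0.2), c(1, 0)), 6), 0.164252)
  expect_lte(batchLoss(c(1, 0, 1), c(1, 0, 1)), 2e-6)
  expect_error(batchLoss(c(0.5, 0.5), c(1)), "equal length")
  set.seed(6)
  for (i in 1:100) {
    n <- sample(1:40, 1)
    p <- runif(n)
    y <- rbinom(n, 1, 0.5)
    expect_equal(batchLoss(p, y), bceOracle(p, y), tolerance = 1e-9)
  }
})

test_that("learning-rate schedule decays on plateaus, at most three times", {
  tc <- trainConfig()
  st <- list(valLoss = c(1, 0.8, 0.6, 0.5, 0.4, 0.3), lr = 0.001,
             decays = 0L, lastDecayEpoch = 0L)
  expect_equal(lrScheduleStep(st, tc)$lr, 0.001)  # still improving

  flat <- list(valLoss = rep(0.5, 8), lr = 0.001, decays = 0L,
               lastDecayEpoch = 0L)
  st2 <- lrScheduleStep(flat, tc)
  expect_equal(st2$lr, 1e-4, tolerance = 1e-12)
  expect_identical(st2$decays, 1L)

  capped <- list(valLoss = rep(0.5, 30), lr = 1e-6, decays = 3L,
                 lastDecayEpoch = 0L)
  expect_equal(lrScheduleStep(capped, tc)$lr, 1e-6)
  expect_error(lrScheduleStep(list(valLoss = numeric(0), lr = 1,
                                   decays = 0L, lastDecayEpoch = 0L), tc),
               "at least one")
})

test_that("early stopping follows the moving-average accuracy rule", {
  tc <- trainConfig()
  rising <- seq(0.5, by = 0.01, length.out = 12)
  expect_false(earlyStopCheck(rising, tc))
  expect_true(earlyStopCheck(rep(0.8, 12), tc))
  # improving by exactly the threshold over the window is not "more
  # than" the delta: stop
  slow <- seq(0.5, by = 5e-4 / 5, length.out = 12)
  expect_true(earlyStopCheck(slow, tc))
  expect_error(earlyStopCheck(c(0.5, 0.6), tc), "entries")
})

test_that("backpropagated gradients match finite differences", {
  cc <- classifierConfig(featureDim = 8L, inputSize = 16L, nSlices = 4L)
  w <- initWeights(cc, seed = 13)
  set.seed(14)
  B <- 3L
  x <- array(runif(16 * 16 * 3 * B), c(16L, 16L, 3L * B))
  meta <- matrix(runif(3 * B), 3, B)
  y <- c(1, 0, 1)
  bs <- coronalAD:::initBnStats(cc)
  fw <- coronalAD:::forwardBatch(w, cc, x, meta, bs, training = TRUE,
                                 keepCache = TRUE)
  gr <- coronalAD:::backwardBatch(w, cc, fw$cache, y)
  lossAt <- function(w) {
    batchLoss(coronalAD:::forwardBatch(w, cc, x, meta, bs,
                                       training = TRUE)$probAD, y)
  }
  # conv biases are cancelled exactly by batch normalisation (gradient
  # ~0), so compare the informative parameter groups
  for (nm in c("convW1", "bnG1", "bnB1", "convW2", "convW3", "fcW", "fcB",
               "headW", "headB")) {
    for (r in 1:3) {
      i <- sample(length(w[[nm]]), 1)
      h <- 1e-5
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + h
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - h
      fd <- (lossAt(wp) - lossAt(wm)) / (2 * h)
      expect_lt(abs(fd - gr[[nm]][i]),
                1e-6 + 1e-4 * (abs(fd) + abs(gr[[nm]][i])))
    }
  }
})

test_that("training separates a linearly separable toy problem", {
  toy <- toySliceData(n = 10, seed = 11)
  tc <- trainConfig(batchSize = 16L, maxEpochs = 20L)
  m <- trainFold(toy$ds, toy$train, toy$val, toy$cconfig, tc,
                 aconfig = NULL, seed = 42)
  expect_equal(max(m@history$valAccuracy), 1)
  expect_lte(nrow(m@history), 20)
})

test_that("training is deterministic and responds to weight decay", {
  toy <- toySliceData(n = 6, seed = 23)
  tc <- trainConfig(batchSize = 16L, maxEpochs = 3L)
  m1 <- trainFold(toy$ds, toy$train, toy$val, toy$cconfig, tc,
                  aconfig = augmentConfig(), seed = 7)
  m2 <- trainFold(toy$ds, toy$train, toy$val, toy$cconfig, tc,
                  aconfig = augmentConfig(), seed = 7)
  expect_identical(m1@history$trainLoss, m2@history$trainLoss)
  expect_identical(m1@weights, m2@weights)

  tc0 <- trainConfig(batchSize = 16L, maxEpochs = 3L, weightDecay = 0)
  m0 <- trainFold(toy$ds, toy$train, toy$val, toy$cconfig, tc0,
                  aconfig = augmentConfig(), seed = 7)
  norm1 <- sqrt(sum(unlist(m1@weights)^2))
  norm0 <- sqrt(sum(unlist(m0@weights)^2))
  expect_false(isTRUE(all.equal(norm0, norm1)))

  expect_error(trainFold(toy$ds, character(0), toy$val, toy$cconfig, tc),
               "empty")
  expect_error(trainFold(toy$ds, toy$train, toy$train, toy$cconfig, tc),
               "disjoint")
})

test_that("the unavailable large backbone is reported, not silently swapped", {
  cc <- classifierConfig(backbone = "inception_v4")
  expect_error(initWeights(cc), "tiny_cnn")
})
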