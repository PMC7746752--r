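test_that("rigid transforms compose, invert and never scale", {
  set.seed(4)
  for (i in 1:20) {
    a <- rigidTransform(runif(3, -20, 20), runif(3, -15, 15))
    b <- rigidTransform(runif(3, -20, 20), runif(3, -15, 15))
    expect_equal(transformMatrix(composeTransforms(a, b)),
                 transformMatrix(a) %*% transformMatrix(b),
                 tolerance = 1e-10)
    dev <- transformDeviation(composeTransforms(a, invertTransform(a)))
    expect_lt(dev["rotationDeg"], 1e-8)
    expect_lt(dev["translationMm"], 1e-8)
    expect_equal(det(transformMatrix(a)[1:3, 1:3]), 1, tolerance = 1e-6)
  }
})

test_that("min-max normalization: affine map, degenerate case, idempotence", {
  m <- matrix(c(0, 5, 10, 5), 2)
  expect_equal(minmaxNormalize(m), matrix(c(0, 0.5, 1, 0.5), 2))
  expect_equal(minmaxNormalize(matrix(3.7, 4, 4)), matrix(0, 4, 4))
  set.seed(8)
  s <- matrix(rnorm(64), 8)
  n1 <- minmaxNormalize(s)
  expect_equal(min(n1), 0)
  expect_equal(max(n1), 1)
  expect_identical(minmaxNormalize(n1), n1)
  expect_error(minmaxNormalize(matrix(c(1, NA, 2, 3), 2)), "finite")
})

test_that("isotropic resampling preserves grids, constants and centring", {
  expect_identical(eval(formals(resampleIsotropic)$grid), 256L)
  expect_identical(eval(formals(resampleIsotropic)$spacing), 1)
  set.seed(2)
  v <- brainVolume(array(runif(24^3), c(24, 24, 24)), 2)
  same <- resampleIsotropic(v, 24, 2)
  expect_lt(max(abs(volData(same) - volData(v))), 1e-6)
  const <- brainVolume(array(0.4, c(20, 20, 20)), 2)
  down <- resampleIsotropic(const, 10, 2)
  # interior voxels of a constant field stay constant
  expect_equal(volData(down)[3:8, 3:8, 3:8],
               array(0.4, c(6, 6, 6)), tolerance = 1e-9)
  expect_error(resampleIsotropic(v, -1, 1), "positive")
})

test_that("registration recovers identity, pure shifts and misalignments", {
  spec <- fastSpec(intensityNoiseSd = 0.04)
  can <- canonicalPhantom(spec)
  r0 <- registerRigid(can, can)
  d0 <- transformDeviation(r0$transform)
  expect_lt(d0["rotationDeg"], 0.1)
  expect_lt(d0["translationMm"], 0.1)

  shifted <- applyTransform(can, rigidTransform(c(0, 0, 0), c(5, 0, 0)))
  rs <- registerRigid(shifted, can)
  expect_lt(abs(sqrt(sum(rs$transform@translations^2)) - 5), 0.5)
  expect_lt(max(abs(rs$transform@rotations)), 0.5)

  # misalignment recovery at the standard 2 mm sampling (rotations are
  # only weakly identified at the 3 mm fast-test spacing); accuracy is a
  # median property — single poses can sit in a shallow rotation basin
  spec2 <- phantomSpec(intensityNoiseSd = 0.04)
  can2 <- canonicalPhantom(spec2)
  devs <- t(vapply(1:6, function(i) {
    g <- generateVolume(spec2, list(subject_id = "r", age_years = 75,
                                    sex = 0, diagnosis = "CN"),
                        seed = 300 + i)
    reg <- registerRigid(g$volume, can2)
    transformDeviation(reg$transform, g$subject$trueTransform)
  }, numeric(2)))
  expect_lte(median(devs[, 1]), 1)
  expect_lte(median(devs[, 2]), 1)
})

test_that("brain extraction recovers the parenchyma and rejects empties", {
  spec <- fastSpec(intensityNoiseSd = 0)
  can <- canonicalPhantom(spec)
  ext <- extractBrain(can)
  gt <- canonicalBrainMask(spec)
  dice <- 2 * sum(ext$mask == 1 & gt == 1) / (sum(ext$mask) + sum(gt))
  expect_gte(dice, 0.95)
  expect_true(all(volData(ext$volume)[ext$mask == 0] == 0))
  zero <- brainVolume(array(0, c(16, 16, 16)), 3)
  expect_error(extractBrain(zero), "empty|constant")
})

test_that("two-step alignment is a fixed point on aligned input", {
  spec <- fastSpec(intensityNoiseSd = 0.04, misalignRotDegMax = 0,
                   misalignTransMmMax = 0)
  tpl <- phantomTemplate(spec, n = 2, seed = 31)
  g <- generateVolume(spec, list(subject_id = "f", age_years = 70, sex = 1,
                                 diagnosis = "CN"), seed = 77)
  al <- twoStepAlign(g$volume, tpl)
  for (tr in al$transforms) {
    dev <- transformDeviation(tr)
    expect_lt(dev["rotationDeg"], 0.2)
    expect_lt(dev["translationMm"], 0.2)
  }
  expect_identical(dim(volData(al$volume)), dim(volData(tpl@volume)))
})

test_that("second alignment step does not degrade the first on average", {
  spec <- fastSpec(intensityNoiseSd = 0.06, misalignRotDegMax = 6,
                   misalignTransMmMax = 6)
  tpl <- phantomTemplate(spec, n = 3, seed = 101)
  err1 <- err2 <- numeric(0)
  for (i in 1:20) {
    g <- generateVolume(spec, list(subject_id = paste0("t", i),
                                   age_years = 75, sex = 0,
                                   diagnosis = "CN"), seed = 400 + i)
    step1 <- registerRigid(g$volume, tpl@volume)
    stripped <- extractBrain(step1$resampled)
    strippedTpl <- brainVolume(volData(tpl@volume) * tpl@brainMask,
                               voxelSpacing(tpl@volume))
    step2 <- registerRigid(stripped$volume, strippedTpl)
    composed <- composeTransforms(step1$transform, step2$transform)
    d1 <- transformDeviation(step1$transform, g$subject$trueTransform)
    d2 <- transformDeviation(composed, g$subject$trueTransform)
    err1 <- c(err1, d1["rotationDeg"] + d1["translationMm"])
    err2 <- c(err2, d2["rotationDeg"] + d2["translationMm"])
  }
  expect_lte(mean(err2), mean(err1))
})

test_that("coronal slice extraction honours anchor, order and contracts", {
  expect_identical(eval(formals(extractCoronalSlices)$nSlices), 30L)
  spec <- fastSpec(intensityNoiseSd = 0.02, misalignRotDegMax = 0,
                   misalignTransMmMax = 0)
  can <- canonicalPhantom(spec)
  tpl <- buildTemplate(list(can), analyticAnchorIndex(spec))
  st <- extractCoronalSlices(can, tpl, nSlices = 10L, subjectRef = "c")
  expect_equal(nSlices(st), 10L)
  expect_identical(st@sliceIndices,
                   seq(tpl@anchorIndex, tpl@anchorIndex + 9L))
  expect_gte(min(st@slices), 0)
  expect_lte(max(st@slices), 1)
  st2 <- extractCoronalSlices(can, tpl, nSlices = 10L, subjectRef = "c")
  expect_identical(st@slices, st2@slices)
  stRev <- extractCoronalSlices(can, tpl, nSlices = 5L,
                                direction = "anterior-to-posterior")
  expect_identical(stRev@sliceIndices,
                   seq(tpl@anchorIndex, tpl@anchorIndex - 4L))
  expect_error(extractCoronalSlices(can, tpl, nSlices = 1000L), "exceeds")
})

test_that("slice stacks enforce shape and value invariants", {
  ok <- array(runif(4 * 4 * 3), c(4, 4, 3))
  st <- new("SliceStack", slices = ok, sliceIndices = 5:7, subjectRef = "x")
  expect_s4_class(st, "SliceStack")
  expect_error(new("SliceStack", slices = ok, sliceIndices = c(5L, 7L, 9L),
                   subjectRef = "x"), "consecutive")
  bad <- ok; bad[1] <- 2
  expect_error(new("SliceStack", slices = bad, sliceIndices = 5:7,
                   subjectRef = "x"), "0, 1")
})
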