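test_that("phantom generation is deterministic and diagnosis-driven", {
  spec <- fastSpec(intensityNoiseSd = 0.05)
  params <- list(subject_id = "S1", age_years = 74, sex = 1,
                 diagnosis = "AD")
  g1 <- generateVolume(spec, params, seed = 42)
  g2 <- generateVolume(spec, params, seed = 42)
  expect_identical(volData(g1$volume), volData(g2$volume))
  g3 <- generateVolume(spec, params, seed = 43)
  expect_false(identical(volData(g1$volume), volData(g3$volume)))

  # zero atrophy effect: AD and CN generation paths coincide exactly
  spec0 <- fastSpec(atrophyEffect = 0)
  pAD <- params
  pCN <- params; pCN$diagnosis <- "CN"
  vAD <- generateVolume(spec0, pAD, seed = 7)
  vCN <- generateVolume(spec0, pCN, seed = 7)
  expect_identical(volData(vAD$volume), volData(vCN$volume))
  expect_equal(vAD$subject$trueMtlVolumeMm3, vCN$subject$trueMtlVolumeMm3)
})

test_that("infeasible phantom geometry is rejected", {
  expect_error(phantomSpec(gridSize = 32L, voxelSpacingMm = 2),
               "does not fit")
  expect_error(phantomSpec(atrophyEffect = 1), "atrophyEffect")
  expect_error(phantomSpec(intensityNoiseSd = -0.1), ">= 0")
})

test_that("cohort generation counts, uniqueness and determinism", {
  spec <- fastSpec(intensityNoiseSd = 0.05, misalignRotDegMax = 3,
                   misalignTransMmMax = 3)
  expect_error(cohortMetadata(spec, 0, 5), ">= 1")
  m1 <- cohortMetadata(spec, 5, 5, seed = 3)
  expect_equal(nrow(m1), 10)
  expect_equal(sum(m1$diagnosis == "AD"), 5)
  expect_equal(sum(m1$diagnosis == "CN"), 5)
  expect_false(any(duplicated(m1$subject_id)))
  m2 <- cohortMetadata(spec, 5, 5, seed = 3)
  expect_identical(m1, m2)
  expect_true(all(m1$age_years >= 55 & m1$age_years <= 95))

  ch <- generateCohort(spec, 2, 2, seed = 9)
  expect_length(ch, 4)
  ch2 <- generateCohort(spec, 2, 2, seed = 9)
  expect_identical(volData(ch[[3]]$volume), volData(ch2[[3]]$volume))
})

test_that("simulated atrophy reproduces the generative volume ratio", {
  # atrophy 0.3, jitter sdlog 0.05, n = 40 + 40: the sample mean AD/CN
  # medial-temporal volume ratio should sit at 0.7 within 3 SE, where
  # SE ~= 0.7 * sqrt(2 * sdlog^2 / n) from the lognormal jitter
  spec <- fastSpec(atrophyEffect = 0.3, mtlJitterSd = 0.05,
                   intensityNoiseSd = 0, misalignRotDegMax = 0,
                   misalignTransMmMax = 0)
  meta <- cohortMetadata(spec, 40, 40, seed = 21)
  vols <- vapply(seq_len(nrow(meta)), function(i) {
    generateVolume(spec, as.list(meta[i, , drop = FALSE]),
                   seed = coronalAD:::derivedSeed(21, i))$subject$trueMtlVolumeMm3
  }, numeric(1))
  ratio <- mean(vols[meta$diagnosis == "AD"]) /
    mean(vols[meta$diagnosis == "CN"])
  se <- 0.7 * sqrt(2 * 0.05^2 / 40)
  expect_lt(abs(ratio - 0.7), 3 * se)
})

test_that("rendered medial-temporal structure shrinks with atrophy", {
  geo <- coronalAD:::phantomGeometry()
  spec <- fastSpec(atrophyEffect = 0.4, mtlJitterSd = 0,
                   intensityNoiseSd = 0, misalignRotDegMax = 0,
                   misalignTransMmMax = 0)
  pAD <- list(subject_id = "a", age_years = 75, sex = 0, diagnosis = "AD")
  pCN <- pAD; pCN$diagnosis <- "CN"
  vAD <- volData(generateVolume(spec, pAD, seed = 2)$volume)
  vCN <- volData(generateVolume(spec, pCN, seed = 2)$volume)
  # count voxels in the medial-temporal intensity band within a box
  # around the structures (the bright shell shares the upper band)
  n <- spec$gridSize; s <- spec$voxelSpacingMm
  ax <- (seq_len(n) - 1 - (n - 1) / 2) * s
  inBox <- function(v) {
    box <- outer(outer(abs(ax) >= 10 & abs(ax) <= 46,
                       ax >= -32 & ax <= 12, "&"),
                 ax >= -30 & ax <= 2, "&")
    sum(v > 0.7 & v < 0.9 & box)
  }
  ratio <- inBox(vAD) / inBox(vCN)
  expect_lt(ratio, 0.8)
  expect_gt(ratio, 0.4)
})

test_that("template construction: identity mean, analytic anchor, mask", {
  spec <- fastSpec(intensityNoiseSd = 0)
  can <- canonicalPhantom(spec)
  tpl <- buildTemplate(list(can), analyticAnchorIndex(spec))
  expect_equal(volData(tpl@volume), volData(can), tolerance = 1e-12)
  expect_identical(tpl@anchorIndex, analyticAnchorIndex(spec))

  # the brain mask must exclude the scalp/skull shell
  geo <- coronalAD:::phantomGeometry()
  n <- spec$gridSize
  xs <- (seq_len(n) - 1 - (n - 1) / 2) * spec$voxelSpacingMm
  ell <- function(semi) outer(outer((xs / semi[1])^2, (xs / semi[2])^2,
                                    "+"), (xs / semi[3])^2, "+")
  shell <- ell(geo$shellOuter) <= 1 & ell(geo$shellInner) > 1
  expect_lt(sum(tpl@brainMask == 1 & shell) / sum(shell), 0.01)

  expect_error(buildTemplate(list(), 1), "at least one")
  small <- brainVolume(array(0.5, c(8, 8, 8)), 3)
  expect_error(buildTemplate(list(can, small), 1), "same grid")
})

test_that("phantom-space template anchor matches the generator geometry", {
  spec <- fastSpec(intensityNoiseSd = 0.04, misalignRotDegMax = 0,
                   misalignTransMmMax = 0)
  tpl <- phantomTemplate(spec, n = 3, seed = 5)
  expect_identical(tpl@anchorIndex, analyticAnchorIndex(spec))
  expect_identical(dim(tpl@brainMask), dim(volData(tpl@volume)))
})
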