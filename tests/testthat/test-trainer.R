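# Desk-scale training sizes are deliberately small (tens of gradient steps
# on images a few dozen pixels across); the properties under test are
# structural, not capacity-dependent.

cleanFrame <- function(scene) {
  truth <- generateTruth(scene)
  list(truth = truth,
       sup = SupervisionFrame(truth,
                              ConfidenceMap(matrix(1, scene@height,
                                                   scene@width))))
}

test_that("training configs reject non-positive step budgets", {
  expect_error(TrainConfig(maxSteps = 0L), "maxSteps")
  expect_error(TrainConfig(stepSize = 0), "stepSize")
})

test_that("a realizable noiseless target is fit to numerical zero", {
  scene <- SceneConfig(height = 24L, width = 32L, seed = 3L)
  cf <- cleanFrame(scene)
  fit <- fitPredictor(list(cf$sup),
                      TrainConfig(maxSteps = 40L,
                                  loss = LossConfig(weight = WeightConfig("uniform"))))
  expect_lt(fit@finalLoss, 1e-6)
  pred <- predictSurface(fit, scene@height, scene@width)
  a <- alignLSQ(pred, cf$truth)
  aligned <- mapValues(applyAffine(pred, a))
  tv <- mapValues(cf$truth)
  expect_lt(mean(abs(aligned - tv) / tv), 1e-3)
})

test_that("the best-so-far loss trajectory never increases", {
  scene <- SceneConfig(height = 20L, width = 28L, seed = 11L)
  truth <- generateTruth(scene)
  sup <- corruptTruth(truth, CorruptionConfig(occlusionBorderCols = 4L,
                                              seed = 12L))
  fit <- fitPredictor(list(sup),
                      TrainConfig(maxSteps = 15L,
                                  loss = LossConfig(weight = WeightConfig("soft"))))
  expect_true(all(diff(fit@trajectory) <= 0))
  expect_identical(fit@finalLoss, min(fit@trajectory))
})

test_that("training is deterministic given the seed", {
  scene <- SceneConfig(height = 16L, width = 20L, seed = 21L)
  truth <- generateTruth(scene)
  sup <- corruptTruth(truth, CorruptionConfig(occlusionBorderCols = 3L,
                                              blobCount = 2L,
                                              blobRadiusRange = c(2, 4),
                                              seed = 22L))
  cfg <- TrainConfig(maxSteps = 10L, augmentNoiseSd = 0.01, seed = 5L,
                     loss = LossConfig(weight = WeightConfig("hard")))
  f1 <- fitPredictor(list(sup), cfg)
  f2 <- fitPredictor(list(sup), cfg)
  expect_identical(f1@coefficients, f2@coefficients)
})

test_that("the hard-mask objective ignores values at sub-threshold pixels", {
  s <- randomSupervision(12, 14, 31, lowFrac = 0.3)
  pred <- randomMap(12, 14, 32)
  d <- mapValues(supDisparity(s$sup))
  d[s$lowIdx] <- d[s$lowIdx] + withSeed(33, runif(length(s$lowIdx), -80, 80))
  wild <- SupervisionFrame(InverseDepthMap(d), supConfidence(s$sup))
  cfg <- LossConfig(weight = WeightConfig("hard"))
  expect_identical(batchLoss(list(pred), list(s$sup), cfg)$total,
                   batchLoss(list(pred), list(wild), cfg)$total)
})

test_that("consistent flips leave the loss unchanged", {
  s <- randomSupervision(10, 12, 41)
  pred <- randomMap(10, 12, 42)
  cfg <- LossConfig(weight = WeightConfig("soft"))
  flipped <- SupervisionFrame(
    InverseDepthMap(flipLR(mapValues(supDisparity(s$sup)))),
    ConfidenceMap(flipLR(mapValues(supConfidence(s$sup)))))
  expect_equal(lossTotal(imageLoss(pred, s$sup, cfg)),
               lossTotal(imageLoss(InverseDepthMap(flipLR(mapValues(pred))),
                                   flipped, cfg)),
               tolerance = 1e-12)
})

test_that("a soft mask with zero sharpness trains identically to hard", {
  scene <- SceneConfig(height = 20L, width = 24L, seed = 51L)
  truth <- generateTruth(scene)
  frames <- lapply(1:2, function(i)
    corruptTruth(truth, CorruptionConfig(occlusionBorderCols = 3L,
                                         blobCount = 2L,
                                         blobRadiusRange = c(2, 4),
                                         seed = 60L + i)))
  mk <- function(kind, lambda) TrainConfig(
    maxSteps = 12L, seed = 9L,
    loss = LossConfig(weight = WeightConfig(kind, 0.5, lambda)))
  fHard <- fitPredictor(frames, mk("hard", 10))
  fSoft0 <- fitPredictor(frames, mk("soft", 0))
  expect_identical(fHard@coefficients, fSoft0@coefficients)
  expect_identical(fHard@trajectory, fSoft0@trajectory)
})

test_that("uncontaminated comparison shows no mask effect", {
  scene <- SceneConfig(height = 20L, width = 26L, seed = 71L)
  corr <- CorruptionConfig(occlusionBorderCols = 3L, blobCount = 0L,
                           inlierNoiseSd = 0, seed = 72L)
  rep <- runComparison(scene, corr,
                       TrainConfig(maxSteps = 30L,
                                   loss = LossConfig(weight = WeightConfig("soft"))),
                       nImages = 2L)
  expect_length(rep@failedArms, 0L)
  expect_true(all(rep@recoveryError < 1e-4))
  expect_lt(abs(rep@winMargin), 1e-4)
})
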