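test_that("confidence weights follow the mask definitions, boundary included", {
  hard <- WeightConfig("hard", threshold = 0.5)
  expect_equal(confidenceWeight(c(0.5, 0.499, 1, 0), hard), c(1, 0, 1, 0))

  soft <- WeightConfig("soft", threshold = 0.5, sharpness = 10)
  expect_equal(confidenceWeight(1, soft), 1)
  expect_equal(confidenceWeight(0.5, soft), exp(-5))
  expect_equal(confidenceWeight(0.49, soft), 0)

  unif <- WeightConfig("uniform")
  expect_equal(confidenceWeight(c(0, 0.2, 1), unif), c(1, 1, 1))

  expect_error(confidenceWeight(1.2, hard), class = "cwdepth_domain_error")
  expect_error(confidenceWeight(-0.1, soft), class = "cwdepth_domain_error")
})

test_that("confidence weights are non-decreasing in q for every mask", {
  q <- seq(0, 1, by = 0.01)
  for (cfg in list(WeightConfig("hard", 0.3), WeightConfig("soft", 0.3, 7),
                   WeightConfig("soft", 0.5, 0), WeightConfig("uniform"))) {
    w <- confidenceWeight(q, cfg)
    expect_true(all(diff(w) >= 0))
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("data term matches hand evaluation on a 2x2 image", {
  gt <- InverseDepthMap(matrix(0, 2, 2))
  pred <- InverseDepthMap(matrix(c(1, -1, 2, 0), 2, 2))
  mask <- ValidityMask(matrix(TRUE, 2, 2))
  unifConf <- ConfidenceMap(matrix(1, 2, 2))
  expect_equal(cwDataTerm(pred, gt, unifConf, mask, WeightConfig("uniform")),
               0.75)
  # hard mask zeroes the residual-2 pixel; M stays 4
  q <- matrix(1, 2, 2); q[mapValues(pred) == 2] <- 0.2
  expect_equal(cwDataTerm(pred, gt, ConfidenceMap(q), mask,
                          WeightConfig("hard", 0.5)), 0.25)
  # zero residual is zero loss whatever the confidences
  expect_equal(cwDataTerm(gt, gt, ConfidenceMap(q), mask,
                          WeightConfig("soft")), 0)
})

test_that("pyramids pool by 2x2 averages with all-valid validity", {
  mk <- function(m) InverseDepthMap(m)
  cb <- outer(1:4, 1:4, function(i, j) (-1)^(i + j))   # +1/-1 checkerboard
  pyr <- buildPyramid(mk(cb), mk(matrix(0, 4, 4)), matrix(1, 4, 4),
                      ValidityMask(matrix(TRUE, 4, 4)), 2L)
  expect_equal(pyr@levels[[2]]$residual, matrix(0, 2, 2))
  expect_true(all(pyr@levels[[2]]$valid))

  # constant residual survives every level
  pyr2 <- buildPyramid(mk(matrix(3, 8, 8)), mk(matrix(0, 8, 8)),
                       matrix(1, 8, 8), ValidityMask(matrix(TRUE, 8, 8)), 4L)
  for (lev in pyr2@levels) expect_true(all(lev$residual == 3))

  # K = 1 is exactly the full-resolution residual
  pyr3 <- buildPyramid(mk(cb), mk(matrix(0, 4, 4)), matrix(1, 4, 4),
                       ValidityMask(matrix(TRUE, 4, 4)), 1L)
  expect_length(pyr3@levels, 1L)
  expect_equal(pyr3@levels[[1]]$residual, cb)

  # too many levels truncate with a warning, never an error
  expect_warning(
    buildPyramid(mk(cb), mk(matrix(0, 4, 4)), matrix(1, 4, 4),
                 ValidityMask(matrix(TRUE, 4, 4)), 6L),
    class = "cwdepth_pyramid_truncated")
})

test_that("gradient term matches hand-computed forward differences", {
  # residual row [0, 1, 3, 3]: |1| + |2| + |0| over M = 4
  lev <- list(residual = matrix(c(0, 1, 3, 3), 1, 4),
              weight = matrix(1, 1, 4), valid = matrix(TRUE, 1, 4))
  expect_equal(cwGradientTerm(ScalePyramid(list(lev), 4L)), 0.75)

  # constant residual at every level vanishes
  levc <- list(residual = matrix(2, 3, 3), weight = matrix(1, 3, 3),
               valid = matrix(TRUE, 3, 3))
  expect_equal(cwGradientTerm(ScalePyramid(list(levc, levc), 9L)), 0)

  # an invalid pixel suppresses both differences through it
  levv <- list(residual = matrix(c(0, 1, 3, 3), 1, 4),
               weight = matrix(1, 1, 4),
               valid = matrix(c(TRUE, TRUE, FALSE, TRUE), 1, 4))
  expect_equal(cwGradientTerm(ScalePyramid(list(levv), 4L)), 0.25)
})

test_that("image loss vanishes for exact affine transforms of the target", {
  sup <- randomSupervision(8, 8, 41)$sup
  g <- mapValues(supDisparity(sup))
  cfg <- LossConfig(weight = WeightConfig("soft"))
  bl <- imageLoss(InverseDepthMap(7 * g + 2), sup, cfg)
  expect_lt(lossTotal(bl), 1e-12)
})

test_that("fully masked images contribute zero with a warning", {
  d <- randomMap(6, 6, 3)
  q <- ConfidenceMap(matrix(0.2, 6, 6))   # all below the 0.5 threshold
  sup <- SupervisionFrame(d, q)
  expect_warning(
    bl <- imageLoss(randomMap(6, 6, 4), sup,
                    LossConfig(weight = WeightConfig("hard"))),
    class = "cwdepth_degenerate_image")
  expect_identical(lossTotal(bl), 0)
  expect_identical(effectivePixels(bl), 0L)
})

test_that("image loss agrees with an independent loop reference", {
  for (seed in c(7, 19, 23)) {
    for (kind in c("uniform", "hard", "soft")) {
      s <- randomSupervision(8, 8, seed)
      pred <- plausiblePred(s$truth, seed + 5)
      cfg <- LossConfig(gradientWeight = 0.5, scaleLevels = 4L,
                        weight = WeightConfig(kind, 0.5, 10))
      bl <- imageLoss(pred, s$sup, cfg)
      ref <- refImageLoss(mapValues(pred), mapValues(supDisparity(s$sup)),
                          mapValues(supConfidence(s$sup)),
                          maskFlags(supMask(s$sup)),
                          kind, 0.5, 10, 0.5, 4L)
      expect_equal(lossTotal(bl), ref$total, tolerance = 1e-10)
      expect_equal(lossDataTerm(bl), ref$data, tolerance = 1e-10)
      expect_equal(lossGradientTerm(bl), ref$grad, tolerance = 1e-10)
    }
  }
})

test_that("the loss is invariant to scale and shift of the prediction", {
  for (seed in 1:8) {
    s <- randomSupervision(9, 11, seed)
    pred <- plausiblePred(s$truth, seed + 100)
    ab <- withSeed(seed + 200, c(runif(1, 0.1, 10), runif(1, -5, 5)))
    cfg <- LossConfig(weight = WeightConfig("soft"))
    l1 <- lossTotal(imageLoss(pred, s$sup, cfg))
    l2 <- lossTotal(imageLoss(
      InverseDepthMap(ab[1] * mapValues(pred) + ab[2]), s$sup, cfg))
    expect_lt(abs(l1 - l2) / max(l1, 1e-12), 1e-8)
  }
})

test_that("soft mask with zero sharpness reproduces the hard mask exactly", {
  s <- randomSupervision(8, 8, 77)
  pred <- plausiblePred(s$truth, 78)
  soft0 <- LossConfig(weight = WeightConfig("soft", 0.5, 0))
  hard <- LossConfig(weight = WeightConfig("hard", 0.5))
  expect_identical(lossTotal(imageLoss(pred, s$sup, soft0)),
                   lossTotal(imageLoss(pred, s$sup, hard)))
})

test_that("outliers at sub-threshold pixels damage only the uniform loss", {
  s <- randomSupervision(8, 8, 55, lowFrac = 0.3)
  pred <- plausiblePred(s$truth, 56)
  d <- mapValues(supDisparity(s$sup))
  d[s$lowIdx[1]] <- d[s$lowIdx[1]] + 8
  corrupted <- SupervisionFrame(InverseDepthMap(d), supConfidence(s$sup))
  for (kind in c("hard", "soft")) {
    cfg <- LossConfig(weight = WeightConfig(kind))
    expect_identical(lossTotal(imageLoss(pred, s$sup, cfg)),
                     lossTotal(imageLoss(pred, corrupted, cfg)))
  }
  unif <- LossConfig(weight = WeightConfig("uniform"))
  expect_gt(lossTotal(imageLoss(pred, corrupted, unif)),
            lossTotal(imageLoss(pred, s$sup, unif)))
})

test_that("batch loss is the mean of per-image totals", {
  s1 <- randomSupervision(8, 8, 61); s2 <- randomSupervision(8, 8, 62)
  p1 <- plausiblePred(s1$truth, 63); p2 <- plausiblePred(s2$truth, 64)
  cfg <- LossConfig(weight = WeightConfig("soft"))
  single <- batchLoss(list(p1), list(s1$sup), cfg)
  expect_identical(single$total, lossTotal(imageLoss(p1, s1$sup, cfg)))
  twice <- batchLoss(list(p1, p1), list(s1$sup, s1$sup), cfg)
  expect_equal(twice$total, single$total, tolerance = 1e-15)
  both <- batchLoss(list(p1, p2), list(s1$sup, s2$sup), cfg)
  expect_equal(both$total,
               mean(c(lossTotal(imageLoss(p1, s1$sup, cfg)),
                      lossTotal(imageLoss(p2, s2$sup, cfg)))),
               tolerance = 1e-12)
  expect_error(batchLoss(list(), list(), cfg), class = "cwdepth_empty_batch")
})

test_that("the loss is non-negative and zero only on weighted-zero residuals", {
  s <- randomSupervision(8, 8, 91)
  pred <- plausiblePred(s$truth, 92)
  cfg <- LossConfig(weight = WeightConfig("soft"))
  bl <- imageLoss(pred, s$sup, cfg)
  expect_gte(lossDataTerm(bl), 0)
  expect_gte(lossGradientTerm(bl), 0)
  expect_gt(lossTotal(bl), 0)
})
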