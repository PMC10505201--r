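test_that("closed-form alignment recovers exact affine relations", {
  g <- withSeed(2, matrix(runif(60, 1, 3), 6, 10))
  G <- InverseDepthMap(g)
  expect_equal(affineScale(alignLSQ(G, G)), 1, tolerance = 1e-12)
  expect_equal(affineShift(alignLSQ(G, G)), 0, tolerance = 1e-12)

  P <- InverseDepthMap((g - 3) / 2)
  a <- alignLSQ(P, G)
  expect_equal(affineScale(a), 2, tolerance = 1e-10)
  expect_equal(affineShift(a), 3, tolerance = 1e-10)
})

test_that("solver matches the brute-force grid-search oracle", {
  for (seed in 1:5) {
    withSeed(100 + seed, {
      n <- sample(5:20, 1)
      x <- runif(n, -2, 2)
      y <- runif(1, -3, 3) * x + runif(1, -4, 4) + rnorm(n, sd = 0.3)
    })
    P <- InverseDepthMap(matrix(c(x, x), ncol = 2))
    G <- InverseDepthMap(matrix(c(y, y), ncol = 2))
    mask <- ValidityMask(matrix(c(rep(TRUE, n), rep(FALSE, n)), ncol = 2))
    a <- alignLSQ(P, G, mask)
    oracle <- gridSearchLSQ(x, y)
    expect_lt(abs(affineScale(a) - oracle[["s"]]), 1e-3)
    expect_lt(abs(affineShift(a) - oracle[["t"]]), 1e-3)
  }
})

test_that("alignment is equivariant under affine reparameterisation", {
  for (seed in 1:6) {
    P <- randomMap(7, 9, seed)
    G <- randomMap(7, 9, seed + 50, lo = 2, hi = 5)
    a <- withSeed(seed, runif(1, 0.1, 10))
    b <- withSeed(seed + 7, runif(1, -5, 5))
    base <- alignLSQ(P, G)
    re <- alignLSQ(InverseDepthMap(a * mapValues(P) + b), G)
    expect_equal(affineScale(re), affineScale(base) / a, tolerance = 1e-9)
    expect_equal(affineShift(re),
                 affineShift(base) - affineScale(base) * b / a,
                 tolerance = 1e-9)
  }
})

test_that("aligned residuals satisfy the normal equations", {
  P <- randomMap(8, 8, 31); G <- randomMap(8, 8, 32)
  a <- alignLSQ(P, G)
  r <- mapValues(applyAffine(P, a)) - mapValues(G)
  scale <- sum(abs(mapValues(G)))
  expect_lt(abs(sum(r)) / scale, 1e-8)
  expect_lt(abs(sum(r * mapValues(P))) / scale, 1e-8)
  # idempotence: re-aligning the aligned prediction is the identity
  a2 <- alignLSQ(applyAffine(P, a), G)
  expect_equal(affineScale(a2), 1, tolerance = 1e-9)
  expect_equal(affineShift(a2), 0, tolerance = 1e-9)
})

test_that("applyAffine is elementwise and keeps invalid pixels invalid", {
  v <- matrix(c(5, NA, 1, 2), 2, 2)
  out <- mapValues(applyAffine(InverseDepthMap(v), AffineParams(2, 3)))
  expect_equal(out[1, 1], 13)
  expect_true(is.na(out[2, 1]))
  expect_identical(mapValues(applyAffine(InverseDepthMap(v),
                                         AffineParams(1, 0)))[c(1, 3, 4)],
                   v[c(1, 3, 4)])
})

test_that("degenerate alignment inputs raise classified errors", {
  G <- randomMap(4, 4, 9)
  flat <- InverseDepthMap(matrix(2, 4, 4))
  err <- tryCatch(alignLSQ(flat, G), condition = identity)
  expect_s3_class(err, "cwdepth_degenerate_input")
  expect_equal(err$fallbackShift, mean(mapValues(G)) - 2, tolerance = 1e-12)

  tiny <- ValidityMask(matrix(c(TRUE, rep(FALSE, 15)), 4, 4))
  expect_error(alignLSQ(G, G, tiny), class = "cwdepth_insufficient_data")
})

test_that("biweight weights hit their endpoints", {
  expect_equal(tukeyBiweight(0), 1)
  expect_equal(tukeyBiweight(c(4.685, -4.685, 10)), c(0, 0, 0))
  expect_equal(tukeyBiweight(2.5, c = 5), (1 - 0.25)^2)
})

test_that("IRLS equals least squares in the clean limit", {
  P <- randomMap(10, 10, 21)
  # exact affine relation, no contamination
  G <- InverseDepthMap(2.5 * mapValues(P) - 0.75)
  lsq <- alignLSQ(P, G)
  rob <- alignIRLS(P, G)
  expect_lt(abs(affineScale(rob) - affineScale(lsq)), 1e-6)
  expect_lt(abs(affineShift(rob) - affineShift(lsq)), 1e-6)

  # vanishing noise, still no outliers
  Gn <- InverseDepthMap(mapValues(G) + withSeed(23, rnorm(100, sd = 1e-8)))
  lsqN <- alignLSQ(P, Gn); robN <- alignIRLS(P, Gn)
  expect_lt(abs(affineScale(robN) - affineScale(lsqN)), 1e-6)
  expect_lt(abs(affineShift(robN) - affineShift(lsqN)), 1e-6)
})

test_that("IRLS resists gross outliers that break least squares", {
  withSeed(77, {
    x <- rnorm(200)
    y <- 2 * x + 3 + rnorm(200, sd = 0.01)
    idx <- sample.int(200, 40)
    y[idx] <- y[idx] + 50
  })
  P <- InverseDepthMap(matrix(x, 10)); G <- InverseDepthMap(matrix(y, 10))
  rob <- alignIRLS(P, G)
  lsq <- alignLSQ(P, G)
  expect_lt(abs(affineScale(rob) - 2), 0.05)
  expect_lt(abs(affineShift(rob) - 3), 0.05)
  expect_gt(max(abs(affineScale(lsq) - 2), abs(affineShift(lsq) - 3)), 0.5)
})

test_that("IRLS agrees with an established robust-regression fit", {
  withSeed(13, {
    x <- rnorm(300)
    y <- 1.5 * x - 2 + rnorm(300)
    y[1:30] <- y[1:30] - 25
  })
  rob <- alignIRLS(InverseDepthMap(matrix(x, 15)),
                   InverseDepthMap(matrix(y, 15)))
  ref <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685, maxit = 100)
  expect_equal(affineScale(rob), unname(coef(ref)[2]), tolerance = 0.02)
  expect_equal(affineShift(rob), unname(coef(ref)[1]), tolerance = 0.02)
})

test_that("biweight efficiency degenerates to 1 for huge tuning constants", {
  eff <- simulateBiweightEfficiency(500L, 200L,
                                    IRLSConfig(tuningConstant = 1e6), 3L)
  expect_lt(abs(eff - 1), 0.01)
})

test_that("a harsher tuning constant costs efficiency", {
  effHarsh <- simulateBiweightEfficiency(500L, 300L,
                                         IRLSConfig(tuningConstant = 1), 9L)
  effStd <- simulateBiweightEfficiency(500L, 300L, IRLSConfig(), 9L)
  expect_lt(effHarsh, effStd)
})
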