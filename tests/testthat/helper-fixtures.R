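# Fixtures are generated in code, seeded, at test time.

randomMap <- function(h, w, seed, lo = 0.5, hi = 2) {
  withSeed(seed, InverseDepthMap(matrix(runif(h * w, lo, hi), h, w)))
}

# supervision with mixed confidence: a share of pixels below `theta`
randomSupervision <- function(h, w, seed, lowFrac = 0.25, theta = 0.5,
                              noiseSd = 0.05) {
  withSeed(seed, {
    truth <- matrix(runif(h * w, 0.5, 2), h, w)
    d <- truth + rnorm(h * w, sd = noiseSd)
    q <- matrix(runif(h * w, theta, 1), h, w)
    nLow <- round(lowFrac * h * w)
    lowIdx <- sample.int(h * w, nLow)
    q[lowIdx] <- runif(nLow, 0.01, theta - 0.01)
    list(sup = SupervisionFrame(InverseDepthMap(d), ConfidenceMap(q)),
         truth = InverseDepthMap(truth), lowIdx = lowIdx)
  })
}

# Brute-force 2-D grid-search minimiser of sum((s x + t - y)^2), refined by
# repeated zooming; independent of the closed-form normal-equation solve.
gridSearchLSQ <- function(x, y, sRange = c(-10, 10), tRange = c(-10, 10),
                          rounds = 7L, gridN = 61L) {
  sse <- function(s, t) {
    n <- length(x)
    s^2 * sum(x^2) + 2 * s * t * sum(x) - 2 * s * sum(x * y) +
      t^2 * n - 2 * t * sum(y) + sum(y^2)
  }
  for (r in seq_len(rounds)) {
    ss <- seq(sRange[1], sRange[2], length.out = gridN)
    tt <- seq(tRange[1], tRange[2], length.out = gridN)
    grid <- outer(ss, tt, Vectorize(sse))
    ij <- arrayInd(which.min(grid), dim(grid))
    sBest <- ss[ij[1]]; tBest <- tt[ij[2]]
    sStep <- ss[2] - ss[1]; tStep <- tt[2] - tt[1]
    sRange <- c(sBest - 2 * sStep, sBest + 2 * sStep)
    tRange <- c(tBest - 2 * tStep, tBest + 2 * tStep)
  }
  c(s = sBest, t = tBest)
}

# Independent single-pass reference for the per-image loss: explicit loops,
# solve() on the 2x2 normal matrix, block-loop pooling. Mirrors the
# documented conventions only, never the package internals.
refImageLoss <- function(pred, d, q, valid, kind, theta, lambda, alpha, K) {
  h <- nrow(pred); w <- ncol(pred)
  wgt <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    wgt[i, j] <- switch(kind,
      uniform = 1,
      hard = as.numeric(q[i, j] >= theta),
      soft = if (q[i, j] >= theta) exp(lambda * (q[i, j] - 1)) else 0)
  }
  support <- valid & wgt > 0
  xs <- pred[support]; ys <- d[support]
  A <- matrix(c(sum(xs^2), sum(xs), sum(xs), length(xs)), 2, 2)
  st <- solve(A, c(sum(xs * ys), sum(ys)))
  if (st[1] <= 0) return(list(data = 0, grad = 0, total = 0))
  pa <- st[1] * pred + st[2]
  M <- sum(valid)
  dataTerm <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) if (valid[i, j])
    dataTerm <- dataTerm + wgt[i, j] * (pa[i, j] - d[i, j])^2
  dataTerm <- dataTerm / (2 * M)

  # gradient term: only pixels that are valid AND positively weighted are
  # active; inactive pixels anchor nothing and are excluded from pooling
  active <- valid & wgt > 0
  R <- pa - d; R[!active] <- NA
  W <- wgt; W[!active] <- 0
  V <- active
  gradTerm <- 0
  for (k in seq_len(K)) {
    hh <- nrow(R); ww <- ncol(R)
    for (i in seq_len(hh)) for (j in seq_len(ww)) {
      if (j < ww && V[i, j] && V[i, j + 1])
        gradTerm <- gradTerm +
          (W[i, j] + W[i, j + 1]) / 2 * abs(R[i, j + 1] - R[i, j])
      if (i < hh && V[i, j] && V[i + 1, j])
        gradTerm <- gradTerm +
          (W[i, j] + W[i + 1, j]) / 2 * abs(R[i + 1, j] - R[i, j])
    }
    if (k == K) break
    h2 <- ceiling(hh / 2); w2 <- ceiling(ww / 2)
    R2 <- matrix(NA_real_, h2, w2); W2 <- matrix(0, h2, w2)
    V2 <- matrix(FALSE, h2, w2)
    for (i in seq_len(h2)) for (j in seq_len(w2)) {
      ri <- (2 * i - 1):min(2 * i, hh); rj <- (2 * j - 1):min(2 * j, ww)
      vs <- V[ri, rj]; rs <- R[ri, rj]; wsub <- W[ri, rj]
      V2[i, j] <- all(vs)
      if (any(vs)) R2[i, j] <- mean(rs[vs])
      W2[i, j] <- mean(wsub)   # invalid children already carry weight 0
    }
    R <- R2; W <- W2; V <- V2
  }
  gradTerm <- gradTerm / M
  list(data = dataTerm, grad = gradTerm,
       total = dataTerm + alpha * gradTerm)
}

flipLR <- function(m) m[, ncol(m):1, drop = FALSE]

# a plausible prediction: positively correlated with the underlying truth,
# up to an arbitrary affine transform plus noise
plausiblePred <- function(truth, seed, noiseSd = 0.1) {
  v <- mapValues(truth)
  withSeed(seed, InverseDepthMap(
    runif(1, 0.5, 2) * v + runif(1, -1, 1) + rnorm(length(v), sd = noiseSd)))
}
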