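# Affine (scale, shift) alignment in inverse-depth space.
#
# Monocular predictions are defined only up to s * d + t; both the training
# loss and the evaluation protocol first fit (s, t) against the supervisory
# signal. The loss uses the closed-form least-squares fit; evaluation uses a
# robust IRLS fit with Tukey biweight weights so gross supervisory outliers
# do not drag the alignment.

.validVec <- function(pred, gt, mask) {
  p <- mapValues(pred); g <- mapValues(gt)
  if (!identical(dim(p), dim(g)))
    .stopc("cwdepth_dimension_error", "prediction and target shapes differ")
  f <- maskFlags(mask)
  if (!identical(dim(f), dim(p)))
    .stopc("cwdepth_dimension_error", "mask shape differs from maps")
  keep <- f & is.finite(p) & is.finite(g)
  list(x = p[keep], y = g[keep])
}

# Closed-form weighted least squares for y ~ s x + t. Returns NULL when the
# 2x2 normal system is singular (x effectively constant under w).
.wlsFit <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  sw <- sum(w)
  if (sw <= 0) return(NULL)
  sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x * x); sxy <- sum(w * x * y)
  denom <- sw * sxx - sx * sx
  if (!is.finite(denom) || abs(denom) <= 1e-12 * max(sw * sxx, sx * sx, 1))
    return(NULL)
  s <- (sw * sxy - sx * sy) / denom
  t <- (sy - s * sx) / sw
  c(s = s, t = t)
}

#' Least-squares scale/shift alignment
#'
#' Unique minimiser of \eqn{\sum_i (s d_i + t - d^*_i)^2} over valid pixels,
#' from the 2 x 2 normal equations.
#'
#' @param pred predicted \linkS4class{InverseDepthMap}.
#' @param gt target \linkS4class{InverseDepthMap}.
#' @param mask a \linkS4class{ValidityMask}; defaults to pixels where both
#'   maps are finite.
#' @return an \linkS4class{AffineParams}.
#' @export
alignLSQ <- function(pred, gt, mask = NULL) {
  if (is.null(mask))
    mask <- ValidityMask(is.finite(mapValues(pred)) & is.finite(mapValues(gt)))
  v <- .validVec(pred, gt, mask)
  if (length(v$x) < 2L)
    .stopc("cwdepth_insufficient_data",
           sprintf("need >= 2 valid pixels, have %d", length(v$x)))
  fit <- .wlsFit(v$x, v$y)
  if (is.null(fit))
    .stopc("cwdepth_degenerate_input",
           "constant prediction over valid pixels: scale is unidentifiable",
           fallbackShift = mean(v$y) - mean(v$x))
  AffineParams(fit[["s"]], fit[["t"]])
}

#' Apply an affine (scale, shift) transform to a map
#'
#' Elementwise \code{s * pred + t}; invalid (non-finite) pixels stay invalid.
#'
#' @param pred an \linkS4class{InverseDepthMap}.
#' @param params an \linkS4class{AffineParams}.
#' @return an \linkS4class{InverseDepthMap}.
#' @export
applyAffine <- function(pred, params) {
  InverseDepthMap(params@s * mapValues(pred) + params@t)
}

#' Tukey biweight weight function
#'
#' \eqn{w(u) = (1 - (u/c)^2)^2} for \eqn{|u| < c}, 0 beyond: a redescending
#' weight that removes gross outliers entirely from the reweighted fit.
#'
#' @param u standardised residuals.
#' @param c positive tuning constant; 4.685 gives about 95\% efficiency
#'   under Gaussian errors.
#' @return weights in [0, 1].
#' @export
tukeyBiweight <- function(u, c = 4.685) {
  stopifnot(c > 0)
  w <- (1 - (u / c)^2)^2
  w[abs(u) >= c] <- 0
  w
}

# IRLS core on plain vectors; shared by alignIRLS and the efficiency
# simulation. Regresses y on x with Tukey biweight weights; residual scale
# is MAD/0.6745 recomputed each iteration, with a mean-|r| fallback when
# the MAD collapses to zero.
.irlsFit <- function(x, y, cfg) {
  fit <- .wlsFit(x, y)
  if (is.null(fit))
    .stopc("cwdepth_degenerate_input", "singular system at IRLS start")
  st <- fit
  iter <- 0L
  converged <- FALSE
  while (iter < cfg@maxIterations) {
    iter <- iter + 1L
    r <- y - st[["s"]] * x - st[["t"]]
    scale <- stats::mad(r, center = 0, constant = 1 / 0.6745)
    if (scale <= 0) scale <- mean(abs(r))
    if (scale <= 0) { converged <- TRUE; break }  # exact fit
    w <- tukeyBiweight(r / scale, cfg@tuningConstant)
    if (all(w == 0))
      .stopc("cwdepth_robust_degeneracy",
             sprintf("all biweight weights vanished at iteration %d", iter),
             iteration = iter)
    new <- .wlsFit(x, y, w)
    if (is.null(new))
      .stopc("cwdepth_degenerate_input",
             sprintf("singular weighted system at iteration %d", iter))
    delta <- max(abs(new - st) / pmax(1, abs(st)))
    st <- new
    if (delta < cfg@relativeTolerance) { converged <- TRUE; break }
  }
  list(s = st[["s"]], t = st[["t"]], iterations = iter,
       converged = converged)
}

#' Robust IRLS scale/shift alignment (Tukey biweight)
#'
#' Iteratively reweighted least squares for \code{gt ~ s * pred + t},
#' starting from the closed-form least-squares fit. With no contamination
#' the result coincides with \code{\link{alignLSQ}}; with gross outliers the
#' redescending biweight drives their weights to zero.
#'
#' @inheritParams alignLSQ
#' @param cfg an \linkS4class{IRLSConfig}.
#' @return an \linkS4class{AffineParams} with iteration count.
#' @export
alignIRLS <- function(pred, gt, mask = NULL, cfg = IRLSConfig()) {
  if (is.null(mask))
    mask <- ValidityMask(is.finite(mapValues(pred)) & is.finite(mapValues(gt)))
  v <- .validVec(pred, gt, mask)
  if (length(v$x) < 2L)
    .stopc("cwdepth_insufficient_data",
           sprintf("need >= 2 valid pixels, have %d", length(v$x)))
  fit <- .irlsFit(v$x, v$y, cfg)
  AffineParams(fit$s, fit$t, iterations = fit$iterations,
               converged = fit$converged)
}

#' Monte-Carlo efficiency of the biweight slope estimator
#'
#' Simulates \code{reps} simple linear regressions with standard-normal
#' errors and no outliers, fits each by OLS and by IRLS with Tukey biweight
#' weights, and returns the variance ratio
#' Var(OLS slope) / Var(IRLS slope). At the default tuning constant 4.685
#' the biweight pays about a 5\% efficiency premium for its robustness, so
#' the ratio sits near 0.95; as the tuning constant grows the biweight
#' degenerates to OLS and the ratio approaches 1.
#'
#' @param n observations per regression (>= 100).
#' @param reps number of replicates (>= 100).
#' @param cfg an \linkS4class{IRLSConfig}.
#' @param seed integer RNG seed.
#' @return efficiency ratio in (0, 1.05).
#' @export
simulateBiweightEfficiency <- function(n = 2000L, reps = 2000L,
                                       cfg = IRLSConfig(), seed = 1L) {
  stopifnot(n >= 100L, reps >= 100L)
  slopeOLS <- numeric(reps)
  slopeIRLS <- numeric(reps)
  withSeed(seed, {
    for (r in seq_len(reps)) {
      x <- stats::rnorm(n)
      y <- 1 + 2 * x + stats::rnorm(n)
      slopeOLS[r] <- .wlsFit(x, y)[["s"]]
      slopeIRLS[r] <- .irlsFit(x, y, cfg)$s
    }
  })
  stats::var(slopeOLS) / stats::var(slopeIRLS)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so
#' seeded generators do not perturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
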