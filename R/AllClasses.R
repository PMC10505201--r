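#' @import methods
NULL

# Internal condition helper: all package errors carry a subclass so callers
# (and tests) can dispatch on the failure mode rather than on message text.
.stopc <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "cwdepth_error")))
}

.warnc <- function(class, msg, ...) {
  warning(warningCondition(msg, ..., class = c(class, "cwdepth_warning")))
}

#' Dense inverse-depth / disparity map
#'
#' A 2-D grid of per-pixel values in inverse-depth (disparity) space. Both
#' model predictions and stereo-derived supervisory signals live here:
#' monocular predictions are defined only up to an affine (scale, shift)
#' transform of true inverse depth, and rectified stereo disparity is itself
#' proportional to inverse depth. Non-finite values mark pixels where no
#' estimate exists (e.g. the unmatched occlusion band of a stereo pair).
#'
#' The grid is stored row-major with the origin at the top-left pixel;
#' bottom-up file formats (PFM) are normalised to this convention on read.
#'
#' @slot values numeric matrix, at least 2 x 2.
#' @export
setClass("InverseDepthMap", representation(values = "matrix"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be a numeric matrix")
    if (nrow(v) < 2L || ncol(v) < 2L) return("map must be at least 2 x 2")
    TRUE
  })

#' @describeIn InverseDepthMap-class Constructor.
#' @param values numeric matrix of inverse-depth values.
#' @export
InverseDepthMap <- function(values) {
  new("InverseDepthMap", values = as.matrix(values) * 1.0)
}

#' Per-pixel confidence map
#'
#' Confidence \eqn{q \in [0, 1]} attached to each pixel of a supervisory
#' disparity map. Zero marks pixels where disparity was never computed
#' (unmatched / occluded); low positive values flag unreliable matches
#' (droplets, smoke, specular highlights); values near 1 mark reliable
#' stereo matches.
#'
#' @slot values numeric matrix with all entries in [0, 1].
#' @export
setClass("ConfidenceMap", representation(values = "matrix"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be a numeric matrix")
    if (anyNA(v) || any(!is.finite(v))) return("confidence must be finite")
    if (any(v < 0) || any(v > 1)) return("confidence must lie in [0, 1]")
    TRUE
  })

#' @describeIn ConfidenceMap-class Constructor.
#' @param values numeric matrix of confidences in [0, 1].
#' @export
ConfidenceMap <- function(values) {
  new("ConfidenceMap", values = as.matrix(values) * 1.0)
}

#' Validity mask
#'
#' Boolean flags marking pixels that carry usable ground truth: the count of
#' \code{TRUE} flags is the denominator M of the per-image loss terms.
#'
#' @slot flags logical matrix.
#' @slot countValid integer, number of \code{TRUE} flags.
#' @export
setClass("ValidityMask",
  representation(flags = "matrix", countValid = "integer"),
  validity = function(object) {
    f <- object@flags
    if (!is.logical(f)) return("flags must be a logical matrix")
    if (anyNA(f)) return("flags must not contain NA")
    if (object@countValid != sum(f)) return("countValid must equal sum(flags)")
    TRUE
  })

#' @describeIn ValidityMask-class Constructor.
#' @param flags logical matrix of per-pixel validity.
#' @export
ValidityMask <- function(flags) {
  flags <- as.matrix(flags)
  storage.mode(flags) <- "logical"
  new("ValidityMask", flags = flags, countValid = as.integer(sum(flags)))
}

#' A self-supervisory signal: disparity, confidence, validity
#'
#' Bundles one supervisory frame as produced by a stereo matcher: the
#' disparity estimate, its per-pixel confidence, and the validity mask
#' derived from the two (finite disparity and strictly positive confidence).
#'
#' @slot disparity an \linkS4class{InverseDepthMap}.
#' @slot confidence a \linkS4class{ConfidenceMap} of identical shape.
#' @slot mask a \linkS4class{ValidityMask} of identical shape.
#' @export
setClass("SupervisionFrame",
  representation(disparity = "InverseDepthMap",
                 confidence = "ConfidenceMap",
                 mask = "ValidityMask"),
  validity = function(object) {
    d <- object@disparity@values
    q <- object@confidence@values
    f <- object@mask@flags
    if (!identical(dim(d), dim(q)) || !identical(dim(d), dim(f)))
      return("disparity, confidence and mask must share one shape")
    bad <- f & (q == 0 | !is.finite(d))
    if (any(bad))
      return("mask must be FALSE wherever confidence is 0 or disparity non-finite")
    TRUE
  })

#' @describeIn SupervisionFrame-class Constructor; the mask defaults to
#'   \code{buildValidityMask(disparity, confidence)}.
#' @param disparity an \linkS4class{InverseDepthMap}.
#' @param confidence a \linkS4class{ConfidenceMap}.
#' @param mask optional \linkS4class{ValidityMask}; rebuilt when missing.
#' @export
SupervisionFrame <- function(disparity, confidence, mask = NULL) {
  if (is.null(mask)) mask <- buildValidityMask(disparity, confidence)
  new("SupervisionFrame", disparity = disparity, confidence = confidence,
      mask = mask)
}

#' Affine (scale, shift) alignment parameters
#'
#' The pair (s, t) mapping a prediction d to s d + t in inverse-depth space.
#' Robust fits additionally record the iteration count and convergence flag.
#'
#' @slot s numeric scale.
#' @slot t numeric shift.
#' @slot iterations integer, 0 for the closed-form least-squares fit.
#' @slot converged logical.
#' @export
setClass("AffineParams",
  representation(s = "numeric", t = "numeric", iterations = "integer",
                 converged = "logical"),
  validity = function(object) {
    if (length(object@s) != 1L || length(object@t) != 1L)
      return("s and t must be scalars")
    if (!is.finite(object@s) || !is.finite(object@t))
      return("s and t must be finite")
    TRUE
  })

#' @describeIn AffineParams-class Constructor.
#' @param s scale.
#' @param t shift.
#' @param iterations iterations used by an iterative fit (0 = closed form).
#' @param converged whether the iterative fit converged.
#' @export
AffineParams <- function(s, t, iterations = 0L, converged = TRUE) {
  new("AffineParams", s = as.numeric(s), t = as.numeric(t),
      iterations = as.integer(iterations), converged = converged)
}

#' IRLS configuration for robust affine alignment
#'
#' Controls the iteratively reweighted least-squares fit with Tukey biweight
#' weights used by the evaluation protocol. The default tuning constant
#' 4.685 gives the biweight roughly 95\% asymptotic efficiency under
#' Gaussian errors. The residual scale is re-estimated each iteration as
#' MAD / 0.6745 (falling back to the mean absolute residual when the MAD is
#' zero).
#'
#' @slot tuningConstant positive numeric; biweight cut-off c.
#' @slot maxIterations positive integer.
#' @slot relativeTolerance positive numeric stopping tolerance on (s, t).
#' @slot scaleEstimator character; currently \code{"mad"}.
#' @export
setClass("IRLSConfig",
  representation(tuningConstant = "numeric", maxIterations = "integer",
                 relativeTolerance = "numeric", scaleEstimator = "character"),
  validity = function(object) {
    if (object@tuningConstant <= 0) return("tuningConstant must be > 0")
    if (object@maxIterations < 1L) return("maxIterations must be >= 1")
    if (object@relativeTolerance <= 0) return("relativeTolerance must be > 0")
    if (!object@scaleEstimator %in% "mad")
      return("unknown scaleEstimator")
    TRUE
  })

#' @describeIn IRLSConfig-class Constructor.
#' @param tuningConstant biweight tuning constant c (default 4.685).
#' @param maxIterations iteration cap (default 50).
#' @param relativeTolerance relative stopping tolerance (default 1e-8).
#' @param scaleEstimator residual-scale rule (default \code{"mad"}).
#' @export
IRLSConfig <- function(tuningConstant = 4.685, maxIterations = 50L,
                       relativeTolerance = 1e-8, scaleEstimator = "mad") {
  new("IRLSConfig", tuningConstant = as.numeric(tuningConstant),
      maxIterations = as.integer(maxIterations),
      relativeTolerance = as.numeric(relativeTolerance),
      scaleEstimator = scaleEstimator)
}

#' Confidence-weight configuration
#'
#' Selects how supervisory confidence q maps to a loss weight w(q):
#' \describe{
#'   \item{hard}{w = 1 for q >= threshold, else 0 (sub-threshold pixels are
#'     dropped, the rest count uniformly).}
#'   \item{soft}{w = exp(sharpness * (q - 1)) for q >= threshold, else 0
#'     (kept pixels are graded by confidence).}
#'   \item{uniform}{w = 1 everywhere; confidence is ignored.}
#' }
#' The boundary q == threshold is included (weight > 0).
#'
#' @slot maskKind character, one of \code{"hard"}, \code{"soft"},
#'   \code{"uniform"}.
#' @slot threshold numeric in [0, 1]; confidence cut-off (default 0.5).
#' @slot sharpness non-negative numeric; soft-mask exponent rate
#'   (default 10).
#' @export
setClass("WeightConfig",
  representation(maskKind = "character", threshold = "numeric",
                 sharpness = "numeric"),
  validity = function(object) {
    if (!object@maskKind %in% c("hard", "soft", "uniform"))
      return("maskKind must be 'hard', 'soft' or 'uniform'")
    if (object@threshold < 0 || object@threshold > 1)
      return("threshold must lie in [0, 1]")
    if (object@sharpness < 0) return("sharpness must be >= 0")
    TRUE
  })

#' @describeIn WeightConfig-class Constructor.
#' @param maskKind one of \code{"hard"}, \code{"soft"}, \code{"uniform"}.
#' @param threshold confidence cut-off in [0, 1].
#' @param sharpness soft-mask exponent rate (ignored by hard/uniform).
#' @export
WeightConfig <- function(maskKind = c("hard", "soft", "uniform"),
                         threshold = 0.5, sharpness = 10) {
  maskKind <- match.arg(maskKind)
  new("WeightConfig", maskKind = maskKind, threshold = as.numeric(threshold),
      sharpness = as.numeric(sharpness))
}

#' Loss configuration
#'
#' @slot gradientWeight non-negative numeric; weight of the multi-scale
#'   gradient-matching term (default 0.5).
#' @slot scaleLevels positive integer; number of pyramid levels, resolution
#'   halving at each (default 4).
#' @slot weight a \linkS4class{WeightConfig}.
#' @export
setClass("LossConfig",
  representation(gradientWeight = "numeric", scaleLevels = "integer",
                 weight = "WeightConfig"),
  validity = function(object) {
    if (object@gradientWeight < 0) return("gradientWeight must be >= 0")
    if (object@scaleLevels < 1L) return("scaleLevels must be >= 1")
    TRUE
  })

#' @describeIn LossConfig-class Constructor.
#' @param gradientWeight gradient-term weight (default 0.5).
#' @param scaleLevels pyramid levels (default 4).
#' @param weight a \linkS4class{WeightConfig}.
#' @export
LossConfig <- function(gradientWeight = 0.5, scaleLevels = 4L,
                       weight = WeightConfig("hard")) {
  new("LossConfig", gradientWeight = as.numeric(gradientWeight),
      scaleLevels = as.integer(scaleLevels), weight = weight)
}

#' Per-image loss breakdown
#'
#' @slot dataTerm non-negative numeric; confidence-weighted mean squared
#'   residual after alignment.
#' @slot gradientTerm non-negative numeric; multi-scale gradient term.
#' @slot total numeric; dataTerm + gradientWeight * gradientTerm.
#' @slot effectivePixels integer; valid pixels with positive weight.
#' @export
setClass("LossBreakdown",
  representation(dataTerm = "numeric", gradientTerm = "numeric",
                 total = "numeric", effectivePixels = "integer"),
  validity = function(object) {
    if (object@dataTerm < 0 || object@gradientTerm < 0 || object@total < 0)
      return("loss terms must be non-negative")
    TRUE
  })

LossBreakdown <- function(dataTerm, gradientTerm, total, effectivePixels) {
  new("LossBreakdown", dataTerm = as.numeric(dataTerm),
      gradientTerm = as.numeric(gradientTerm), total = as.numeric(total),
      effectivePixels = as.integer(effectivePixels))
}

#' Residual scale pyramid
#'
#' Ordered levels of (residual, weight, validity) grids; level 1 is full
#' resolution and each further level halves both dimensions (rounding up)
#' by 2 x 2 average pooling. A pooled pixel is valid only when all of its
#' children are valid.
#'
#' @slot levels list; each element a list with elements \code{residual},
#'   \code{weight}, \code{valid} (matrices of one shape).
#' @slot fullResValid integer; valid-pixel count M at full resolution.
#' @export
setClass("ScalePyramid",
  representation(levels = "list", fullResValid = "integer"),
  validity = function(object) {
    if (length(object@levels) < 1L) return("pyramid needs >= 1 level")
    TRUE
  })

ScalePyramid <- function(levels, fullResValid) {
  new("ScalePyramid", levels = levels,
      fullResValid = as.integer(fullResValid))
}

#' Scale- and shift-invariant depth metrics for one image or set
#'
#' @slot absRel non-negative numeric; mean |pred - gt| / gt over evaluated
#'   depth pixels.
#' @slot delta1,delta2,delta3 numerics in [0, 1]; fractions of pixels whose
#'   larger depth ratio is strictly below 1.25, 1.25^2, 1.25^3.
#' @slot pixelsEvaluated integer.
#' @export
setClass("MetricsReport",
  representation(absRel = "numeric", delta1 = "numeric", delta2 = "numeric",
                 delta3 = "numeric", pixelsEvaluated = "integer"),
  validity = function(object) {
    d <- c(object@delta1, object@delta2, object@delta3)
    if (any(d < 0) || any(d > 1)) return("deltas must lie in [0, 1]")
    if (object@delta1 > object@delta2 + 1e-12 ||
        object@delta2 > object@delta3 + 1e-12)
      return("deltas must be nested: delta1 <= delta2 <= delta3")
    if (object@absRel < 0) return("absRel must be >= 0")
    TRUE
  })

MetricsReport <- function(absRel, delta1, delta2, delta3, pixelsEvaluated) {
  new("MetricsReport", absRel = as.numeric(absRel),
      delta1 = as.numeric(delta1), delta2 = as.numeric(delta2),
      delta3 = as.numeric(delta3),
      pixelsEvaluated = as.integer(pixelsEvaluated))
}

#' Synthetic scene configuration
#'
#' Describes the smooth true inverse-depth surface the generator emulates:
#' a low-order random polynomial over normalised pixel coordinates, rescaled
#' into \code{invDepthRange}. Default resolution 192 x 384 mirrors common
#' rectified endoscopic stereo frames.
#'
#' @slot height,width positive integers.
#' @slot surfaceOrder small non-negative integer; polynomial order.
#' @slot invDepthRange numeric length-2, 0 < low < high.
#' @slot seed integer RNG seed.
#' @export
setClass("SceneConfig",
  representation(height = "integer", width = "integer",
                 surfaceOrder = "integer", invDepthRange = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@height < 2L || object@width < 2L)
      return("height and width must be >= 2")
    if (object@surfaceOrder < 0L) return("surfaceOrder must be >= 0")
    r <- object@invDepthRange
    if (length(r) != 2L || r[1] <= 0 || r[1] >= r[2])
      return("invDepthRange must satisfy 0 < low < high")
    TRUE
  })

#' @describeIn SceneConfig-class Constructor.
#' @param height,width image dimensions in pixels.
#' @param surfaceOrder polynomial order of the true surface (default 2).
#' @param invDepthRange range of true inverse depth (default c(0.5, 2)).
#' @param seed RNG seed.
#' @export
SceneConfig <- function(height = 192L, width = 384L, surfaceOrder = 2L,
                        invDepthRange = c(0.5, 2), seed = 1L) {
  new("SceneConfig", height = as.integer(height), width = as.integer(width),
      surfaceOrder = as.integer(surfaceOrder),
      invDepthRange = as.numeric(invDepthRange), seed = as.integer(seed))
}

#' Supervision corruption configuration
#'
#' Encodes the failure structure of stereo supervisory signals in surgical
#' scenes: a zero-confidence occlusion band at the left image border where
#' disparity is never computed, low-confidence blob regions (droplets,
#' smoke, specularities) whose disparity carries gross errors, and
#' high-confidence regions carrying only small Gaussian noise.
#'
#' @slot occlusionBorderCols non-negative integer.
#' @slot blobCount non-negative integer.
#' @slot blobRadiusRange numeric length-2 (pixels).
#' @slot outlierMagnitude positive numeric; gross-error scale.
#' @slot inlierNoiseSd non-negative numeric.
#' @slot confHighRange,confLowRange numeric length-2 sub-intervals of [0, 1];
#'   the low interval must lie entirely below the high one.
#' @slot seed integer RNG seed.
#' @export
setClass("CorruptionConfig",
  representation(occlusionBorderCols = "integer", blobCount = "integer",
                 blobRadiusRange = "numeric", outlierMagnitude = "numeric",
                 inlierNoiseSd = "numeric", confHighRange = "numeric",
                 confLowRange = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@occlusionBorderCols < 0L) return("occlusionBorderCols >= 0")
    if (object@blobCount < 0L) return("blobCount must be >= 0")
    r <- object@blobRadiusRange
    if (length(r) != 2L || r[1] <= 0 || r[1] > r[2])
      return("blobRadiusRange must satisfy 0 < min <= max")
    if (object@outlierMagnitude <= 0) return("outlierMagnitude must be > 0")
    if (object@inlierNoiseSd < 0) return("inlierNoiseSd must be >= 0")
    lo <- object@confLowRange; hi <- object@confHighRange
    if (any(c(lo, hi) < 0) || any(c(lo, hi) > 1))
      return("confidence ranges must lie in [0, 1]")
    if (lo[1] > lo[2] || hi[1] > hi[2]) return("confidence ranges reversed")
    if (lo[2] >= hi[1])
      return("confLowRange must lie entirely below confHighRange")
    TRUE
  })

#' @describeIn CorruptionConfig-class Constructor.
#' @param occlusionBorderCols width of the left zero-confidence band.
#' @param blobCount number of low-confidence outlier blobs.
#' @param blobRadiusRange blob radius range in pixels.
#' @param outlierMagnitude gross disparity-error scale inside blobs.
#' @param inlierNoiseSd Gaussian noise sd outside blobs.
#' @param confHighRange confidence interval for reliable pixels.
#' @param confLowRange confidence interval for blob pixels.
#' @param seed RNG seed.
#' @export
CorruptionConfig <- function(occlusionBorderCols = 8L, blobCount = 5L,
                             blobRadiusRange = c(3, 8),
                             outlierMagnitude = 5, inlierNoiseSd = 0.02,
                             confHighRange = c(0.7, 1),
                             confLowRange = c(0.05, 0.45), seed = 1L) {
  new("CorruptionConfig", occlusionBorderCols = as.integer(occlusionBorderCols),
      blobCount = as.integer(blobCount),
      blobRadiusRange = as.numeric(blobRadiusRange),
      outlierMagnitude = as.numeric(outlierMagnitude),
      inlierNoiseSd = as.numeric(inlierNoiseSd),
      confHighRange = as.numeric(confHighRange),
      confLowRange = as.numeric(confLowRange), seed = as.integer(seed))
}

#' Trainer configuration
#'
#' Full-batch gradient descent on the batch loss, with the step size
#' attenuated by \code{stepDecay} after every pass (default 0.95). Optional
#' augmentation mirrors 50\%-probability horizontal/vertical flips and
#' additive Gaussian noise on the supervisory disparity; both default off.
#'
#' @slot loss a \linkS4class{LossConfig}.
#' @slot maxSteps positive integer.
#' @slot stepSize positive numeric initial step.
#' @slot stepDecay numeric in (0, 1]; per-pass attenuation.
#' @slot augmentFlips logical.
#' @slot augmentNoiseSd non-negative numeric.
#' @slot seed integer.
#' @export
setClass("TrainConfig",
  representation(loss = "LossConfig", maxSteps = "integer",
                 stepSize = "numeric", stepDecay = "numeric",
                 augmentFlips = "logical", augmentNoiseSd = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@maxSteps < 1L) return("maxSteps must be >= 1")
    if (object@stepSize <= 0) return("stepSize must be > 0")
    if (object@stepDecay <= 0 || object@stepDecay > 1)
      return("stepDecay must lie in (0, 1]")
    if (object@augmentNoiseSd < 0) return("augmentNoiseSd must be >= 0")
    TRUE
  })

#' @describeIn TrainConfig-class Constructor.
#' @param loss a \linkS4class{LossConfig}.
#' @param maxSteps gradient steps (default 150).
#' @param stepSize initial step size (default 0.5).
#' @param stepDecay per-pass step attenuation (default 0.95).
#' @param augmentFlips enable random flips (default FALSE).
#' @param augmentNoiseSd supervisory-noise augmentation sd (default 0).
#' @param seed RNG seed for initialisation and augmentation.
#' @export
TrainConfig <- function(loss = LossConfig(), maxSteps = 150L, stepSize = 0.5,
                        stepDecay = 0.95, augmentFlips = FALSE,
                        augmentNoiseSd = 0, seed = 1L) {
  new("TrainConfig", loss = loss, maxSteps = as.integer(maxSteps),
      stepSize = as.numeric(stepSize), stepDecay = as.numeric(stepDecay),
      augmentFlips = augmentFlips, augmentNoiseSd = as.numeric(augmentNoiseSd),
      seed = as.integer(seed))
}

#' Parameters of the desk-scale inverse-depth predictor
#'
#' Coefficients of a low-order 2-D polynomial surface over normalised pixel
#' coordinates, expressed in a basis orthonormalised over the pixel grid.
#' Stands in for a full dense-prediction network: the loss-level claims
#' (scale-shift invariance, robustness of confidence weighting) are
#' properties of the objective and hold for any differentiable predictor.
#'
#' @slot coefficients numeric vector.
#' @slot order integer polynomial order.
#' @slot trajectory numeric vector of best-so-far batch losses per step.
#' @slot finalLoss numeric.
#' @export
setClass("PredictorParams",
  representation(coefficients = "numeric", order = "integer",
                 trajectory = "numeric", finalLoss = "numeric"),
  validity = function(object) {
    if (any(!is.finite(object@coefficients)))
      return("coefficients must be finite")
    expected <- (object@order + 1L) * (object@order + 2L) / 2L
    if (length(object@coefficients) != expected)
      return("coefficient count must match the declared order")
    TRUE
  })

PredictorParams <- function(coefficients, order, trajectory = numeric(0),
                            finalLoss = NA_real_) {
  new("PredictorParams", coefficients = as.numeric(coefficients),
      order = as.integer(order), trajectory = as.numeric(trajectory),
      finalLoss = as.numeric(finalLoss))
}

#' Report of the mask-comparison experiment
#'
#' @slot recoveryError named numeric; mean |aligned prediction - clean truth|
#'   in inverse depth per mask kind (uniform, hard, soft).
#' @slot finalLoss named numeric; final training batch loss per arm.
#' @slot winMargin numeric; uniform recovery error minus soft recovery error.
#' @slot failedArms character; arms that diverged, if any.
#' @export
setClass("ExperimentReport",
  representation(recoveryError = "numeric", finalLoss = "numeric",
                 winMargin = "numeric", failedArms = "character"),
  validity = function(object) {
    ok <- is.finite(object@recoveryError)
    if (any(object@recoveryError[ok] < 0))
      return("recovery errors must be >= 0")
    TRUE
  })

ExperimentReport <- function(recoveryError, finalLoss, winMargin,
                             failedArms = character(0)) {
  new("ExperimentReport", recoveryError = recoveryError,
      finalLoss = finalLoss, winMargin = as.numeric(winMargin),
      failedArms = failedArms)
}
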