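# Scale- and shift-invariant evaluation protocol: robust IRLS alignment in
# inverse-depth space, then absolute relative error and threshold
# accuracies in depth space (reciprocal of the aligned inverse depth, with
# a small positive floor guarding the division).

#' Mean absolute relative depth error
#'
#' \eqn{(1/N) \sum_i |d_i - d^*_i| / d^*_i} over valid pixels.
#'
#' @param predDepth,gtDepth numeric matrices (or vectors) of depths.
#' @param mask a \linkS4class{ValidityMask} (or logical grid) selecting the
#'   evaluated pixels.
#' @return non-negative scalar.
#' @export
absRel <- function(predDepth, gtDepth, mask) {
  f <- if (is(mask, "ValidityMask")) maskFlags(mask) else mask
  p <- predDepth[f]; g <- gtDepth[f]
  if (any(g <= 0))
    .stopc("cwdepth_domain_error",
           "ground-truth depth must be strictly positive on valid pixels")
  mean(abs(p - g) / g)
}

#' Threshold accuracy
#'
#' Fraction of valid pixels whose larger depth ratio
#' \eqn{\max(d/d^*, d^*/d)} is strictly below \code{t}.
#'
#' @inheritParams absRel
#' @param t threshold, > 1 (conventionally 1.25, 1.25^2, 1.25^3).
#' @return fraction in [0, 1].
#' @export
thresholdAccuracy <- function(predDepth, gtDepth, mask, t) {
  if (t <= 1) .stopc("cwdepth_domain_error", "threshold t must exceed 1")
  f <- if (is(mask, "ValidityMask")) maskFlags(mask) else mask
  p <- predDepth[f]; g <- gtDepth[f]
  if (any(p <= 0) || any(g <= 0))
    .stopc("cwdepth_domain_error",
           "depths must be strictly positive on valid pixels")
  ratio <- pmax(p / g, g / p)
  mean(ratio < t)
}

#' Evaluate one prediction against its ground truth
#'
#' Builds the validity mask, fits the robust IRLS scale/shift alignment in
#' inverse-depth space, applies it, converts the aligned prediction and the
#' ground truth to depth by reciprocal, and reports absolute relative error
#' and the three threshold accuracies. Pixels whose aligned inverse depth
#' falls at or below \code{epsilon} are dropped from the metric sums;
#' \code{pixelsEvaluated} records the count kept.
#'
#' @param predInv predicted \linkS4class{InverseDepthMap}.
#' @param gtInv ground-truth \linkS4class{InverseDepthMap}.
#' @param conf optional \linkS4class{ConfidenceMap}; pixels with zero
#'   confidence are excluded as invalid.
#' @param irls an \linkS4class{IRLSConfig}.
#' @param space \code{"depth"} (default) evaluates the metrics on
#'   reciprocal depths; \code{"disparity"} evaluates directly on the
#'   aligned inverse-depth values.
#' @param epsilon positive floor on inverse depth before the reciprocal.
#' @return a \linkS4class{MetricsReport}.
#' @export
evaluatePair <- function(predInv, gtInv, conf = NULL, irls = IRLSConfig(),
                         space = c("depth", "disparity"), epsilon = 1e-8) {
  space <- match.arg(space)
  g <- mapValues(gtInv); p <- mapValues(predInv)
  flags <- is.finite(g) & is.finite(p)
  if (!is.null(conf)) flags <- flags & mapValues(conf) > 0
  mask <- ValidityMask(flags)
  if (countValid(mask) < 2L)
    .stopc("cwdepth_insufficient_data", "need >= 2 valid pixels to evaluate")
  params <- tryCatch(alignIRLS(predInv, gtInv, mask, irls), error = function(e)
    .stopc("cwdepth_evaluation_error",
           paste("degenerate alignment:", conditionMessage(e))))
  pa <- params@s * p + params@t
  keep <- flags & pa > epsilon & g > epsilon
  if (space == "depth") {
    pd <- 1 / pa; gd <- 1 / g
  } else {
    pd <- pa; gd <- g
  }
  MetricsReport(absRel(pd, gd, keep),
                thresholdAccuracy(pd, gd, keep, 1.25),
                thresholdAccuracy(pd, gd, keep, 1.25^2),
                thresholdAccuracy(pd, gd, keep, 1.25^3),
                sum(keep))
}

#' Evaluate a set of prediction / ground-truth pairs
#'
#' @param pairs non-empty list; each element a list with components
#'   \code{pred}, \code{gt} and optionally \code{conf} and \code{name}.
#' @param irls an \linkS4class{IRLSConfig}.
#' @param space,epsilon passed to \code{\link{evaluatePair}}.
#' @return list with \code{aggregate} (a \linkS4class{MetricsReport} of
#'   unweighted per-image means) and \code{perImage} (a data.frame, one row
#'   per image).
#' @export
evaluateSet <- function(pairs, irls = IRLSConfig(),
                        space = c("depth", "disparity"), epsilon = 1e-8) {
  if (length(pairs) == 0L)
    .stopc("cwdepth_empty_set", "no pairs to evaluate")
  space <- match.arg(space)
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    rep <- evaluatePair(pr$pred, pr$gt, pr$conf, irls, space, epsilon)
    cbind(data.frame(name = pr$name %||% sprintf("image%03d", i),
                     stringsAsFactors = FALSE),
          metricsAsDataFrame(rep))
  })
  perImage <- do.call(rbind, rows)
  MetricsReport(mean(perImage$absRel), mean(perImage$delta1),
                mean(perImage$delta2), mean(perImage$delta3),
                sum(perImage$pixelsEvaluated)) -> agg
  list(aggregate = agg, perImage = perImage)
}
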