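#' Extract the value grid of a map
#'
#' @param x an \linkS4class{InverseDepthMap} or \linkS4class{ConfidenceMap}.
#' @return numeric matrix.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname mapValues
#' @export
setMethod("mapValues", "InverseDepthMap", function(x) x@values)

#' @rdname mapValues
#' @export
setMethod("mapValues", "ConfidenceMap", function(x) x@values)

#' @describeIn ValidityMask-class Logical flag matrix.
#' @param x a \linkS4class{ValidityMask}.
#' @export
maskFlags <- function(x) x@flags

#' @describeIn ValidityMask-class Number of valid pixels.
#' @export
countValid <- function(x) x@countValid

#' @describeIn SupervisionFrame-class Component accessors.
#' @param x a \linkS4class{SupervisionFrame}.
#' @export
supDisparity <- function(x) x@disparity

#' @rdname supDisparity
#' @export
supConfidence <- function(x) x@confidence

#' @rdname supDisparity
#' @export
supMask <- function(x) x@mask

#' @describeIn AffineParams-class Scale and shift accessors.
#' @param x an \linkS4class{AffineParams}.
#' @export
affineScale <- function(x) x@s

#' @rdname affineScale
#' @export
affineShift <- function(x) x@t

#' @describeIn LossBreakdown-class Accessors.
#' @param x a \linkS4class{LossBreakdown}.
#' @export
lossTotal <- function(x) x@total

#' @rdname lossTotal
#' @export
lossDataTerm <- function(x) x@dataTerm

#' @rdname lossTotal
#' @export
lossGradientTerm <- function(x) x@gradientTerm

#' @rdname lossTotal
#' @export
effectivePixels <- function(x) x@effectivePixels

#' Coerce a MetricsReport to a one-row data.frame
#'
#' @param x a \linkS4class{MetricsReport}.
#' @return data.frame with columns absRel, delta1..3, pixelsEvaluated.
#' @export
metricsAsDataFrame <- function(x) {
  data.frame(absRel = x@absRel, delta1 = x@delta1, delta2 = x@delta2,
             delta3 = x@delta3, pixelsEvaluated = x@pixelsEvaluated)
}

setMethod("dim", "InverseDepthMap", function(x) dim(x@values))
setMethod("dim", "ConfidenceMap", function(x) dim(x@values))
setMethod("dim", "ValidityMask", function(x) dim(x@flags))
setMethod("dim", "SupervisionFrame", function(x) dim(x@disparity@values))

setMethod("show", "InverseDepthMap", function(object) {
  v <- object@values
  fin <- v[is.finite(v)]
  cat(sprintf("InverseDepthMap: %d x %d, %d finite, range [%.4g, %.4g]\n",
              nrow(v), ncol(v), length(fin),
              if (length(fin)) min(fin) else NA, if (length(fin)) max(fin) else NA))
})

setMethod("show", "ConfidenceMap", function(object) {
  v <- object@values
  cat(sprintf("ConfidenceMap: %d x %d, mean %.3f, %d zero-confidence px\n",
              nrow(v), ncol(v), mean(v), sum(v == 0)))
})

setMethod("show", "ValidityMask", function(object) {
  cat(sprintf("ValidityMask: %d x %d, %d / %d valid\n",
              nrow(object@flags), ncol(object@flags), object@countValid,
              length(object@flags)))
})

setMethod("show", "SupervisionFrame", function(object) {
  cat("SupervisionFrame\n")
  show(object@disparity); show(object@confidence); show(object@mask)
})

setMethod("show", "AffineParams", function(object) {
  cat(sprintf("AffineParams: s = %.6g, t = %.6g (%s, %d iterations)\n",
              object@s, object@t,
              if (object@converged) "converged" else "not converged",
              object@iterations))
})

setMethod("show", "LossBreakdown", function(object) {
  cat(sprintf(
    "LossBreakdown: total %.6g (data %.6g, gradient %.6g), %d effective px\n",
    object@total, object@dataTerm, object@gradientTerm,
    object@effectivePixels))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport: absRel %.4f | d<1.25 %.3f | d<1.25^2 %.3f | d<1.25^3 %.3f | %d px\n",
    object@absRel, object@delta1, object@delta2, object@delta3,
    object@pixelsEvaluated))
})

setMethod("show", "ExperimentReport", function(object) {
  cat("ExperimentReport (mean |aligned prediction - truth|, inverse depth)\n")
  for (nm in names(object@recoveryError))
    cat(sprintf("  %-8s recovery error %.5f (final loss %.5g)\n", nm,
                object@recoveryError[[nm]], object@finalLoss[[nm]]))
  cat(sprintf("  win margin (uniform - soft): %.5f\n", object@winMargin))
  if (length(object@failedArms))
    cat("  failed arms:", paste(object@failedArms, collapse = ", "), "\n")
})
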