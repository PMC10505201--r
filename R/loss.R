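# Confidence-weighted scale- and shift-invariant loss.
#
# Per image: align the prediction to the supervisory disparity by least
# squares over the pixels the mask keeps, then accumulate a confidence-
# weighted squared-residual data term and a multi-scale gradient-matching
# term over a residual pyramid. Both terms are normalised by M, the number
# of valid pixels, regardless of how many of those the confidence weights
# zero out.

#' Confidence-to-weight mapping
#'
#' Hard mask: indicator of q >= threshold. Soft mask:
#' exp(sharpness * (q - 1)) for q >= threshold, else 0. Uniform: 1 for all
#' q. The boundary q == threshold is kept (weight > 0). A soft mask with
#' sharpness 0 reproduces the hard mask exactly.
#'
#' @param q numeric vector/matrix of confidences in [0, 1].
#' @param cfg a \linkS4class{WeightConfig}.
#' @return weights in [0, 1], same shape as \code{q}.
#' @export
confidenceWeight <- function(q, cfg) {
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1))
    .stopc("cwdepth_domain_error", "confidence values must lie in [0, 1]")
  w <- switch(cfg@maskKind,
    uniform = rep(1, length(q)),
    hard = (q >= cfg@threshold) * 1.0,
    soft = ifelse(q >= cfg@threshold, exp(cfg@sharpness * (q - 1)), 0))
  if (is.matrix(q) && !is.matrix(w)) w <- matrix(w, nrow = nrow(q))
  w
}

#' Confidence-weighted squared-residual data term
#'
#' \eqn{(1/2M) \sum_i w(q_i) (dhat_i - dhat^*_i)^2} over valid pixels, with
#' M the valid-pixel count (masked-out pixels contribute zero to the sum but
#' stay in M).
#'
#' @param predAligned prediction after affine alignment
#'   (\linkS4class{InverseDepthMap}).
#' @param gt supervisory \linkS4class{InverseDepthMap}.
#' @param conf a \linkS4class{ConfidenceMap}.
#' @param mask a \linkS4class{ValidityMask}.
#' @param cfg a \linkS4class{WeightConfig}.
#' @return non-negative scalar.
#' @export
cwDataTerm <- function(predAligned, gt, conf, mask, cfg) {
  M <- countValid(mask)
  if (M == 0L) .stopc("cwdepth_empty_image", "no valid pixels")
  f <- maskFlags(mask)
  r <- mapValues(predAligned)[f] - mapValues(gt)[f]
  w <- confidenceWeight(mapValues(conf)[f], cfg)
  sum(w * r * r) / (2 * M)
}

# 2x2 average pooling to ceiling(dim / 2); partial edge blocks average the
# cells present. Residuals average their valid children only; weights are
# plain block averages (full-resolution weights are already zero at invalid
# pixels); a pooled pixel is valid only when every child present is valid.
.pool2 <- function(residual, weight, valid) {
  h <- nrow(residual); w <- ncol(residual)
  ri <- (seq_len(h) + 1L) %/% 2L
  ci <- (seq_len(w) + 1L) %/% 2L
  h2 <- max(ri); w2 <- max(ci)
  grp <- matrix(ri + (rep(ci, each = h) - 1L) * h2, h, w)
  cnt <- tabulate(grp, nbins = h2 * w2)
  vres <- residual; vres[!valid] <- 0
  sumValidRes <- tabulate2(grp, vres, h2 * w2)
  nValid <- tabulate2(grp, valid * 1.0, h2 * w2)
  sumW <- tabulate2(grp, weight, h2 * w2)
  res2 <- ifelse(nValid > 0, sumValidRes / pmax(nValid, 1), NA_real_)
  val2 <- nValid == cnt
  w2m <- sumW / cnt
  list(residual = matrix(res2, h2, w2), weight = matrix(w2m, h2, w2),
       valid = matrix(val2, h2, w2))
}

# grouped sum; every bin 1..nbins is present by construction, so rowsum's
# sorted output is already in bin order
tabulate2 <- function(grp, vals, nbins) {
  as.vector(rowsum(as.vector(vals), group = as.vector(grp), reorder = TRUE))
}

#' Build the residual scale pyramid
#'
#' Level 1 is the full-resolution residual (aligned prediction minus
#' target) with its weight and validity grids; each further level halves
#' resolution by 2 x 2 average pooling. Levels are truncated (with a
#' warning) when the image cannot support the requested count.
#'
#' The validity grid passed in should mark the pixels that actively carry
#' loss (typically valid AND positive confidence weight): inactive pixels
#' anchor no differences and are excluded from residual pooling, so their
#' values never reach the gradient term.
#'
#' @param predAligned,gt \linkS4class{InverseDepthMap}s.
#' @param weights numeric matrix of per-pixel loss weights.
#' @param mask a \linkS4class{ValidityMask} of loss-active pixels.
#' @param levels requested level count K.
#' @param denomValid optional valid-pixel count M used as the normaliser;
#'   defaults to the active count in \code{mask}.
#' @return a \linkS4class{ScalePyramid}.
#' @export
buildPyramid <- function(predAligned, gt, weights, mask, levels,
                         denomValid = NULL) {
  stopifnot(levels >= 1L)
  valid <- maskFlags(mask)
  residual <- mapValues(predAligned) - mapValues(gt)
  residual[!valid] <- NA_real_
  w <- weights; w[!valid] <- 0
  h <- nrow(residual); wd <- ncol(residual)
  maxLevels <- 1L
  while (min(h, wd) >= 2^maxLevels) maxLevels <- maxLevels + 1L
  if (levels > maxLevels) {
    .warnc("cwdepth_pyramid_truncated",
           sprintf("image %d x %d supports %d levels; %d requested",
                   h, wd, maxLevels, levels))
    levels <- maxLevels
  }
  lv <- list(list(residual = residual, weight = w, valid = valid))
  for (k in seq_len(levels - 1L)) {
    prev <- lv[[k]]
    lv[[k + 1L]] <- .pool2(prev$residual, prev$weight, prev$valid)
  }
  ScalePyramid(lv, denomValid %||% countValid(mask))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multi-scale confidence-weighted gradient-matching term
#'
#' Forward differences of the residual along x and y at every pyramid
#' level; a difference contributes only when both participating pixels are
#' valid at that level, weighted by the mean of the two pixels' pooled
#' weights (so the term is exactly symmetric under image flips). The level
#' sums are divided once by the full-resolution valid-pixel count M.
#'
#' @param pyramid a \linkS4class{ScalePyramid}.
#' @return non-negative scalar.
#' @export
cwGradientTerm <- function(pyramid) {
  M <- pyramid@fullResValid
  if (M == 0L) .stopc("cwdepth_empty_image", "no valid pixels")
  total <- 0
  for (lev in pyramid@levels) {
    R <- lev$residual; W <- lev$weight; V <- lev$valid
    h <- nrow(R); w <- ncol(R)
    if (w >= 2L) {
      dx <- R[, -1L, drop = FALSE] - R[, -w, drop = FALSE]
      ok <- V[, -1L, drop = FALSE] & V[, -w, drop = FALSE]
      wx <- (W[, -1L, drop = FALSE] + W[, -w, drop = FALSE]) / 2
      total <- total + sum(wx[ok] * abs(dx[ok]))
    }
    if (h >= 2L) {
      dy <- R[-1L, , drop = FALSE] - R[-h, , drop = FALSE]
      ok <- V[-1L, , drop = FALSE] & V[-h, , drop = FALSE]
      wy <- (W[-1L, , drop = FALSE] + W[-h, , drop = FALSE]) / 2
      total <- total + sum(wy[ok] * abs(dy[ok]))
    }
  }
  total / M
}

#' Per-image confidence-weighted scale/shift-invariant loss
#'
#' Aligns the prediction to the supervisory disparity by least squares over
#' the pixels that are valid \emph{and} carry positive confidence weight,
#' applies the affine transform, and accumulates the data term plus
#' \code{gradientWeight} times the multi-scale gradient term. Degenerate
#' images (all weights zero, a singular alignment, or non-positive fitted
#' scale) contribute zero with a warning, so batch averaging stays
#' well defined.
#'
#' @param pred predicted \linkS4class{InverseDepthMap}.
#' @param sup a \linkS4class{SupervisionFrame}.
#' @param cfg a \linkS4class{LossConfig}.
#' @return a \linkS4class{LossBreakdown}.
#' @export
imageLoss <- function(pred, sup, cfg) {
  p <- mapValues(pred)
  if (!identical(dim(p), dim(sup)))
    .stopc("cwdepth_dimension_error",
           "prediction and supervision shapes differ")
  valid <- maskFlags(supMask(sup))
  w <- confidenceWeight(mapValues(supConfidence(sup)), cfg@weight)
  w[!valid] <- 0
  support <- valid & w > 0 & is.finite(p)
  zero <- function(msg) {
    .warnc("cwdepth_degenerate_image", msg)
    LossBreakdown(0, 0, 0, 0L)
  }
  if (sum(support) < 2L)
    return(zero("fewer than 2 positively weighted valid pixels"))
  params <- tryCatch(
    alignLSQ(pred, supDisparity(sup), ValidityMask(support)),
    cwdepth_degenerate_input = function(e) NULL)
  if (is.null(params))
    return(zero("degenerate scale/shift alignment"))
  if (params@s <= 0)
    return(zero(sprintf("non-positive fitted scale (s = %.4g)", params@s)))
  predA <- applyAffine(pred, params)
  mask <- supMask(sup)
  dataTerm <- cwDataTerm(predA, supDisparity(sup), supConfidence(sup), mask,
                         cfg@weight)
  # zero-weight pixels are inactive for the gradient term: an outlier at a
  # sub-threshold-confidence pixel must not reach the hard/soft loss
  gradTerm <- withCallingHandlers(
    cwGradientTerm(buildPyramid(predA, supDisparity(sup), w,
                                ValidityMask(support), cfg@scaleLevels,
                                denomValid = countValid(mask))),
    cwdepth_pyramid_truncated = function(wc) invokeRestart("muffleWarning"))
  LossBreakdown(dataTerm, gradTerm,
                dataTerm + cfg@gradientWeight * gradTerm,
                sum(valid & w > 0))
}

#' Batch confidence-weighted loss
#'
#' Arithmetic mean of per-image totals over the training set; each total
#' already carries its gradient-term contribution, matching the two
#' averaged sums of the training objective.
#'
#' @param preds list of \linkS4class{InverseDepthMap}s.
#' @param sups list of \linkS4class{SupervisionFrame}s, same length.
#' @param cfg a \linkS4class{LossConfig}.
#' @return list with elements \code{total} (numeric) and
#'   \code{breakdowns} (list of \linkS4class{LossBreakdown}).
#' @export
batchLoss <- function(preds, sups, cfg) {
  if (length(preds) == 0L || length(preds) != length(sups))
    .stopc("cwdepth_empty_batch",
           "preds and sups must be non-empty lists of equal length")
  breakdowns <- mapply(imageLoss, preds, sups,
                       MoreArgs = list(cfg = cfg), SIMPLIFY = FALSE)
  list(total = mean(vapply(breakdowns, lossTotal, numeric(1))),
       breakdowns = breakdowns)
}
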