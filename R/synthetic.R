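# Seeded generator of synthetic supervisory signals with the failure
# structure of stereo matching in surgical scenes: a zero-confidence
# occlusion band at the left border (no disparity computed), low-confidence
# blob regions (droplets / smoke / specularities) carrying gross disparity
# outliers, and high-confidence regions carrying only small Gaussian noise.
# Outliers are tied to low confidence by construction, which turns the
# premise of confidence weighting into a testable property.

.normGrid <- function(height, width) {
  list(x = matrix(rep((seq_len(width) - 1) / (width - 1), each = height),
                  height, width),
       y = matrix(rep((seq_len(height) - 1) / (height - 1), width),
                  height, width))
}

#' Generate a smooth true inverse-depth surface
#'
#' A random polynomial of order \code{surfaceOrder} over normalised pixel
#' coordinates, affinely rescaled into \code{invDepthRange}. Deterministic
#' given the seed.
#'
#' @param cfg a \linkS4class{SceneConfig}.
#' @return an \linkS4class{InverseDepthMap}.
#' @export
generateTruth <- function(cfg) {
  g <- .normGrid(cfg@height, cfg@width)
  withSeed(cfg@seed, {
    z <- matrix(0, cfg@height, cfg@width)
    for (a in 0:cfg@surfaceOrder) for (b in 0:(cfg@surfaceOrder - a))
      z <- z + stats::rnorm(1) * g$x^a * g$y^b
    lo <- cfg@invDepthRange[1]; hi <- cfg@invDepthRange[2]
    rng <- range(z)
    if (rng[2] - rng[1] < 1e-12) {
      # constant surface (order 0 or degenerate draw): place it in-range
      z[] <- lo + stats::runif(1) * (hi - lo)
    } else {
      z <- lo + (z - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
    }
    InverseDepthMap(pmin(pmax(z, lo), hi))
  })
}

#' Corrupt a true surface into a supervisory signal
#'
#' Applies, in order: (a) the left \code{occlusionBorderCols} columns get
#' confidence 0 and invalid (NA) disparity; (b) \code{blobCount} random
#' disks get per-pixel confidence drawn from \code{confLowRange} and
#' disparity replaced by truth plus a gross error of magnitude about
#' \code{outlierMagnitude} with a per-blob random sign; (c) remaining
#' pixels get confidence from \code{confHighRange} and truth plus Gaussian
#' noise of sd \code{inlierNoiseSd}.
#'
#' @param truth an \linkS4class{InverseDepthMap}.
#' @param cfg a \linkS4class{CorruptionConfig}.
#' @return a \linkS4class{SupervisionFrame}.
#' @export
corruptTruth <- function(truth, cfg) {
  z <- mapValues(truth)
  h <- nrow(z); w <- ncol(z)
  withSeed(cfg@seed, {
    disparity <- z + if (cfg@inlierNoiseSd > 0)
      matrix(stats::rnorm(h * w, sd = cfg@inlierNoiseSd), h, w) else 0
    confidence <- matrix(stats::runif(h * w, cfg@confHighRange[1],
                                      cfg@confHighRange[2]), h, w)
    inBlob <- matrix(FALSE, h, w)
    if (cfg@blobCount > 0L) {
      rows <- matrix(rep(seq_len(h), w), h, w)
      cols <- matrix(rep(seq_len(w), each = h), h, w)
      for (b in seq_len(cfg@blobCount)) {
        cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
        rad <- stats::runif(1, cfg@blobRadiusRange[1], cfg@blobRadiusRange[2])
        sign <- if (stats::runif(1) < 0.5) -1 else 1
        disk <- (rows - cy)^2 + (cols - cx)^2 <= rad^2
        n <- sum(disk)
        if (n == 0L) next
        disparity[disk] <- z[disk] +
          sign * cfg@outlierMagnitude * stats::runif(n, 0.8, 1.2)
        confidence[disk] <- stats::runif(n, cfg@confLowRange[1],
                                         cfg@confLowRange[2])
        inBlob <- inBlob | disk
      }
    }
    if (cfg@occlusionBorderCols > 0L) {
      bc <- seq_len(min(cfg@occlusionBorderCols, w))
      disparity[, bc] <- NA_real_
      confidence[, bc] <- 0
      inBlob[, bc] <- FALSE
    }
    usable <- if (cfg@occlusionBorderCols > 0L)
      inBlob[, -seq_len(min(cfg@occlusionBorderCols, w)), drop = FALSE]
    else inBlob
    if (length(usable) == 0L || all(usable))
      .stopc("cwdepth_config_error", "blobs cover the whole usable image")
    SupervisionFrame(InverseDepthMap(disparity), ConfidenceMap(confidence))
  })
}

#' Generate and write a synthetic supervision dataset
#'
#' Writes \code{n} groups of files to \code{outDir}: the clean truth and
#' the corrupted supervisory disparity as PFM, the confidence map as
#' 16-bit PNG (scale factor 65535), plus \code{manifest.csv} recording
#' filenames, per-image seeds and corruption statistics. Each image draws
#' from its own stream derived from the configured seeds and the image
#' index, so any image regenerates independently.
#'
#' @param n number of images (>= 1).
#' @param scene a \linkS4class{SceneConfig}.
#' @param corr a \linkS4class{CorruptionConfig}.
#' @param outDir output directory (created if missing).
#' @return the manifest as a data.frame (invisibly also on disk).
#' @export
generateDataset <- function(n, scene, corr, outDir) {
  stopifnot(n >= 1L)
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outDir, 2L) != 0L)
    .stopc("cwdepth_io_error", sprintf("cannot write to '%s'", outDir))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sceneSeed <- (scene@seed * 10007L + i) %% 2147483647L
    corrSeed <- (corr@seed * 20011L + i) %% 2147483647L
    sc <- scene; sc@seed <- as.integer(sceneSeed)
    cc <- corr; cc@seed <- as.integer(corrSeed)
    truth <- generateTruth(sc)
    sup <- corruptTruth(truth, cc)
    truthFile <- sprintf("truth_%03d.pfm", i)
    dispFile <- sprintf("disp_%03d.pfm", i)
    confFile <- sprintf("conf_%03d.png", i)
    writePFM(truth, file.path(outDir, truthFile))
    writePFM(supDisparity(sup), file.path(outDir, dispFile))
    # confidence in [0,1] stored as round(q * 65535); zero confidence maps
    # to the stored-0 invalid sentinel (read back as NA -> confidence 0)
    qv <- mapValues(supConfidence(sup))
    qv[qv == 0] <- NA_real_
    writeDepthPNG(InverseDepthMap(qv), file.path(outDir, confFile), 65535)
    q <- mapValues(supConfidence(sup))
    d <- mapValues(supDisparity(sup))
    rows[[i]] <- data.frame(
      index = i, truthFile = truthFile, dispFile = dispFile,
      confFile = confFile, sceneSeed = sceneSeed, corrSeed = corrSeed,
      validCount = countValid(supMask(sup)),
      occludedFraction = mean(q == 0),
      outlierFraction = mean(q > 0 & q < 0.5),
      meanAbsError = mean(abs(d - mapValues(truth))[is.finite(d)]),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
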