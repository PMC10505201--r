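# Internal convention: grids are row-major with origin at the top-left
# pixel; PFM stores rows bottom-up and is flipped on read/write.

#' Read a grayscale PFM disparity map
#'
#' Portable FloatMap: ASCII header ("Pf", dimensions, scale) followed by
#' raw 32-bit floats stored bottom-up. The sign of the scale field selects
#' endianness (negative = little-endian); its magnitude is applied as a
#' multiplicative unit factor. Rows are flipped to the package's
#' top-left-origin convention.
#'
#' @param path path to a \code{Pf} (single-channel) PFM file.
#' @return an \linkS4class{InverseDepthMap}.
#' @export
readPFM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readToken <- function() {
    # whitespace-delimited token, reading byte-wise so the binary payload
    # position is preserved
    chs <- character(0)
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0L)
        .stopc("cwdepth_format_error", "PFM header truncated")
      ch <- rawToChar(b)
      if (ch %in% c(" ", "\n", "\r", "\t")) {
        if (length(chs)) break else next
      }
      chs <- c(chs, ch)
    }
    paste(chs, collapse = "")
  }
  magic <- readToken()
  if (identical(magic, "PF"))
    .stopc("cwdepth_unsupported_format",
           "color PFM ('PF') is not supported; expected grayscale 'Pf'")
  if (!identical(magic, "Pf"))
    .stopc("cwdepth_format_error",
           sprintf("malformed PFM header: magic line '%s'", magic))
  w <- suppressWarnings(as.integer(readToken()))
  h <- suppressWarnings(as.integer(readToken()))
  if (is.na(w) || is.na(h) || w < 1L || h < 1L)
    .stopc("cwdepth_format_error", "malformed PFM header: dimensions line")
  scale <- suppressWarnings(as.numeric(readToken()))
  if (is.na(scale) || scale == 0)
    .stopc("cwdepth_format_error", "malformed PFM header: scale line")
  endian <- if (scale < 0) "little" else "big"
  vals <- readBin(con, "numeric", n = w * h, size = 4L, endian = endian)
  if (length(vals) != w * h)
    .stopc("cwdepth_format_error", "PFM data block shorter than header dims")
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  m <- m[h:1, , drop = FALSE] * abs(scale)   # bottom-up -> top-down
  InverseDepthMap(m)
}

#' Write a grayscale PFM disparity map
#'
#' Emits little-endian scale -1.0, so \code{readPFM} inverts it exactly.
#' Non-finite pixels are stored as \code{sentinel}.
#'
#' @param map an \linkS4class{InverseDepthMap}.
#' @param path output path.
#' @param sentinel value stored at non-finite pixels (default 0).
#' @export
writePFM <- function(map, path, sentinel = 0) {
  v <- mapValues(map)
  v[!is.finite(v)] <- sentinel
  con <- tryCatch(file(path, "wb"), error = function(e)
    .stopc("cwdepth_io_error", sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  writeChar(sprintf("Pf\n%d %d\n-1.000000\n", ncol(v), nrow(v)), con,
            eos = NULL)
  flipped <- v[nrow(v):1, , drop = FALSE]
  writeBin(as.numeric(t(flipped)), con, size = 4L, endian = "little")
  invisible(NULL)
}

#' Read a 16-bit grayscale PNG disparity map
#'
#' Stored integers are divided by \code{scaleFactor}; the stored value 0 is
#' the invalid-pixel sentinel and decodes to \code{NA}.
#'
#' @param path path to a 16-bit single-channel PNG.
#' @param scaleFactor positive divisor mapping stored integers to disparity.
#' @return an \linkS4class{InverseDepthMap}.
#' @export
readDepthPNG <- function(path, scaleFactor) {
  stopifnot(is.numeric(scaleFactor), scaleFactor > 0)
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (info$bit.depth != 16L)
    .stopc("cwdepth_unsupported_format",
           sprintf("expected 16-bit PNG, got %d-bit", info$bit.depth))
  if (length(dim(img)) > 2L)
    .stopc("cwdepth_unsupported_format",
           "expected single-channel grayscale PNG")
  ints <- round(img * 65535)
  vals <- ints / scaleFactor
  vals[ints == 0] <- NA_real_
  InverseDepthMap(matrix(vals, nrow = nrow(img)))
}

#' Write a 16-bit grayscale PNG disparity map
#'
#' Values are multiplied by \code{scaleFactor}, rounded and clamped to
#' [1, 65535]; non-finite pixels are stored as 0 (the invalid sentinel).
#' Round trips through \code{readDepthPNG} are exact to within the
#' 1/scaleFactor quantisation step.
#'
#' @inheritParams readDepthPNG
#' @param map an \linkS4class{InverseDepthMap}.
#' @export
writeDepthPNG <- function(map, path, scaleFactor) {
  stopifnot(is.numeric(scaleFactor), scaleFactor > 0)
  v <- mapValues(map)
  ints <- round(v * scaleFactor)
  ints[!is.finite(v)] <- 0
  ints[is.finite(v) & ints < 1] <- 1      # keep valid pixels off the sentinel
  ints[ints > 65535] <- 65535
  .writePNG16(matrix(as.integer(ints), nrow = nrow(v)), path)
  invisible(NULL)
}

#' Build the validity mask of a supervision pair
#'
#' A pixel is valid iff its disparity is finite and its confidence is
#' strictly positive; the zero-confidence occlusion band and uncomputed
#' pixels are excluded from every downstream sum.
#'
#' @param disparity an \linkS4class{InverseDepthMap}.
#' @param confidence a \linkS4class{ConfidenceMap} of the same shape.
#' @return a \linkS4class{ValidityMask}.
#' @export
buildValidityMask <- function(disparity, confidence) {
  d <- mapValues(disparity)
  q <- mapValues(confidence)
  if (!identical(dim(d), dim(q)))
    .stopc("cwdepth_dimension_error",
           "disparity and confidence shapes differ")
  ValidityMask(is.finite(d) & q > 0)
}

## ---- minimal 16-bit grayscale PNG writer ---------------------------------
## The png package decodes 16-bit but encodes 8-bit only, so encoding is done
## here: IHDR/IDAT/IEND chunks, zlib stream with stored (uncompressed)
## deflate blocks, CRC32 and Adler32 computed in R.

.crc32Table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1)) # 0xEDB88320
      else bitwShiftR(bitwAnd(c, -2L), 1)
    }
    tab[n + 1L] <- c
  }
  tab
})

.crc32 <- function(bytes) {
  crc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwAnd(bitwXor(crc, b[i]), 255L)
    crc <- bitwXor(.crc32Table[idx + 1L], bitwShiftR(bitwAnd(crc, -256L), 8))
  }
  bitwXor(crc, -1L)
}

.adler32 <- function(bytes) {
  MOD <- 65521
  b <- as.integer(bytes)
  a <- 1; s2 <- 0
  # chunked so doubles never lose integer precision
  step <- 3000L
  i <- 1L
  n <- length(b)
  while (i <= n) {
    j <- min(i + step - 1L, n)
    seg <- as.numeric(b[i:j])
    cs <- cumsum(seg)
    s2 <- (s2 + length(seg) * a + sum(cs)) %% MOD
    a <- (a + cs[length(cs)]) %% MOD
    i <- j + 1L
  }
  c(a = a, b = s2)
}

.u32be <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

.pngChunk <- function(type, data) {
  payload <- c(charToRaw(type), data)
  crc <- .crc32(payload)
  c(.u32be(length(data)), payload, .u32be(if (crc < 0) crc + 4294967296 else crc))
}

.writePNG16 <- function(ints, path) {
  h <- nrow(ints); w <- ncol(ints)
  # scanlines: filter byte 0 + big-endian 16-bit samples, row-major top-down
  hi <- as.raw(ints %/% 256L)
  lo <- as.raw(ints %% 256L)
  rows <- vector("list", h)
  for (r in seq_len(h)) {
    inter <- raw(2L * w)
    inter[seq(1L, 2L * w, 2L)] <- hi[r + (seq_len(w) - 1L) * h]
    inter[seq(2L, 2L * w, 2L)] <- lo[r + (seq_len(w) - 1L) * h]
    rows[[r]] <- c(as.raw(0L), inter)
  }
  rawData <- do.call(c, rows)
  # zlib: CMF/FLG header, stored deflate blocks (<= 65535 bytes), Adler32
  blocks <- list(as.raw(c(0x78, 0x01)))
  n <- length(rawData); i <- 1L; bi <- 2L
  while (i <= n) {
    j <- min(i + 65534L, n)
    len <- j - i + 1L
    final <- if (j == n) as.raw(1L) else as.raw(0L)
    hdr <- c(final, as.raw(len %% 256L), as.raw(len %/% 256L),
             as.raw(bitwAnd(bitwXor(len, 65535L), 255L)),
             as.raw(bitwXor(len, 65535L) %/% 256L))
    blocks[[bi]] <- c(hdr, rawData[i:j]); bi <- bi + 1L
    i <- j + 1L
  }
  ad <- .adler32(rawData)
  blocks[[bi]] <- c(.u32be(ad[["b"]] * 65536 + ad[["a"]]))
  idat <- do.call(c, blocks)
  ihdr <- c(.u32be(w), .u32be(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  sig <- as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))
  out <- c(sig, .pngChunk("IHDR", ihdr), .pngChunk("IDAT", idat),
           .pngChunk("IEND", raw(0)))
  con <- tryCatch(file(path, "wb"), error = function(e)
    .stopc("cwdepth_io_error", sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  writeBin(out, con)
  invisible(NULL)
}
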