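# Minimal 16-bit greyscale PNG encoder. `png::writePNG` only emits 8-bit
# images, which would truncate millimetre depth; this writes the 16-bit
# single-channel format that `png::readPNG` reads back losslessly.

.pngChunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- .crc32_cpp(body)
  c(.u32(length(data)), body, .u32(crc))
}

.u32 <- function(x) {
  rev(as.raw(c(x %% 256, (x %/% 256) %% 256,
               (x %/% 65536) %% 256, (x %/% 16777216) %% 256)))
}

#' Write a 16-bit greyscale PNG
#'
#' @param units Integer matrix of stored values in [0, 65535]
#'   (rows = image rows).
#' @param path Output path.
#' @export
writePng16 <- function(units, path) {
  units <- round(units)
  if (any(units < 0) || any(units > 65535))
    stop("values outside the 16-bit range")
  h <- nrow(units); w <- ncol(units)
  hi <- as.raw(units %/% 256L)
  lo <- as.raw(units %% 256L)
  # scanlines: filter byte 0, then big-endian sample pairs, row by row
  rowbytes <- 1L + 2L * w
  raw_data <- raw(h * rowbytes)
  for (r in seq_len(h)) {
    off <- (r - 1L) * rowbytes
    interleaved <- as.vector(rbind(hi[r + (seq_len(w) - 1L) * h],
                                   lo[r + (seq_len(w) - 1L) * h]))
    raw_data[(off + 2L):(off + rowbytes)] <- interleaved
  }
  ihdr <- c(.u32(w), .u32(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  idat <- memCompress(raw_data, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(.pngChunk("IHDR", ihdr), con)
  writeBin(.pngChunk("IDAT", idat), con)
  writeBin(.pngChunk("IEND", raw(0)), con)
  invisible(path)
}
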