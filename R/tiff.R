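# Minimal baseline TIFF reader.
#
# No TIFF package ships with this toolchain, so uncompressed baseline
# TIFF 6.0 is parsed directly: both byte orders, 8- or 16-bit samples,
# grayscale or RGB (extra samples such as alpha are dropped), strip
# layout, first IFD only. Anything else (LZW/deflate/JPEG compression,
# tiles, palettes, planar layout) is rejected with a clear error.

read_tiff_baseline <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  order_tag <- readBin(con, "raw", 2L)
  endian <- if (identical(order_tag, charToRaw("II"))) "little"
            else if (identical(order_tag, charToRaw("MM"))) "big"
            else stop(sprintf("read_tiff: not a TIFF file: %s", path),
                      call. = FALSE)
  u16 <- function() readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                            endian = endian)
  u32 <- function() readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (u16() != 42L)
    stop(sprintf("read_tiff: bad TIFF magic in %s", path), call. = FALSE)
  ifd_offset <- u32()
  seek(con, ifd_offset)
  n_entries <- u16()
  tags <- list()
  for (i in seq_len(n_entries)) {
    tag <- u16(); type <- u16(); count <- u32()
    value_pos <- seek(con)             # offset of the 4-byte value field
    type_size <- c(1L, 1L, 2L, 4L, 8L)[type]
    if (is.na(type_size)) { seek(con, value_pos + 4L); next }
    nbytes <- type_size * count
    if (nbytes > 4L) seek(con, u32()) else seek(con, value_pos)
    vals <- switch(as.character(type),
      "1" = readBin(con, "integer", count, size = 1L, signed = FALSE),
      "3" = readBin(con, "integer", count, size = 2L, signed = FALSE,
                    endian = endian),
      "4" = readBin(con, "integer", count, size = 4L, endian = endian),
      NULL)
    tags[[as.character(tag)]] <- vals
    seek(con, value_pos + 4L)
  }
  g <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) default else v
  }
  width  <- g(256); height <- g(257)
  if (is.null(width) || is.null(height))
    stop(sprintf("read_tiff: missing dimensions in %s", path), call. = FALSE)
  bits   <- g(258, 8L)
  compression <- g(259, 1L)
  if (compression != 1L)
    stop(sprintf("read_tiff: only uncompressed TIFF is supported (%s)", path),
         call. = FALSE)
  spp    <- g(277, 1L)
  strip_offsets <- g(273)
  rows_per_strip <- g(278, height)
  if (is.null(strip_offsets))
    stop(sprintf("read_tiff: missing strip offsets in %s", path), call. = FALSE)
  if (g(284, 1L) != 1L)
    stop(sprintf("read_tiff: planar TIFF is not supported (%s)", path),
         call. = FALSE)
  if (!all(bits %in% c(8L, 16L)) || length(unique(bits)) != 1L)
    stop(sprintf("read_tiff: only 8/16-bit samples supported (%s)", path),
         call. = FALSE)
  bits <- bits[1L]
  samples <- integer(0)
  for (k in seq_along(strip_offsets)) {
    rows <- min(rows_per_strip, height - (k - 1L) * rows_per_strip)
    n <- rows * width * spp
    seek(con, strip_offsets[k])
    samples <- c(samples, if (bits == 8L)
      readBin(con, "integer", n, size = 1L, signed = FALSE)
    else
      readBin(con, "integer", n, size = 2L, signed = FALSE, endian = endian))
  }
  if (bits == 16L) samples <- samples / 65535 * 255 else samples <- samples
  # samples are interleaved row-major: (row, col, channel) fastest last
  a <- aperm(array(samples, dim = c(spp, width, height)), c(3L, 2L, 1L))
  nch <- min(spp, 3L)
  a <- a[, , seq_len(nch), drop = FALSE]
  if (nch == 1L) a <- array(rep(a, 3L), dim = c(height, width, 3L))
  if (nch == 2L) a <- array(rep(a[, , 1L], 3L), dim = c(height, width, 3L))
  a / 255
}
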