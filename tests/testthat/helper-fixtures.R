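# Shared fixture builders. Everything is generated in code at test
# time; nothing binary is stored in the repository.

# image from per-channel matrices (h x w), 0-based (x, y) convention
img_from_channels <- function(r, g, b) {
  rgb_image(array(c(r, g, b), dim = c(nrow(r), ncol(r), 3L)))
}

# uniform-colour image
uniform_img <- function(color, width = 4L, height = 3L) {
  img_from_channels(matrix(color[1], height, width),
                    matrix(color[2], height, width),
                    matrix(color[3], height, width))
}

# random 8-bit image, seeded
random_img <- function(width, height, seed) {
  with_seed_local(seed, {
    rgb_image(array(sample(0:255, height * width * 3L, replace = TRUE),
                    dim = c(height, width, 3L)))
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Minimal baseline TIFF writer used to build read fixtures: single or
# multi strip, 8- or 16-bit, gray or RGB, either byte order. Kept
# independent of the package reader; the reader itself was validated
# against tifffile-generated files during development.
write_tiff_fixture <- function(path, arr, bits = 8L, endian = "little",
                               rows_per_strip = NULL) {
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  h <- dim(arr)[1L]; w <- dim(arr)[2L]; spp <- dim(arr)[3L]
  if (is.null(rows_per_strip)) rows_per_strip <- h
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = endian)
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = endian)
  writeBin(charToRaw(if (endian == "little") "II" else "MM"), con)
  w16(42L); w32(8L)                       # IFD at byte 8
  n_strips <- ceiling(h / rows_per_strip)
  entries <- 10L
  ifd_size <- 2L + entries * 12L + 4L
  aux_off <- 8L + ifd_size                # external value area
  aux <- list()                           # name -> offset
  aux_bytes <- 0L
  reserve <- function(nvals, size) {
    off <- aux_off + aux_bytes
    aux_bytes <<- aux_bytes + nvals * size
    off
  }
  bits_off <- if (spp > 1L) reserve(spp, 2L) else NA
  strip_off_off <- if (n_strips > 1L) reserve(n_strips, 4L) else NA
  strip_cnt_off <- if (n_strips > 1L) reserve(n_strips, 4L) else NA
  data_off <- aux_off + aux_bytes
  bytes_per_sample <- bits / 8L
  rows_k <- pmin(rows_per_strip, h - (seq_len(n_strips) - 1L) * rows_per_strip)
  strip_bytes <- rows_k * w * spp * bytes_per_sample
  strip_offsets <- data_off + cumsum(c(0L, utils::head(strip_bytes, -1L)))
  entry <- function(tag, type, count, value, offset = NULL) {
    w16(tag); w16(type); w32(count)
    if (!is.null(offset)) w32(offset)
    else if (type == 3L) { w16(value); w16(0L) }
    else w32(value)
  }
  w16(entries)
  entry(256L, 3L, 1L, w)
  entry(257L, 3L, 1L, h)
  if (spp > 1L) entry(258L, 3L, spp, NA, offset = bits_off)
  else entry(258L, 3L, 1L, bits)
  entry(259L, 3L, 1L, 1L)                 # uncompressed
  entry(262L, 3L, 1L, if (spp == 1L) 1L else 2L)
  if (n_strips > 1L) entry(273L, 4L, n_strips, NA, offset = strip_off_off)
  else entry(273L, 4L, 1L, strip_offsets[1L])
  entry(277L, 3L, 1L, spp)
  entry(278L, 3L, 1L, rows_per_strip)
  if (n_strips > 1L) entry(279L, 4L, n_strips, NA, offset = strip_cnt_off)
  else entry(279L, 4L, 1L, strip_bytes[1L])
  entry(284L, 3L, 1L, 1L)                 # chunky
  w32(0L)                                 # no next IFD
  if (spp > 1L) w16(rep(bits, spp))
  if (n_strips > 1L) { w32(strip_offsets); w32(strip_bytes) }
  # interleaved row-major samples
  flat <- as.integer(aperm(arr, c(3L, 2L, 1L)))
  writeBin(flat, con, size = bytes_per_sample, endian = endian)
  invisible(path)
}

# default synthetic palette, used all over the segmentation tests
default_palette <- function() fixture_params()$colors
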