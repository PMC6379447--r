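#' Construct an RGB image
#'
#' The canonical raster representation used throughout ttcquant: a
#' `height x width x 3` integer array with channel values in `[0, 255]`,
#' ordered red, green, blue. Rows are pixel rows (y), columns are pixel
#' columns (x), so `img[y + 1, x + 1, ]` is the pixel at 0-based
#' coordinate `(x, y)`.
#'
#' @param arr numeric array of dimension `c(height, width, 3)` (or a
#'   `height x width` matrix, replicated across channels), values in
#'   `[0, 255]`.
#' @return an object of class `rgb_image`.
#' @export
rgb_image <- function(arr) {
  if (is.matrix(arr)) arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  if (!is.array(arr) || length(dim(arr)) != 3L || dim(arr)[3L] != 3L)
    stop("rgb_image: expected a height x width x 3 array", call. = FALSE)
  if (dim(arr)[1L] < 1L || dim(arr)[2L] < 1L)
    stop("rgb_image: width and height must be >= 1", call. = FALSE)
  if (anyNA(arr) || min(arr) < 0 || max(arr) > 255)
    stop("rgb_image: channel values must lie in [0, 255]", call. = FALSE)
  storage.mode(arr) <- "integer"
  structure(arr, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d (width x height), 8-bit RGB>\n",
              img_width(x), img_height(x)))
  invisible(x)
}

#' Image dimensions
#' @param image an `rgb_image`.
#' @return integer number of pixel columns (width) or rows (height).
#' @export
img_width <- function(image) dim(image)[2L]

#' @rdname img_width
#' @export
img_height <- function(image) dim(image)[1L]

#' Rectangular region of interest
#'
#' Half-open pixel rectangle `[x0, x1) x [y0, y1)` in 0-based
#' coordinates, `x` indexing columns and `y` rows. The user selects one
#' ROI per brain section; all analysis happens inside it.
#'
#' @param x0,y0 inclusive top-left corner (0-based).
#' @param x1,y1 exclusive bottom-right corner.
#' @return an object of class `roi`.
#' @export
roi <- function(x0, y0, x1, y1) {
  v <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  if (anyNA(v) || any(v != floor(v)))
    stop("roi: coordinates must be integers", call. = FALSE)
  if (x0 < 0 || y0 < 0)
    stop(sprintf("roi: origin must be non-negative (got x0=%d, y0=%d)", x0, y0),
         call. = FALSE)
  if (x1 <= x0)
    stop(sprintf("roi: empty rectangle, x1=%d <= x0=%d", x1, x0), call. = FALSE)
  if (y1 <= y0)
    stop(sprintf("roi: empty rectangle, y1=%d <= y0=%d", y1, y0), call. = FALSE)
  structure(as.list(stats::setNames(as.integer(v), names(v))), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi [%d,%d) x [%d,%d)>\n", x$x0, x$x1, x$y0, x$y1))
  invisible(x)
}

#' Full-frame ROI of an image
#' @param image an `rgb_image`.
#' @return the `roi` covering every pixel.
#' @export
full_roi <- function(image) roi(0L, 0L, img_width(image), img_height(image))

check_roi <- function(image, r) {
  if (!inherits(r, "roi")) r <- do.call(roi, as.list(unlist(r)[1:4]))
  if (r$x1 > img_width(image))
    stop(sprintf("roi: x1=%d exceeds image width %d", r$x1, img_width(image)),
         call. = FALSE)
  if (r$y1 > img_height(image))
    stop(sprintf("roi: y1=%d exceeds image height %d", r$y1, img_height(image)),
         call. = FALSE)
  r
}

#' Read an image file into the canonical RGB representation
#'
#' Accepts 8- or 16-bit PNG, JPEG, and baseline uncompressed TIFF.
#' Grayscale images are replicated across the three channels, alpha
#' channels are discarded, and 16-bit samples are rescaled to
#' `[0, 255]`. Channel bytes are taken at face value: no ICC/gamma
#' transform is applied, matching the behaviour of the original
#' supervised-thresholding tools this package reimplements.
#'
#' @param path path to a PNG, JPEG or TIFF file. Format is detected
#'   from the file's magic bytes, not its extension.
#' @return an [rgb_image].
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("load_image: path must be a single string", call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("load_image: file not found: %s", path), call. = FALSE)
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) < 4L)
    stop(sprintf("load_image: unreadable or truncated file: %s", path),
         call. = FALSE)
  if (identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
    a <- png::readPNG(path)
  } else if (identical(magic[1:2], as.raw(c(0xff, 0xd8)))) {
    a <- jpeg::readJPEG(path)
  } else if (identical(magic[1:2], charToRaw("II")) ||
             identical(magic[1:2], charToRaw("MM"))) {
    a <- read_tiff_baseline(path)
  } else {
    stop(sprintf("load_image: unsupported image format: %s", path),
         call. = FALSE)
  }
  # readPNG/readJPEG return doubles in [0,1]; 16-bit PNGs are already
  # normalised by 65535 so one round trip through *255 covers both depths.
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3L] >= 4L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3L] == 2L) a <- array(rep(a[, , 1L], 3L), dim = c(dim(a)[1:2], 3L))
  if (dim(a)[3L] == 1L) a <- array(rep(a[, , 1L], 3L), dim = c(dim(a)[1:2], 3L))
  rgb_image(round(a * 255))
}

#' Crop a region of interest
#'
#' @param image an [rgb_image].
#' @param r an [roi] (half-open, 0-based); must lie inside the image.
#' @return the `(x1-x0) x (y1-y0)` sub-image.
#' @export
crop_roi <- function(image, r) {
  r <- check_roi(image, r)
  rgb_image(unclass(image)[(r$y0 + 1L):r$y1, (r$x0 + 1L):r$x1, , drop = FALSE])
}

#' Write an RGB image or a binary mask as PNG
#'
#' Masks are written as 8-bit grayscale with members at 255 and
#' non-members at 0. Output is bit-reproducible for identical input.
#'
#' @param x an [rgb_image] or a logical matrix (mask).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_png <- function(x, path) {
  if (inherits(x, "rgb_image")) {
    png::writePNG(unclass(x) / 255, target = path)
  } else if (is.logical(x) && is.matrix(x)) {
    png::writePNG(matrix(as.numeric(x), nrow(x), ncol(x)), target = path)
  } else {
    stop("write_png: expected an rgb_image or a logical matrix", call. = FALSE)
  }
  invisible(path)
}
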