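#' Infarct mask by brightness binarization
#'
#' First stage of the two-stage extraction. On a dark plate the pale
#' (unstained, infarcted) tissue is the brightest content in the frame,
#' so a pixel is classified infarct iff its brightness strictly exceeds
#' `t_infarct`. Ties at the threshold are excluded ("greater than").
#'
#' @param image an [rgb_image] (typically an ROI crop).
#' @param t_infarct brightness threshold in `[0, 255]`.
#' @return logical `height x width` matrix, `TRUE` for infarct pixels.
#' @export
infarct_mask <- function(image, t_infarct) {
  stopifnot(inherits(image, "rgb_image"))
  check_threshold(t_infarct, "t_infarct")
  a <- unclass(image)
  px_brightness(a[, , 1L], a[, , 2L], a[, , 3L]) > t_infarct
}

#' Viable-tissue mask by red threshold plus hue gate
#'
#' Second stage. A pixel is classified as normal (viable, deep-red)
#' tissue iff its red channel strictly exceeds `t_red`, its hue lies in
#' the red band `[-60F, +60F]` (see [in_red_band()]), and it was not
#' already assigned to the infarct mask. The infarct assignment is made
#' first and is final: a pale pixel that also happens to pass the red
#' test is infarct, never normal.
#'
#' @param image an [rgb_image].
#' @param t_red red-channel threshold in `[0, 255]`.
#' @param f_hue hue factor in `[0, 0.2]`.
#' @param infarct logical matrix from [infarct_mask()], same dimensions
#'   as `image`.
#' @return logical `height x width` matrix, `TRUE` for viable tissue.
#' @export
normal_mask <- function(image, t_red, f_hue, infarct) {
  stopifnot(inherits(image, "rgb_image"))
  check_threshold(t_red, "t_red")
  check_f_hue(f_hue)
  if (!is.logical(infarct) || !is.matrix(infarct) ||
      nrow(infarct) != img_height(image) || ncol(infarct) != img_width(image))
    stop("normal_mask: infarct mask dimensions must match the image",
         call. = FALSE)
  a <- unclass(image)
  hue <- px_hue(as.vector(a[, , 1L]), as.vector(a[, , 2L]),
                as.vector(a[, , 3L]))
  red_ok <- a[, , 1L] > t_red
  hue_ok <- matrix(in_red_band(hue, f_hue), nrow(infarct), ncol(infarct))
  red_ok & hue_ok & !infarct
}

#' Analyze one brain section
#'
#' Runs the full per-section pipeline: crop the ROI, extract the
#' infarct mask by brightness binarization, extract the viable-tissue
#' mask by the red threshold gated through the hue band (excluding
#' infarct pixels), and report the infarct ratio
#' `100 * n_infarct / (n_infarct + n_normal)` — the infarct size as a
#' percentage of the whole coronal section area. Background pixels
#' inside the ROI belong to neither mask and never enter the
#' denominator.
#'
#' @param image an [rgb_image] of the whole photograph.
#' @param r an [roi] selecting one section.
#' @param config a [threshold_config].
#' @return an object of class `section_result` with fields `n_infarct`,
#'   `n_normal`, `ratio_percent`, `config`, `roi`.
#' @export
analyze_section <- function(image, r, config) {
  stopifnot(inherits(config, "threshold_config"))
  r <- check_roi(image, r)
  sub <- crop_roi(image, r)
  inf <- infarct_mask(sub, config$t_infarct)
  nor <- normal_mask(sub, config$t_red, config$f_hue, inf)
  n_i <- sum(inf)
  n_n <- sum(nor)
  if (n_i + n_n == 0L)
    stop("analyze_section: no tissue detected at these thresholds (empty section)",
         call. = FALSE)
  structure(list(n_infarct = n_i, n_normal = n_n,
                 ratio_percent = 100 * n_i / (n_i + n_n),
                 config = config, roi = r),
            class = "section_result")
}

#' @export
print.section_result <- function(x, ...) {
  cat(sprintf("<section_result infarct=%d normal=%d ratio_percent=%.2f>\n",
              x$n_infarct, x$n_normal, x$ratio_percent))
  invisible(x)
}

#' Sweep one threshold parameter over a list of values
#'
#' Batch emulation of the supervised scrollbar: the interactive tool
#' redraws the binarization while the analyst drags a slider; here the
#' same supervision is done by sweeping one parameter across candidate
#' values and inspecting the returned masks (or the overlays written by
#' the CLI).
#'
#' @param image an [rgb_image].
#' @param r an [roi].
#' @param base a [threshold_config]; parameters other than `parameter`
#'   are held at these values.
#' @param parameter one of `"t_infarct"`, `"t_red"`, `"f_hue"`.
#' @param values ordered vector of candidate values, each within the
#'   parameter's domain.
#' @return list with one entry per value: `list(value, result,
#'   infarct_mask, normal_mask)`.
#' @export
threshold_sweep <- function(image, r, base, parameter, values) {
  stopifnot(inherits(base, "threshold_config"))
  if (!parameter %in% c("t_infarct", "t_red", "f_hue"))
    stop(sprintf("threshold_sweep: unknown parameter '%s'", parameter),
         call. = FALSE)
  if (length(values) == 0L)
    stop("threshold_sweep: empty values list", call. = FALSE)
  r <- check_roi(image, r)
  sub <- crop_roi(image, r)
  lapply(values, function(v) {
    cfg <- base
    cfg[[parameter]] <- v
    cfg <- threshold_config(cfg$t_infarct, cfg$t_red, cfg$f_hue)
    inf <- infarct_mask(sub, cfg$t_infarct)
    nor <- normal_mask(sub, cfg$t_red, cfg$f_hue, inf)
    n_i <- sum(inf); n_n <- sum(nor)
    res <- structure(list(n_infarct = n_i, n_normal = n_n,
                          ratio_percent = if (n_i + n_n > 0)
                            100 * n_i / (n_i + n_n) else NA_real_,
                          config = cfg, roi = r),
                     class = "section_result")
    list(value = v, result = res, infarct_mask = inf, normal_mask = nor)
  })
}

# Otsu's criterion on a 256-bin histogram of integer values 0..255:
# returns the cut t maximizing between-class variance, classes {<=t}
# and {>t}. The criterion is flat between adjacent populated levels, so
# ties are broken by taking the midpoint of the maximizing plateau
# (centres the cut in the empty gap between classes).
otsu_threshold <- function(values) {
  values <- as.integer(round(values))
  h <- as.numeric(tabulate(values + 1L, nbins = 256L))
  n <- sum(h)
  if (sum(h > 0L) < 2L)
    stop("otsu: degenerate histogram (fewer than two distinct values)",
         call. = FALSE)
  lv <- 0:255
  w0 <- cumsum(h)
  m0 <- cumsum(h * lv)
  mu <- m0[256L]
  # between-class variance at cut t (index t+1), excluding degenerate cuts
  valid <- w0 > 0L & w0 < n
  bcv <- rep(-Inf, 256L)
  bcv[valid] <- (mu * w0[valid] - m0[valid] * n)^2 /
    (as.numeric(w0[valid]) * (n - w0[valid]))
  m <- max(bcv)
  plateau <- which(bcv >= m - 1e-9 * abs(m) - 1e-12)
  as.integer(floor((min(plateau) + max(plateau)) / 2)) - 1L
}

#' Suggest starting thresholds from the ROI histogram
#'
#' Convenience extension beyond the canonical supervised workflow, in
#' which the analyst chooses all three parameters by eye. Here
#' `t_infarct` is the Otsu split of the brightness histogram restricted
#' to provisional tissue pixels (pixels above the Otsu split of the
#' full brightness histogram, which separates the dark plate from
#' tissue), `t_red` is the Otsu split of the red-channel histogram, and
#' `f_hue` defaults to the widest band, 0.2. The result is a starting
#' point to be reviewed with [threshold_sweep()], not a replacement for
#' supervision.
#'
#' @param image an [rgb_image].
#' @param r an [roi]; must contain at least two distinct brightness
#'   levels.
#' @return a [threshold_config].
#' @export
suggest_thresholds <- function(image, r) {
  r <- check_roi(image, r)
  a <- unclass(crop_roi(image, r))
  bright <- px_brightness(as.vector(a[, , 1L]), as.vector(a[, , 2L]),
                          as.vector(a[, , 3L]))
  t_bg <- otsu_threshold(bright)          # plate vs tissue
  tissue <- bright[round(bright) > t_bg]
  t_inf <- if (length(unique(as.integer(round(tissue)))) >= 2L)
    otsu_threshold(tissue) else t_bg
  t_red <- otsu_threshold(as.vector(a[, , 1L]))
  threshold_config(t_infarct = t_inf, t_red = t_red, f_hue = 0.2)
}

#' Average the results of two independent analysts
#'
#' Study designs using supervised thresholding have each section
#' analyzed by two researchers independently; the section's infarct
#' size is the mean of their two ratios.
#'
#' @param a,b `section_result`s for the same section (ROIs of equal
#'   size).
#' @return the mean ratio, in percent.
#' @export
average_results <- function(a, b) {
  stopifnot(inherits(a, "section_result"), inherits(b, "section_result"))
  da <- c(a$roi$x1 - a$roi$x0, a$roi$y1 - a$roi$y0)
  db <- c(b$roi$x1 - b$roi$x0, b$roi$y1 - b$roi$y0)
  if (!identical(da, db))
    stop("average_results: results refer to ROIs of different size",
         call. = FALSE)
  (a$ratio_percent + b$ratio_percent) / 2
}

#' Remove small connected components from a mask
#'
#' Optional cleanup, OFF by default everywhere: the canonical method is
#' pure per-pixel thresholding. 4-connectivity.
#'
#' @param mask logical matrix.
#' @param min_size smallest component (in pixels) to keep.
#' @return logical matrix with small components removed.
#' @export
filter_small_components <- function(mask, min_size = 1L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (min_size <= 1L) return(mask)
  lab <- label_components(mask)
  keep <- which(tabulate(lab) >= min_size)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[lab %in% keep] <- TRUE
  out
}

# 4-connected labelling by iterative label propagation (small images).
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    nb <- lab
    if (h > 1L) {
      nb[-1, ] <- pmax(nb[-1, ], lab[-h, ] * mask[-1, ])
      nb[-h, ] <- pmax(nb[-h, ], lab[-1, ] * mask[-h, ])
    }
    if (w > 1L) {
      nb[, -1] <- pmax(nb[, -1], lab[, -w] * mask[, -1])
      nb[, -w] <- pmax(nb[, -w], lab[, -1] * mask[, -w])
    }
    if (identical(nb, lab)) break
    lab <- nb
  }
  # compact labels
  u <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

#' Write a colorized overlay of a segmentation
#'
#' Infarct pixels are drawn white, viable tissue deep red, everything
#' else black — the three classes the thresholds carve the ROI into.
#'
#' @param image the analyzed [rgb_image] (ROI crop); used for
#'   dimensions only.
#' @param infarct,normal logical masks from [infarct_mask()] /
#'   [normal_mask()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(image, infarct, normal, path) {
  h <- img_height(image); w <- img_width(image)
  a <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) {
    plane <- matrix(0, h, w)
    plane[infarct] <- 255
    plane[normal] <- c(180, 40, 40)[ch]
    a[, , ch] <- plane
  }
  write_png(rgb_image(a), path)
}

#' Section results as a CSV-ready data frame
#'
#' Stable column schema used by the CLI and accepted back by the
#' comparison command: `section_id, x0, y0, x1, y1, t_infarct, t_red,
#' f_hue, n_infarct, n_normal, ratio_percent`.
#'
#' @param results list of `section_result`s.
#' @param ids character vector of section identifiers.
#' @return data.frame, one row per result.
#' @export
results_table <- function(results, ids = as.character(seq_along(results))) {
  stopifnot(length(results) == length(ids))
  do.call(rbind, lapply(seq_along(results), function(i) {
    x <- results[[i]]
    data.frame(section_id = ids[i],
               x0 = x$roi$x0, y0 = x$roi$y0, x1 = x$roi$x1, y1 = x$roi$y1,
               t_infarct = x$config$t_infarct, t_red = x$config$t_red,
               f_hue = x$config$f_hue,
               n_infarct = x$n_infarct, n_normal = x$n_normal,
               ratio_percent = x$ratio_percent,
               stringsAsFactors = FALSE)
  }))
}
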