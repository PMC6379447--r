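#' Per-pixel brightness
#'
#' Brightness of an RGB pixel, defined as the arithmetic mean
#' `(r + g + b) / 3`. The mean (rather than `max(r, g, b)`) preserves
#' the ordering the staining method relies on — pale infarct brighter
#' than deep-red viable tissue brighter than the black background —
#' whereas under `max` pure red would equal white and the brightness
#' threshold could not separate the two tissue classes.
#'
#' All three arguments are vectorized and recycled together.
#'
#' @param r,g,b channel values in `[0, 255]`.
#' @return numeric brightness in `[0, 255]` (exact rational mean, not
#'   rounded).
#' @export
px_brightness <- function(r, g, b) {
  check_channel(r); check_channel(g); check_channel(b)
  (r + g + b) / 3
}

check_channel <- function(x) {
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    stop("channel values must lie in [0, 255]", call. = FALSE)
  invisible(x)
}

#' Per-pixel hue, signed degrees with red at zero
#'
#' Standard HSV hue computed from max/min channel arithmetic, then
#' mapped from `[0, 360)` to the signed range `(-180, 180]` so the
#' symmetric red band `[-60F, +60F]` used by the red filter is directly
#' expressible. Achromatic pixels (`r == g == b`) have no hue and
#' return `NA`; they never pass the red filter.
#'
#' @param r,g,b channel values in `[0, 255]`, vectorized.
#' @return hue in degrees in `(-180, 180]`, or `NA` for achromatic
#'   pixels.
#' @export
px_hue <- function(r, g, b) {
  check_channel(r); check_channel(g); check_channel(b)
  n <- max(length(r), length(g), length(b))
  r <- rep_len(as.numeric(r), n)
  g <- rep_len(as.numeric(g), n)
  b <- rep_len(as.numeric(b), n)
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  ch <- mx - mn
  h <- rep(NA_real_, n)
  i <- ch > 0 & mx == r
  h[i] <- 60 * (((g[i] - b[i]) / ch[i]) %% 6)
  i <- ch > 0 & mx == g & r < g        # max==g, not already claimed by red
  h[i] <- 60 * ((b[i] - r[i]) / ch[i] + 2)
  i <- ch > 0 & mx == b & r < b & g < b
  h[i] <- 60 * ((r[i] - g[i]) / ch[i] + 4)
  ifelse(h > 180, h - 360, h)
}

#' Red-band membership ("digital red filter")
#'
#' A pixel counts as red when its hue lies in `[-60F, +60F]` degrees,
#' `F` in `[0, 0.2]`. At the widest setting `F = 0.2` the band is
#' exactly `[-12, +12]` degrees; at `F = 0` only hue 0 passes.
#' Achromatic pixels (hue `NA`) never pass, so gray impurities are
#' rejected regardless of `F`.
#'
#' @param h hue in signed degrees as returned by [px_hue()] (`NA` for
#'   achromatic pixels); vectorized.
#' @param f_hue hue factor `F` in `[0, 0.2]`.
#' @return logical vector.
#' @export
in_red_band <- function(h, f_hue) {
  check_f_hue(f_hue)
  half <- 60 * f_hue
  !is.na(h) & h >= -half & h <= half
}

check_f_hue <- function(f_hue) {
  if (length(f_hue) != 1L || is.na(f_hue) || f_hue < 0 || f_hue > 0.2)
    stop("f_hue must be a single value in [0, 0.2]", call. = FALSE)
  invisible(f_hue)
}

check_threshold <- function(t, name) {
  if (length(t) != 1L || is.na(t) || t < 0 || t > 255)
    stop(sprintf("%s must be a single value in [0, 255]", name),
         call. = FALSE)
  invisible(t)
}

#' Threshold configuration
#'
#' The three user-supervised tuning parameters of the analysis:
#' `t_infarct`, the brightness threshold above which a pixel is called
#' infarct; `t_red`, the red-channel threshold above which a non-infarct
#' pixel may be called viable tissue; and `f_hue`, the hue factor `F`
#' controlling the width of the red band `[-60F, +60F]` that gates the
#' viable-tissue test. In the original interactive tool these are three
#' scrollbars adjusted under the analyst's eye; here they are explicit
#' values, typically explored with [threshold_sweep()].
#'
#' @param t_infarct brightness threshold in `[0, 255]`.
#' @param t_red red-channel threshold in `[0, 255]`.
#' @param f_hue hue factor in `[0, 0.2]`; default 0.2, the widest band,
#'   so the filter only ever removes clearly non-red pixels.
#' @return an object of class `threshold_config`.
#' @export
threshold_config <- function(t_infarct, t_red, f_hue = 0.2) {
  check_threshold(t_infarct, "t_infarct")
  check_threshold(t_red, "t_red")
  check_f_hue(f_hue)
  structure(list(t_infarct = t_infarct, t_red = t_red, f_hue = f_hue),
            class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat(sprintf("<threshold_config t_infarct=%g t_red=%g f_hue=%g>\n",
              x$t_infarct, x$t_red, x$f_hue))
  invisible(x)
}
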