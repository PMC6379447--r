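# Independent oracles the implementation is checked against.

# hue via grDevices::rgb2hsv (independent HSV implementation);
# NA for achromatic pixels, signed degrees with red at 0
oracle_hue <- function(r, g, b) {
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  h <- hsv["h", ] * 360
  h[hsv["s", ] == 0] <- NA_real_
  ifelse(h > 180, h - 360, h)
}

# naive per-pixel double loop applying the published classification
# conditions literally; deliberately scalar, no vectorized reuse
oracle_masks <- function(image, t_infarct, t_red, f_hue) {
  a <- unclass(image)
  h <- dim(a)[1L]; w <- dim(a)[2L]
  inf <- matrix(FALSE, h, w); nor <- matrix(FALSE, h, w)
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      r <- a[y, x, 1L]; g <- a[y, x, 2L]; b <- a[y, x, 3L]
      bright <- (r + g + b) / 3
      if (bright > t_infarct) {
        inf[y, x] <- TRUE
      } else if (r > t_red) {
        mx <- max(r, g, b); mn <- min(r, g, b)
        if (mx > mn) {                    # chromatic: hue defined
          hue <- if (mx == r) 60 * (((g - b) / (mx - mn)) %% 6)
                 else if (mx == g) 60 * ((b - r) / (mx - mn) + 2)
                 else 60 * ((r - g) / (mx - mn) + 4)
          if (hue > 180) hue <- hue - 360
          if (hue >= -60 * f_hue && hue <= 60 * f_hue) nor[y, x] <- TRUE
        }
      }
    }
  }
  list(infarct = inf, normal = nor)
}

# exhaustive Otsu criterion: between-class variance evaluated at every
# cut 0..254 by direct class means, no histogram shortcuts
oracle_otsu_bcv <- function(values, t) {
  v <- as.integer(round(values))
  lo <- v[v <= t]; hi <- v[v > t]
  if (length(lo) == 0L || length(hi) == 0L) return(-Inf)
  w0 <- length(lo) / length(v); w1 <- 1 - w0
  w0 * w1 * (mean(lo) - mean(hi))^2
}

# ground-truth ratio directly from the label matrix
oracle_truth_fraction <- function(labels) {
  100 * sum(labels == "infarct") /
    (sum(labels == "infarct") + sum(labels == "normal"))
}
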