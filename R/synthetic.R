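#' Parameters for a synthetic TTC-section photograph
#'
#' Describes the stated world the segmentation method assumes: one
#' elliptical coronal section on a near-black plate, a pale infarct
#' sub-region inside it, and optionally a few non-red impurity blobs on
#' the plate. The default palette — background `(8,8,8)`, viable
#' tissue `(170,30,30)` (hue 0, deep red), infarct `(230,225,215)`
#' (pale, high brightness) — satisfies the orderings the method relies
#' on: brightness infarct > normal > background, red normal >
#' background. These orderings are asserted at construction.
#'
#' The infarct geometry is either an explicit ellipse, a half-plane cut
#' `x >= x_cut` through the section, or a target area fraction
#' (`infarct = list(fraction = f)`), realised as a concentric ellipse
#' scaled by `sqrt(f)` and offset toward the right-hand side of the
#' section, roughly where a middle-cerebral-artery infarct sits.
#'
#' @param width,height image size in pixels.
#' @param section_center,section_axes ellipse centre `(cx, cy)` and
#'   semi-axes `(a, b)` of the section, in pixels (0-based coordinates).
#' @param infarct one of `list(fraction = f)` with `f` in `[0, 1]`,
#'   `list(center = c(cx, cy), axes = c(a, b))`, or
#'   `list(x_cut = x)`; `NULL` for no infarct.
#' @param colors named list with RGB triplets `background`, `normal`,
#'   `infarct`.
#' @param noise_sd per-channel Gaussian noise standard deviation, in
#'   channel units (0 = noiseless).
#' @param impurities list of blobs, each
#'   `list(center = , axes = , color = )`; drawn on background only, so
#'   tissue ground truth is unaffected. Colours must be non-red
#'   (outside the widest hue band) — that is what the hue filter
#'   exists to reject.
#' @param seed RNG seed (mandatory; there is no unseeded path).
#' @return an object of class `fixture_params`.
#' @export
fixture_params <- function(width = 160L, height = 120L,
                           section_center = c(80, 60),
                           section_axes = c(60, 45),
                           infarct = list(fraction = 0.3),
                           colors = list(background = c(8, 8, 8),
                                         normal = c(170, 30, 30),
                                         infarct = c(230, 225, 215)),
                           noise_sd = 0,
                           impurities = list(),
                           seed = 1L) {
  stopifnot(width >= 1, height >= 1, noise_sd >= 0, length(seed) == 1L)
  for (nm in c("background", "normal", "infarct")) {
    if (is.null(colors[[nm]]) || length(colors[[nm]]) != 3L)
      stop(sprintf("fixture_params: colors$%s must be an RGB triplet", nm),
           call. = FALSE)
    check_channel(colors[[nm]])
  }
  b <- vapply(colors, function(x) px_brightness(x[1], x[2], x[3]), 0)
  if (!(b[["infarct"]] > b[["normal"]] && b[["normal"]] > b[["background"]]))
    stop("fixture_params: need brightness(infarct) > brightness(normal) > brightness(background)",
         call. = FALSE)
  if (!(colors$normal[1] > colors$background[1]))
    stop("fixture_params: need red(normal) > red(background)", call. = FALSE)
  for (blob in impurities) {
    check_channel(blob$color)
    bh <- px_hue(blob$color[1], blob$color[2], blob$color[3])
    if (in_red_band(bh, 0.2))
      stop("fixture_params: impurity colours must lie outside the widest red band",
           call. = FALSE)
  }
  if (section_center[1] - section_axes[1] < 0 ||
      section_center[1] + section_axes[1] > width - 1 ||
      section_center[2] - section_axes[2] < 0 ||
      section_center[2] + section_axes[2] > height - 1)
    stop("fixture_params: section ellipse extends outside the image",
         call. = FALSE)
  if (!is.null(infarct) && !is.null(infarct$fraction)) {
    f <- infarct$fraction
    stopifnot(f >= 0, f <= 1)
    if (f == 0) {
      infarct <- NULL
    } else {
      s <- sqrt(f)
      dx <- 0.5 * section_axes[1] * (1 - s)
      infarct <- list(center = c(section_center[1] + dx, section_center[2]),
                      axes = s * section_axes)
    }
  }
  p <- structure(list(width = as.integer(width), height = as.integer(height),
                      section_center = section_center,
                      section_axes = section_axes,
                      infarct = infarct, colors = colors,
                      noise_sd = noise_sd, impurities = impurities,
                      seed = as.integer(seed)),
                 class = "fixture_params")
  labs <- render_labels(p)
  if (!is.null(infarct) && !any(labs == "infarct"))
    stop("fixture_params: infarct geometry contains no pixels", call. = FALSE)
  p
}

# pixel-centre ellipse test on the 0-based grid
inside_ellipse <- function(width, height, center, axes) {
  x <- matrix(rep(0:(width - 1), each = height), height, width)
  y <- matrix(rep(0:(height - 1), width), height, width)
  ((x - center[1]) / axes[1])^2 + ((y - center[2]) / axes[2])^2 <= 1
}

# noiseless class labels; impurities only ever overwrite background,
# and an infarct geometry is clipped to the section (containment)
render_labels <- function(p) {
  sec <- inside_ellipse(p$width, p$height, p$section_center, p$section_axes)
  labs <- matrix("background", p$height, p$width)
  labs[sec] <- "normal"
  if (!is.null(p$infarct)) {
    inf <- if (!is.null(p$infarct$x_cut)) {
      x <- matrix(rep(0:(p$width - 1), each = p$height), p$height, p$width)
      x >= p$infarct$x_cut
    } else {
      inside_ellipse(p$width, p$height, p$infarct$center, p$infarct$axes)
    }
    labs[sec & inf] <- "infarct"
  }
  for (blob in p$impurities) {
    bl <- inside_ellipse(p$width, p$height, blob$center, blob$axes)
    labs[bl & labs == "background"] <- "impurity"
  }
  labs
}

#' Generate one synthetic section with ground truth
#'
#' Renders the class geometry of `params`, assigns each pixel its class
#' colour, adds i.i.d. per-channel Gaussian noise (sd `noise_sd`,
#' rounded and clipped to `[0, 255]`), and returns both the image and
#' the noiseless per-pixel ground truth. Deterministic given
#' `params$seed`; the caller's RNG state is left untouched.
#'
#' @param params a [fixture_params].
#' @return list with `image` (an [rgb_image]) and `truth`, itself a
#'   list with `labels` (character matrix,
#'   background/normal/infarct/impurity) and `true_fraction`
#'   (`100 * n_infarct / (n_infarct + n_normal)`, percent).
#' @export
generate_section <- function(params) {
  stopifnot(inherits(params, "fixture_params"))
  labs <- render_labels(params)
  a <- array(0, dim = c(params$height, params$width, 3L))
  for (ch in 1:3) {
    plane <- matrix(params$colors$background[ch], params$height, params$width)
    plane[labs == "normal"] <- params$colors$normal[ch]
    plane[labs == "infarct"] <- params$colors$infarct[ch]
    a[, , ch] <- plane
  }
  for (blob in params$impurities) {
    bl <- inside_ellipse(params$width, params$height, blob$center, blob$axes) &
      labs == "impurity"
    for (ch in 1:3) {
      plane <- a[, , ch]
      plane[bl] <- blob$color[ch]
      a[, , ch] <- plane
    }
  }
  if (params$noise_sd > 0) {
    a <- with_seed(params$seed, {
      a + array(stats::rnorm(length(a), 0, params$noise_sd), dim = dim(a))
    })
    a <- pmin(pmax(round(a), 0), 255)
  }
  n_i <- sum(labs == "infarct"); n_n <- sum(labs == "normal")
  list(image = rgb_image(a),
       truth = list(labels = labs,
                    true_fraction = if (n_i + n_n > 0)
                      100 * n_i / (n_i + n_n) else NA_real_))
}

# run code under a given seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a seeded multi-animal synthetic study
#'
#' One fixture per animal, with target infarct fractions drawn
#' uniformly in `fraction_range` and per-animal seeds derived from
#' `seed`. Emulates the design used to validate supervised-threshold
#' tools against manual tracing: a cohort of occlusion animals whose
#' infarct sizes span the range seen in practice.
#'
#' @param n_animals number of animals (>= 2).
#' @param fraction_range `c(lo, hi)` in percent, `0 <= lo <= hi <= 100`.
#' @param params a [fixture_params] template; geometry, palette and
#'   noise are taken from it, fraction and seed are overridden per
#'   animal.
#' @param seed study-level RNG seed.
#' @return list with `fixtures` (list of `generate_section()` outputs)
#'   and `manifest` (data.frame: animal, seed, target_fraction,
#'   true_fraction).
#' @export
generate_study <- function(n_animals, fraction_range = c(10, 50),
                           params = fixture_params(), seed = 1L) {
  stopifnot(n_animals >= 2)
  lo <- fraction_range[1]; hi <- fraction_range[2]
  if (is.na(lo) || is.na(hi) || lo < 0 || hi > 100 || lo > hi)
    stop("generate_study: fraction_range must satisfy 0 <= lo <= hi <= 100",
         call. = FALSE)
  draws <- with_seed(seed, list(
    fractions = stats::runif(n_animals, lo, hi),
    seeds = sample.int(.Machine$integer.max, n_animals)
  ))
  fixtures <- vector("list", n_animals)
  manifest <- data.frame(animal = seq_len(n_animals),
                         seed = draws$seeds,
                         target_fraction = draws$fractions,
                         true_fraction = NA_real_)
  for (i in seq_len(n_animals)) {
    p <- fixture_params(width = params$width, height = params$height,
                        section_center = params$section_center,
                        section_axes = params$section_axes,
                        infarct = list(fraction = draws$fractions[i] / 100),
                        colors = params$colors,
                        noise_sd = params$noise_sd,
                        impurities = params$impurities,
                        seed = draws$seeds[i])
    fixtures[[i]] <- generate_section(p)
    manifest$true_fraction[i] <- fixtures[[i]]$truth$true_fraction
  }
  list(fixtures = fixtures, manifest = manifest)
}

#' Mid-gap analysis thresholds for a synthetic palette
#'
#' The supervised workflow places each threshold by eye in the gap
#' between the class levels it must separate; for a known synthetic
#' palette the canonical choice is the gap midpoint: `t_infarct`
#' halfway between the brightness of normal and infarct tissue,
#' `t_red` halfway between the red channel of background and normal
#' tissue, and the widest hue band `f_hue = 0.2` (the filter exists to
#' reject impurities, not to trim red tissue).
#'
#' @param colors palette list as in [fixture_params()].
#' @return a [threshold_config].
#' @export
midgap_config <- function(colors = fixture_params()$colors) {
  b <- vapply(colors, function(x) px_brightness(x[1], x[2], x[3]), 0)
  threshold_config(
    t_infarct = (b[["normal"]] + b[["infarct"]]) / 2,
    t_red = (colors$background[1] + colors$normal[1]) / 2,
    f_hue = 0.2
  )
}

#' Default impurity blobs for robustness tests
#'
#' Three small ellipses on the plate, outside the default section: a
#' gray blob (achromatic — no hue), a green one and a blue one, i.e.
#' the non-red contaminants the hue filter is meant to reject. The gray
#' level is chosen bright enough to pass a typical red-channel
#' threshold, so only the hue gate rejects it.
#'
#' @return list of blobs suitable for `fixture_params(impurities = )`.
#' @export
default_impurities <- function() {
  list(
    list(center = c(12, 12), axes = c(8, 7), color = c(120, 120, 120)),
    list(center = c(148, 12), axes = c(7, 8), color = c(40, 140, 40)),
    list(center = c(12, 108), axes = c(8, 8), color = c(60, 60, 200))
  )
}
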