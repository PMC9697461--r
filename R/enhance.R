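# Luminance-adaptation-style tone mapping and training-set augmentation.
#
# The tone operators are surround-adaptive exponent transforms: each pixel's
# normalized luminance v is raised to an exponent that decreases where the
# Gaussian-blurred surround is dark, so dark regions are brightened and
# their local contrast amplified while bright regions are left nearly
# untouched (highlight range mildly compressed). The single-stage transform
# (slat) applies one strong pass and emphasizes local detail; the
# multi-stage transform (mlat) cascades milder passes, which acts more like
# global tone compression.

#' Tone-mapping configuration
#'
#' @param surround_sigma Gaussian surround scale in pixels (> 0).
#' @param strength Adaptation strength (>= 0); 0 is the identity.
#' @param stages Number of cascaded stages (1 = single-stage).
#' @return An object of class `tone_map_config`.
#' @export
tone_map_config <- function(surround_sigma = 24, strength = 0.8, stages = 1L) {
  assert_that(surround_sigma > 0, "surround_sigma must be > 0")
  assert_that(strength >= 0, "strength must be >= 0")
  assert_that(stages >= 1, "stages must be >= 1")
  structure(list(surround_sigma = surround_sigma, strength = strength,
                 stages = as.integer(stages)),
            class = "tone_map_config")
}

# One surround-adaptive pass on a normalized [0,1] image (not yet rounded):
# out = s^e * (v/s)^c, where s is the Gaussian surround, e < 1 brightens in
# proportion to surround darkness (tone mapping), and c > 1 amplifies the
# center/surround ratio (local detail). A flat field has v = s, so it maps
# to the constant s^e; strength 0 gives e = c = 1, the identity.
lat_pass <- function(v, surround_sigma, strength) {
  if (strength == 0) return(v)
  sigma <- min(surround_sigma, (min(dim(v)) - 5) / 6)  # keep the kernel inside small images
  surround <- as.matrix(EBImage::gblur(v, sigma = max(sigma, 0.5)))
  surround <- pmin(pmax(surround, 0.02), 1)
  expo <- 1 / (1 + strength * (1 - surround))
  detail <- 1 + 0.4 * strength
  out <- surround^expo * (pmax(v, 0) / surround)^detail
  pmin(pmax(out, 0), 1)
}

#' Single-stage luminance adaptation transform
#'
#' Strongly enhances local detail; dark images become brighter overall.
#' Constant images stay constant and `strength = 0` is the identity (within
#' rounding).
#'
#' @param image 8-bit grayscale matrix (0..255).
#' @param cfg A [tone_map_config()]; `stages` is ignored (a single pass is
#'   applied).
#' @return Tone-mapped 8-bit image matrix.
#' @export
slat <- function(image, cfg = tone_map_config()) {
  check_image(image)
  v <- image / 255
  round(clamp255(255 * lat_pass(v, cfg$surround_sigma, cfg$strength)))
}

#' Multi-stage luminance adaptation transform
#'
#' Cascades `cfg$stages` milder passes (total strength split across
#' stages), compressing the global tone rather than local detail. With
#' `stages = 1` it reduces to [slat()] on the same configuration.
#'
#' @inheritParams slat
#' @return Tone-mapped 8-bit image matrix.
#' @export
mlat <- function(image, cfg = tone_map_config(stages = 3L)) {
  check_image(image)
  v <- image / 255
  per_stage <- cfg$strength / cfg$stages
  for (s in seq_len(cfg$stages)) v <- lat_pass(v, cfg$surround_sigma, per_stage)
  round(clamp255(255 * v))
}

#' Gamma correction
#'
#' Per-pixel `255 * (v / 255) ^ gamma`, rounded.
#'
#' @param image 8-bit grayscale matrix.
#' @param gamma Positive exponent; < 1 brightens, > 1 darkens.
#' @return Corrected 8-bit image matrix.
#' @export
gamma_correct <- function(image, gamma) {
  check_image(image)
  assert_that(is.numeric(gamma) && length(gamma) == 1 && gamma > 0,
              "gamma must be a single positive number")
  round(255 * (image / 255)^gamma)
}

#' Augmentation configuration
#'
#' @param crop_fraction Side fraction of the random crop window (0, 1];
#'   default 0.8 (about 80% of the 512 x 512 network input).
#' @param flip_prob Probability of a horizontal flip.
#' @param gamma_values Gamma exponents used when expanding a training set.
#' @param lat_variants Subset of `c("slat", "mlat")` used when expanding.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(crop_fraction = 0.8, flip_prob = 0.5,
                                gamma_values = c(0.75, 1.25),
                                lat_variants = c("slat", "mlat")) {
  assert_that(crop_fraction > 0 && crop_fraction <= 1,
              "crop_fraction must be in (0, 1]")
  assert_that(flip_prob >= 0 && flip_prob <= 1, "flip_prob must be in [0, 1]")
  assert_that(all(gamma_values > 0), "gamma_values must be positive")
  assert_that(all(lat_variants %in% c("slat", "mlat")),
              "lat_variants must be a subset of c('slat', 'mlat')")
  structure(list(crop_fraction = crop_fraction, flip_prob = flip_prob,
                 gamma_values = gamma_values, lat_variants = lat_variants),
            class = "augmentation_config")
}

#' Joint random crop of an image and its masks
#'
#' Crops a `round(fraction * H) x round(fraction * W)` window at a uniform
#' random top-left position, applies the same window to every mask, and
#' resizes back to the original size (bilinear for the image, nearest
#' neighbour for masks). Uses the current RNG state.
#'
#' @param image 8-bit grayscale matrix.
#' @param masks List of 0/1 matrices sharing the image's shape.
#' @param fraction Crop side fraction in (0, 1].
#' @return List with `image`, `masks`, and the applied `window`
#'   (row0, col0, height, width in 1-based matrix coordinates).
#' @export
augment_random_crop <- function(image, masks = list(), fraction = 0.8) {
  check_image(image)
  assert_that(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
  for (m in masks) { check_mask(m); check_same_shape(image, m, "image and masks") }
  h <- nrow(image); w <- ncol(image)
  ch <- round(fraction * h); cw <- round(fraction * w)
  r0 <- if (h > ch) sample.int(h - ch + 1L, 1L) else 1L
  c0 <- if (w > cw) sample.int(w - cw + 1L, 1L) else 1L
  rows <- r0:(r0 + ch - 1L); cols <- c0:(c0 + cw - 1L)
  img_c <- image[rows, cols, drop = FALSE]
  out_img <- if (ch == h && cw == w) img_c else resize_image(img_c, h, w, "bilinear")
  out_masks <- lapply(masks, function(m) {
    mc <- m[rows, cols, drop = FALSE]
    if (ch == h && cw == w) mc else resize_image(mc, h, w, "nearest")
  })
  list(image = out_img, masks = out_masks,
       window = c(row0 = r0, col0 = c0, height = ch, width = cw))
}

#' Joint horizontal flip of an image, masks and box annotations
#'
#' With probability `flip_prob` mirrors the image left-right together with
#' every mask; normalized box centers transform as `cx -> 1 - cx`. The
#' mandible is left/right symmetric, so horizontal flips are the only
#' anatomically valid mirror.
#'
#' @param image 8-bit grayscale matrix.
#' @param masks List of 0/1 matrices.
#' @param flip_prob Probability of flipping (draws from the current RNG).
#' @param boxes Optional detections data.frame (pixel boxes) flipped jointly.
#' @return List with `image`, `masks`, `boxes`, and logical `flipped`.
#' @export
augment_flip <- function(image, masks = list(), flip_prob = 0.5, boxes = NULL) {
  check_image(image)
  assert_that(flip_prob >= 0 && flip_prob <= 1, "flip_prob must be in [0, 1]")
  flip <- stats::runif(1) < flip_prob
  if (!flip) return(list(image = image, masks = masks, boxes = boxes, flipped = FALSE))
  w <- ncol(image)
  fl <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  out_boxes <- boxes
  if (!is.null(boxes) && nrow(boxes) > 0) {
    x0 <- w - boxes$x1; x1 <- w - boxes$x0
    out_boxes$x0 <- x0; out_boxes$x1 <- x1
  }
  list(image = fl(image), masks = lapply(masks, fl), boxes = out_boxes, flipped = TRUE)
}

#' Expand a training set with tone-mapped variants
#'
#' Returns the original images plus one tone-mapped copy per enabled
#' variant, so the output size is `length(images) * (1 + n_variants)`:
#' e.g. 360 images with slat and mlat enabled yield 1080.
#'
#' @param images List of 8-bit image matrices.
#' @param variants Character subset of `c("slat", "mlat", "gamma")`.
#' @param cfg A [tone_map_config()] used for the LAT variants.
#' @param gamma_values Exponents used when `"gamma"` is enabled (each value
#'   contributes one variant).
#' @return List of image matrices; originals first, then per-variant copies.
#' @export
expand_training_set <- function(images, variants = c("slat", "mlat"),
                                cfg = tone_map_config(),
                                gamma_values = numeric()) {
  assert_that(length(images) >= 1, "images must be a nonempty list")
  assert_that(all(variants %in% c("slat", "mlat", "gamma")),
              "variants must be a subset of c('slat', 'mlat', 'gamma')")
  out <- images
  for (v in variants) {
    if (v == "slat") out <- c(out, lapply(images, slat, cfg = cfg))
    if (v == "mlat") out <- c(out, lapply(images, mlat, cfg = tone_map_config(
      surround_sigma = cfg$surround_sigma, strength = cfg$strength,
      stages = max(cfg$stages, 3L))))
    if (v == "gamma") {
      for (g in gamma_values) out <- c(out, lapply(images, gamma_correct, gamma = g))
    }
  }
  out
}

# Resize helper shared across modules; mode "bilinear" for images,
# "nearest" for label masks (keeps masks binary).
resize_image <- function(m, height, width, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  if (nrow(m) == height && ncol(m) == width) return(m)
  if (mode == "nearest") {
    ri <- pmin(nrow(m), pmax(1L, round((seq_len(height) - 0.5) * nrow(m) / height + 0.5)))
    ci <- pmin(ncol(m), pmax(1L, round((seq_len(width) - 0.5) * ncol(m) / width + 0.5)))
    out <- m[ri, ci, drop = FALSE]
  } else {
    out <- as.matrix(EBImage::resize(m, w = height, h = width, filter = "bilinear"))
  }
  out
}
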