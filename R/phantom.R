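# Synthetic panoramic-radiograph phantoms with paired ground truth.
#
# A phantom emulates the features the detection pipeline depends on: a
# U-shaped mandibular arch rendered as a bright bone band on a darker,
# smoothly shaded background; a tooth row band sitting on the anterior part
# of the arch (with periodic interdental seams — the classic source of false
# fracture lines); and one or more fractures drawn from six anatomical
# classes and three morphologies. Oblique fractures are radiolucent gaps
# crossing the bone, shear fractures are brightness steps without a gap, and
# displaced (dislocated condyle) fractures are overlapping bone contours
# with no crack line at all — which is why they carry a box annotation but
# no line-mask pixels.

#' Phantom generator configuration
#'
#' Defaults reproduce the study conditions of the emulated clinical corpus:
#' the six-class fracture distribution follows the training-set frequencies
#' (symphysis 153, body 145, angle 183, ramus 91, condyle 39, coronoid 13 of
#' 624), and the per-image fracture count is 1 + Poisson(0.7) (mean 1.7,
#' close to 624 fractures over 360 radiographs).
#'
#' @param width,height Image size in pixels (>= 128). 512 is the network
#'   input size used for full-scale generation; 128 is the desk-scale test
#'   profile.
#' @param class_probs Probabilities for the six classes in
#'   [fracture_classes()] order; must sum to 1.
#' @param shape_probs Probabilities for (oblique_gap, shear_step, displaced);
#'   must sum to 1. A displaced draw for a non-condyle class is re-drawn
#'   between the first two morphologies, so displaced fractures only ever
#'   occur on the condyle.
#' @param fracture_excess_rate Poisson rate of fractures beyond the first.
#' @param noise_sigma Additive Gaussian noise, gray levels.
#' @param line_thickness Ground-truth fracture-line thickness in pixels.
#' @param gap_range Min/max radiolucent gap width (pixels) for oblique
#'   fractures.
#' @param seed Integer seed; the generator derives one child seed per image,
#'   so a dataset is a pure function of (config, n_images).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(width = 512, height = 512,
                           class_probs = c(153, 145, 183, 91, 39, 13) / 624,
                           shape_probs = c(0.55, 0.35, 0.10),
                           fracture_excess_rate = 0.7,
                           noise_sigma = 4,
                           line_thickness = 3,
                           gap_range = c(3, 6),
                           seed = 1L) {
  assert_that(width >= 128 && height >= 128, "width and height must be >= 128")
  assert_that(length(class_probs) == 6 && all(class_probs >= 0) &&
                abs(sum(class_probs) - 1) <= 1e-9,
              "class_probs must be 6 nonnegative values summing to 1")
  assert_that(length(shape_probs) == 3 && all(shape_probs >= 0) &&
                abs(sum(shape_probs) - 1) <= 1e-9,
              "shape_probs must be 3 nonnegative values summing to 1")
  assert_that(fracture_excess_rate >= 0, "fracture_excess_rate must be >= 0")
  assert_that(noise_sigma >= 0, "noise_sigma must be >= 0")
  assert_that(line_thickness >= 1, "line_thickness must be >= 1")
  structure(list(width = as.integer(width), height = as.integer(height),
                 class_probs = as.numeric(class_probs),
                 shape_probs = as.numeric(shape_probs),
                 fracture_excess_rate = fracture_excess_rate,
                 noise_sigma = noise_sigma,
                 line_thickness = as.integer(line_thickness),
                 gap_range = as.numeric(gap_range),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Sample anatomical fracture classes
#'
#' Draws `n` class labels i.i.d. from the given probabilities using the
#' current RNG state.
#'
#' @param n Number of fractures to sample (>= 1).
#' @param probs 6-vector of class probabilities summing to 1.
#' @return Character vector of `n` labels from [fracture_classes()].
#' @export
sample_fracture_classes <- function(n, probs = phantom_config()$class_probs) {
  assert_that(n >= 1, "n must be >= 1")
  assert_that(length(probs) == 6 && all(probs >= 0) && abs(sum(probs) - 1) <= 1e-9,
              "probs must be 6 nonnegative values summing to 1")
  sample(fracture_classes(), size = n, replace = TRUE, prob = probs)
}

# Arc-parameter intervals per class, symmetric left/right; together they
# cover [0, 1] exactly. Middle classes occupy the anterior arch, side
# classes the two posterior ends.
sector_map <- function() {
  data.frame(
    klass = c("condyle", "coronoid", "ramus", "angle", "body", "symphysis",
              "body", "angle", "ramus", "coronoid", "condyle"),
    t0 = c(0.000, 0.035, 0.075, 0.175, 0.285, 0.450, 0.550, 0.715, 0.825, 0.925, 0.965),
    t1 = c(0.035, 0.075, 0.175, 0.285, 0.450, 0.550, 0.715, 0.825, 0.925, 0.965, 1.000),
    stringsAsFactors = FALSE
  )
}

arch_point <- function(t, width, height) {
  cbind(x = width * (0.16 + 0.68 * t),
        y = height * (0.80 - 0.58 * (2 * t - 1)^2))
}

#' Build the mandible scene geometry for a phantom
#'
#' The arch is a parabolic band whose arc parameter t runs from the left
#' condyle (t = 0) through the symphysis (t = 0.5) to the right condyle
#' (t = 1); anatomical sectors are fixed, symmetric arc intervals. The tooth
#' row is a closed polygon following an offset of the anterior arch.
#'
#' @param config A [phantom_config()].
#' @return An object of class `mandible_scene` with elements `arch_polyline`
#'   (dense n x 2 matrix of x, y), `arch_t` (arc parameters), `sector_map`,
#'   `tooth_polygon`, and `bone_halfwidth`.
#' @export
build_scene <- function(config) {
  assert_that(inherits(config, "phantom_config"), "config must be a phantom_config")
  w <- config$width; h <- config$height
  hw <- 0.055 * min(w, h)
  n_pts <- 4L * max(w, h)
  tt <- seq(0, 1, length.out = n_pts)
  arch <- arch_point(tt, w, h)

  # tooth row: offset of the anterior arch (t in [0.30, 0.70]) raised above
  # the bone band
  t_tooth <- seq(0.30, 0.70, length.out = 200L)
  mid <- arch_point(t_tooth, w, h)
  mid[, "y"] <- mid[, "y"] - 1.9 * hw
  half <- 0.95 * hw
  poly <- rbind(cbind(mid[, "x"], mid[, "y"] - half),
                cbind(rev(mid[, "x"]), rev(mid[, "y"]) + half))
  poly[, 1] <- pmin(pmax(poly[, 1], 1), w - 1)
  poly[, 2] <- pmin(pmax(poly[, 2], 1), h - 1)

  structure(list(arch_polyline = arch, arch_t = tt, sector_map = sector_map(),
                 tooth_polygon = poly, bone_halfwidth = hw,
                 width = w, height = h),
            class = "mandible_scene")
}

# Sample one fracture spec of a given class and shape on the scene, using
# the current RNG state.
sample_fracture_spec <- function(scene, klass, shape, gap_range) {
  sm <- scene$sector_map
  rows <- which(sm$klass == klass)
  row <- if (length(rows) > 1) rows[sample.int(length(rows), 1)] else rows
  span <- sm$t1[row] - sm$t0[row]
  tstar <- sm$t0[row] + span * stats::runif(1, 0.2, 0.8)
  w <- scene$width; h <- scene$height; hw <- scene$bone_halfwidth

  p <- arch_point(tstar, w, h)
  eps <- 1e-3
  p2 <- arch_point(min(tstar + eps, 1), w, h)
  p1 <- arch_point(max(tstar - eps, 0), w, h)
  tang <- c(p2[1] - p1[1], p2[2] - p1[2])
  tang <- tang / sqrt(sum(tang^2))
  norm <- c(-tang[2], tang[1])

  if (shape == "displaced") {
    # dislocated condylar head: terminal arch segment duplicated with an
    # offset; the polyline is the contact segment between the two contours
    t_seg <- if (tstar < 0.5) seq(0, 0.05, length.out = 24L) else seq(0.95, 1, length.out = 24L)
    seg <- arch_point(t_seg, w, h)
    shift <- c(if (tstar < 0.5) 1 else -1, 0.8) * (1.1 * hw)
    polyline <- seg[seq(1, nrow(seg), by = 6L), , drop = FALSE]
    gap_px <- 0
    ext <- rbind(seg, sweep(seg, 2, -shift))
    pad <- hw + 2
  } else {
    tilt <- stats::runif(1, -0.4, 0.4) + if (shape == "oblique_gap") stats::runif(1, -0.2, 0.2) else 0
    dirv <- c(cos(tilt) * norm[1] - sin(tilt) * norm[2],
              sin(tilt) * norm[1] + cos(tilt) * norm[2])
    len <- 2.4 * hw
    polyline <- rbind(p - dirv * len / 2, p, p + dirv * len / 2)
    gap_px <- if (shape == "oblique_gap") stats::runif(1, gap_range[1], gap_range[2]) else 0
    ext <- polyline
    pad <- max(gap_px, 0.45 * hw) + 3
  }
  polyline[, 1] <- pmin(pmax(polyline[, 1], 1), w - 1)
  polyline[, 2] <- pmin(pmax(polyline[, 2], 1), h - 1)
  box <- c(x0 = max(0, floor(min(ext[, 1]) - pad)),
           y0 = max(0, floor(min(ext[, 2]) - pad)),
           x1 = min(w, ceiling(max(ext[, 1]) + pad)),
           y1 = min(h, ceiling(max(ext[, 2]) + pad)))
  list(klass = klass, shape = shape, polyline = unname(polyline),
       gap_px = gap_px, box = box,
       shift = if (shape == "displaced") shift else NULL,
       tstar = tstar)
}

#' Sample fracture specifications for one phantom
#'
#' Classes are drawn from `config$class_probs` and morphologies from
#' `config$shape_probs`; a displaced draw on a non-condyle class is re-drawn
#' between oblique and shear (displaced dislocation only occurs at the
#' condyle).
#'
#' @param scene A [build_scene()] result.
#' @param n Number of fractures.
#' @param config A [phantom_config()].
#' @return List of fracture specs (klass, shape, polyline, gap_px, box).
#' @export
sample_fracture_specs <- function(scene, n, config) {
  if (n == 0) return(list())
  classes <- sample_fracture_classes(n, config$class_probs)
  shapes <- sample(fracture_shapes(), n, replace = TRUE, prob = config$shape_probs)
  for (i in seq_len(n)) {
    if (shapes[i] == "displaced" && classes[i] != "condyle") {
      p2 <- config$shape_probs[1:2]
      shapes[i] <- if (sum(p2) > 0) sample(fracture_shapes()[1:2], 1, prob = p2) else "oblique_gap"
    }
  }
  lapply(seq_len(n), function(i)
    sample_fracture_spec(scene, classes[i], shapes[i], config$gap_range))
}

# Rasterize a polyline into pixel (row, col) indices via Bresenham.
raster_polyline <- function(polyline, height, width) {
  pts <- NULL
  for (i in seq_len(nrow(polyline) - 1)) {
    seg <- bresenham_points(polyline[i, 1], polyline[i, 2],
                            polyline[i + 1, 1], polyline[i + 1, 2])
    pts <- rbind(pts, seg)
  }
  pts <- unique(pts)
  keep <- pts[, 1] >= 1 & pts[, 1] <= height & pts[, 2] >= 1 & pts[, 2] <= width
  pts[keep, , drop = FALSE]
}

# Integer Bresenham walk between two continuous points; returns (row, col).
bresenham_points <- function(x0, y0, x1, y1) {
  c0 <- floor(x0) + 1L; r0 <- floor(y0) + 1L
  c1 <- floor(x1) + 1L; r1 <- floor(y1) + 1L
  dx <- abs(c1 - c0); dy <- abs(r1 - r0)
  n <- max(dx, dy) + 1L
  cbind(row = round(seq(r0, r1, length.out = n)),
        col = round(seq(c0, c1, length.out = n)))
}

# Distance (px) from every pixel to a rasterized point set, via the
# distance transform of the inverted raster.
dist_to_raster <- function(pts, height, width) {
  m <- matrix(1L, height, width)
  if (nrow(pts) > 0) m[pts] <- 0L
  as.matrix(EBImage::distmap(m))
}

# Perpendicular distance and side-sign of window pixels relative to a
# 2-point direction through `p` with unit direction `d`.
signed_dist_to_line <- function(xg, yg, p, d) {
  rx <- xg - p[1]; ry <- yg - p[2]
  list(perp = rx * (-d[2]) + ry * d[1],   # signed perpendicular offset
       along = rx * d[1] + ry * d[2])
}

# Scanline even-odd polygon fill.
poly_fill <- function(poly, height, width) {
  mask <- matrix(0L, height, width)
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  for (r in seq_len(height)) {
    y <- r - 0.5
    cross <- (ys <= y & ye > y) | (ye <= y & ys > y)
    if (!any(cross)) next
    xi <- xs[cross] + (y - ys[cross]) / (ye[cross] - ys[cross]) * (xe[cross] - xs[cross])
    xi <- sort(xi)
    for (k in seq(1, length(xi) - 1, by = 2)) {
      c0 <- max(1L, floor(xi[k]) + 1L)
      c1 <- min(width, ceiling(xi[k + 1]))
      if (c1 >= c0) mask[r, c0:c1] <- 1L
    }
  }
  mask
}

#' Render a phantom radiograph
#'
#' Renders the scene's bone band and tooth row over a smoothly shaded
#' background, draws each fracture according to its morphology, and adds
#' Gaussian noise. Uses the current RNG state for shading and noise, so
#' wrap in a fixed seed for bit-identical output.
#'
#' @param scene A [build_scene()] result.
#' @param specs Fracture specs from [sample_fracture_specs()] (may be empty).
#' @param noise_sigma Additive Gaussian noise, gray levels.
#' @return Numeric matrix 0..255 (rows = y).
#' @export
render_phantom <- function(scene, specs = list(), noise_sigma = 4) {
  w <- scene$width; h <- scene$height; hw <- scene$bone_halfwidth
  xg <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  yg <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)

  # background: base level plus global gradient and low-frequency shading
  gx <- stats::runif(1, -14, 14); gy <- stats::runif(1, -14, 14)
  img <- 48 + gx * (xg / w - 0.5) + gy * (yg / h - 0.5)
  shade <- matrix(stats::rnorm(h * w), h, w)
  shade <- as.matrix(EBImage::gblur(shade, sigma = max(8, min(h, w) / 10)))
  img <- img + shade * (10 / max(stats::sd(shade), 1e-8))

  # bone band along the arch
  arch_pts <- raster_polyline(scene$arch_polyline, h, w)
  d_arch <- dist_to_raster(arch_pts, h, w)
  bone <- exp(-(d_arch / hw)^4)
  img <- img + 120 * bone

  # tooth row with periodic interdental seams
  tooth <- poly_fill(scene$tooth_polygon, h, w)
  seam <- 1 - 0.55 * exp(-((xg %% 9) - 4.5)^2 / (2 * 1.1^2))
  img <- img + 48 * tooth * seam

  for (spec in specs) {
    bx <- spec$box
    r0 <- max(1L, floor(bx["y0"]) + 1L); r1 <- min(h, ceiling(bx["y1"]))
    c0 <- max(1L, floor(bx["x0"]) + 1L); c1 <- min(w, ceiling(bx["x1"]))
    rows <- r0:r1; cols <- c0:c1
    wx <- xg[rows, cols, drop = FALSE]; wy <- yg[rows, cols, drop = FALSE]

    if (spec$shape == "displaced") {
      seg <- spec$polyline
      shifted <- sweep(seg, 2, -spec$shift)
      d2 <- dist_window_to_polyline(wx, wy, shifted)
      img[rows, cols] <- img[rows, cols] + 110 * exp(-(d2 / (0.8 * hw))^4)
    } else {
      p <- spec$polyline[2, ]
      dvec <- spec$polyline[3, ] - spec$polyline[1, ]
      dvec <- dvec / sqrt(sum(dvec^2))
      sd <- signed_dist_to_line(wx, wy, p, dvec)
      half_len <- sqrt(sum((spec$polyline[3, ] - spec$polyline[1, ])^2)) / 2
      inside <- abs(sd$along) <= half_len
      if (spec$shape == "oblique_gap") {
        # the radiolucent gap is rendered at full contrast along the whole
        # labeled polyline, so the line label always traces visible evidence
        band <- exp(-(abs(sd$perp) / (spec$gap_px / 2))^4) * inside
        img[rows, cols] <- img[rows, cols] - 95 * band
      } else {
        step_side <- (sd$perp > 0) * exp(-pmax(sd$perp - 10, 0)^2 / 18) * inside
        img[rows, cols] <- img[rows, cols] + 34 * step_side * bone[rows, cols]
        # shear fractures keep a visible solid crack line along the step
        edge <- exp(-(abs(sd$perp) / 1.4)^2) * inside
        img[rows, cols] <- img[rows, cols] - 42 * edge * pmin(bone[rows, cols] + 0.35, 1)
      }
    }
  }

  if (noise_sigma > 0) img <- img + matrix(stats::rnorm(h * w, 0, noise_sigma), h, w)
  round(clamp255(img))
}

# Min distance from window grid points to a polyline (few segments).
dist_window_to_polyline <- function(wx, wy, polyline) {
  d <- matrix(Inf, nrow(wx), ncol(wx))
  for (i in seq_len(nrow(polyline) - 1)) {
    a <- polyline[i, ]; b <- polyline[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 < 1e-12) next
    t <- ((wx - a[1]) * ab[1] + (wy - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    d <- pmin(d, sqrt((wx - (a[1] + t * ab[1]))^2 + (wy - (a[2] + t * ab[2]))^2))
  }
  d
}

#' Derive ground truth for a phantom
#'
#' The fracture-line mask marks the (dilated) polylines of oblique and shear
#' fractures only — displaced condylar fractures are deliberately excluded
#' from line labels, because overlapping bone contours have no crack line to
#' trace — while the box list covers every fracture including displaced
#' ones. The tooth mask fills the scene's tooth polygon.
#'
#' @param scene A [build_scene()] result.
#' @param specs Fracture specs.
#' @param line_thickness Dilation diameter (px) of line labels.
#' @return An object of class `ground_truth`: `specs`, `line_mask`,
#'   `tooth_mask`, `boxes` (data.frame klass, x0, y0, x1, y1).
#' @export
make_ground_truth <- function(scene, specs, line_thickness = 3) {
  h <- scene$height; w <- scene$width
  line_mask <- matrix(0L, h, w)
  for (spec in specs) {
    if (spec$shape == "displaced") next
    pts <- raster_polyline(spec$polyline, h, w)
    if (nrow(pts) > 0) line_mask[pts] <- 1L
  }
  if (line_thickness > 1 && any(line_mask == 1)) {
    brush_size <- line_thickness + (1 - line_thickness %% 2)  # odd
    line_mask <- as.matrix(EBImage::dilate(line_mask, EBImage::makeBrush(brush_size, "disc")))
    storage.mode(line_mask) <- "integer"
  }
  tooth_mask <- poly_fill(scene$tooth_polygon, h, w)
  boxes <- if (length(specs) == 0) {
    data.frame(klass = character(), x0 = numeric(), y0 = numeric(),
               x1 = numeric(), y1 = numeric(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(specs, function(s)
      data.frame(klass = s$klass, x0 = s$box["x0"], y0 = s$box["y0"],
                 x1 = s$box["x1"], y1 = s$box["y1"],
                 stringsAsFactors = FALSE, row.names = NULL)))
  }
  structure(list(specs = specs, line_mask = line_mask,
                 tooth_mask = tooth_mask, boxes = boxes),
            class = "ground_truth")
}

#' Generate a single phantom with ground truth
#'
#' Deterministic in (config, index): the image's RNG stream is seeded from
#' `child_seed(config$seed, index)`.
#'
#' @param config A [phantom_config()].
#' @param index Image index within the dataset (>= 1).
#' @return List with `image`, `gt` (a `ground_truth`), `scene`, `seed`.
#' @export
generate_phantom <- function(config, index = 1L) {
  assert_that(inherits(config, "phantom_config"), "config must be a phantom_config")
  seed_i <- child_seed(config$seed, index)
  with_seed(seed_i, {
    scene <- build_scene(config)
    n <- 1L + stats::rpois(1, config$fracture_excess_rate)
    specs <- sample_fracture_specs(scene, n, config)
    image <- render_phantom(scene, specs, config$noise_sigma)
    gt <- make_ground_truth(scene, specs, config$line_thickness)
    list(image = image, gt = gt, scene = scene, seed = seed_i)
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes, per image: the radiograph PNG, fracture-line and tooth-region
#' mask PNGs, and a YOLO-format annotation text file (`class_id cx cy w h`,
#' normalized), plus a JSON manifest recording the seed, file names and
#' per-image fracture records.
#'
#' @param config A [phantom_config()].
#' @param n_images Number of phantoms.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
generate_dataset <- function(config, n_images, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(out_dir), sprintf("cannot create output dir: %s", out_dir))
  records <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    ph <- generate_phantom(config, i)
    stem <- sprintf("phantom_%04d", i)
    img_f <- file.path(out_dir, paste0(stem, ".png"))
    line_f <- file.path(out_dir, paste0(stem, "_line_mask.png"))
    tooth_f <- file.path(out_dir, paste0(stem, "_tooth_mask.png"))
    ann_f <- file.path(out_dir, paste0(stem, ".txt"))
    write_radiograph(ph$image, img_f)
    write_mask(ph$gt$line_mask, line_f)
    write_mask(ph$gt$tooth_mask, tooth_f)
    dets <- boxes_to_detections(ph$gt$boxes)
    write_detections(dets, ann_f, image_size = c(config$width, config$height))
    records[[i]] <- list(
      image = basename(img_f), line_mask = basename(line_f),
      tooth_mask = basename(tooth_f), annotations = basename(ann_f),
      seed = ph$seed,
      fractures = lapply(ph$gt$specs, function(s)
        list(klass = s$klass, shape = s$shape, gap_px = s$gap_px,
             box = as.numeric(s$box))))
  }
  manifest <- list(generator = "panfrax phantom", seed = config$seed,
                   width = config$width, height = config$height,
                   n_images = n_images, images = records)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Ground-truth boxes (data.frame) -> detections data.frame with confidence 1.
boxes_to_detections <- function(boxes) {
  data.frame(klass = boxes$klass, x0 = boxes$x0, y0 = boxes$y0,
             x1 = boxes$x1, y1 = boxes$y1,
             confidence = rep(1, nrow(boxes)),
             stringsAsFactors = FALSE)
}
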