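test_that("fracture class sampling follows the requested distribution", {
  expect_error(sample_fracture_classes(5, probs = rep(0.5, 6)), "summing to 1")

  set.seed(1)
  expect_identical(unique(sample_fracture_classes(5, probs = c(1, 0, 0, 0, 0, 0))),
                   "symphysis")

  # binomial standard-error oracle: freq within 3 s.e. of the target
  probs <- phantom_config()$class_probs
  set.seed(42)
  draws <- sample_fracture_classes(624, probs)
  p_hat <- mean(draws == "symphysis")
  se <- sqrt(probs[1] * (1 - probs[1]) / 624)
  expect_lt(abs(p_hat - probs[1]), 3 * se)

  set.seed(7)
  unif <- sample_fracture_classes(10000, rep(1 / 6, 6))
  se6 <- sqrt((1 / 6) * (5 / 6) / 10000)
  for (cl in fracture_classes()) {
    expect_lt(abs(mean(unif == cl) - 1 / 6), 3 * se6)
  }
})

test_that("scene geometry is deterministic, in bounds, and covers all classes", {
  cfg <- desk_config()
  s1 <- build_scene(cfg)
  s2 <- build_scene(cfg)
  expect_identical(s1, s2)

  expect_true(all(s1$arch_polyline[, 1] >= 0 & s1$arch_polyline[, 1] <= cfg$width))
  expect_true(all(s1$arch_polyline[, 2] >= 0 & s1$arch_polyline[, 2] <= cfg$height))
  expect_true(all(s1$tooth_polygon[, 1] >= 0 & s1$tooth_polygon[, 1] <= cfg$width))
  expect_true(all(s1$tooth_polygon[, 2] >= 0 & s1$tooth_polygon[, 2] <= cfg$height))

  sm <- s1$sector_map
  expect_setequal(unique(sm$klass), fracture_classes())
  # intervals concatenate to the full arc range with no gaps or overlap
  ord <- order(sm$t0)
  expect_equal(sm$t0[ord][1], 0)
  expect_equal(sm$t1[ord][length(ord)], 1)
  expect_equal(sm$t0[ord][-1], sm$t1[ord][-length(ord)])
  # left/right symmetry for the paired classes
  for (cl in c("body", "angle", "ramus", "condyle", "coronoid")) {
    iv <- sm[sm$klass == cl, ]
    expect_equal(nrow(iv), 2L)
    expect_equal(iv$t0[1], 1 - iv$t1[2], tolerance = 1e-9)
  }
})

test_that("rendering is deterministic and draws morphologies correctly", {
  cfg <- desk_config()
  scene <- build_scene(cfg)

  i1 <- with_seed <- panfrax:::with_seed(99, render_phantom(scene, list(), 0))
  i2 <- panfrax:::with_seed(99, render_phantom(scene, list(), 0))
  expect_identical(i1, i2)

  # an oblique fracture's gap band is darker than the flanking bone
  spec <- panfrax:::with_seed(3, panfrax:::sample_fracture_spec(
    scene, "body", "oblique_gap", c(4, 4)))
  img <- panfrax:::with_seed(1, render_phantom(scene, list(spec), 0))
  p <- spec$polyline[2, ]
  dirv <- spec$polyline[3, ] - spec$polyline[1, ]
  dirv <- dirv / sqrt(sum(dirv^2))
  normv <- c(-dirv[2], dirv[1])
  at <- function(pt) img[floor(pt[2]) + 1, floor(pt[1]) + 1]
  gap_val <- at(p)
  flank <- mean(c(at(p + normv * 6), at(p - normv * 6)))
  expect_lt(gap_val, flank)
})

test_that("ground truth excludes displaced fractures from the line mask only", {
  cfg <- desk_config()
  scene <- build_scene(cfg)
  specs <- panfrax:::with_seed(5, list(
    panfrax:::sample_fracture_spec(scene, "body", "oblique_gap", c(4, 4)),
    panfrax:::sample_fracture_spec(scene, "condyle", "displaced", c(4, 4))))
  gt <- make_ground_truth(scene, specs, line_thickness = 3)

  expect_equal(nrow(gt$boxes), 2L)
  expect_equal(max(as.matrix(EBImage::bwlabel(gt$line_mask))), 1L)

  # no line pixels under the displaced spec's polyline raster
  pts <- panfrax:::raster_polyline(specs[[2]]$polyline, 128, 128)
  expect_equal(sum(gt$line_mask[pts]), 0L)

  # every non-displaced polyline raster is inside its box
  pts1 <- panfrax:::raster_polyline(specs[[1]]$polyline, 128, 128)
  bx <- specs[[1]]$box
  expect_true(all(pts1[, 2] - 1 >= bx["x0"] & pts1[, 2] <= bx["x1"]))
  expect_true(all(pts1[, 1] - 1 >= bx["y0"] & pts1[, 1] <= bx["y1"]))

  empty <- make_ground_truth(scene, list())
  expect_equal(sum(empty$line_mask), 0L)
  expect_equal(nrow(empty$boxes), 0L)
})

test_that("phantom generation is reproducible and boxes match specs", {
  p1 <- generate_phantom(desk_config(), 3)
  p2 <- generate_phantom(desk_config(), 3)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$gt$line_mask, p2$gt$line_mask)
  expect_equal(nrow(p1$gt$boxes), length(p1$gt$specs))
})

test_that("generate_dataset writes a complete, reproducible file set", {
  cfg <- phantom_config(width = 128, height = 128, seed = 4)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  m1 <- generate_dataset(cfg, 3, d1)
  m2 <- generate_dataset(cfg, 3, d2)

  for (ext in c(".png", "_line_mask.png", "_tooth_mask.png", ".txt")) {
    files <- sprintf("phantom_%04d%s", 1:3, ext)
    expect_true(all(file.exists(file.path(d1, files))))
  }
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_equal(m1$seed, cfg$seed)

  h1 <- tools::md5sum(list.files(d1, full.names = TRUE, pattern = "png$|txt$"))
  h2 <- tools::md5sum(list.files(d2, full.names = TRUE, pattern = "png$|txt$"))
  expect_identical(unname(h1), unname(h2))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("phantom config validates its invariants", {
  expect_error(phantom_config(width = 64), ">= 128")
  expect_error(phantom_config(class_probs = rep(0.2, 6)), "summing to 1")
  expect_error(phantom_config(shape_probs = c(1, 1, 1)), "summing to 1")

  # displaced morphology never lands on a non-condyle class
  scene <- build_scene(desk_config())
  specs <- panfrax:::with_seed(8, sample_fracture_specs(
    scene, 60, phantom_config(width = 128, height = 128,
                              shape_probs = c(0.1, 0.1, 0.8))))
  for (s in specs) {
    if (s$shape == "displaced") expect_equal(s$klass, "condyle")
  }
})
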