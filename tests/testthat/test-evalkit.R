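test_that("precision, recall and F1 follow their closed forms", {
  expect_equal(precision_score(eval_counts(97, 0, 5)), 1.0)
  expect_equal(precision_score(eval_counts(3, 1, 0)), 0.75)
  expect_equal(precision_score(eval_counts(0, 5, 2)), 0.0)
  expect_error(precision_score(eval_counts(0, 0, 3)), "undefined")

  expect_equal(recall_score(eval_counts(4, 2, 0)), 1.0)
  expect_equal(recall_score(eval_counts(4, 0, 1)), 0.8)
  expect_equal(recall_score(eval_counts(0, 1, 5)), 0.0)
  expect_error(recall_score(eval_counts(0, 4, 0)), "undefined")

  expect_equal(f1_score(1, 1), 1.0)
  expect_error(f1_score(0, 0), "undefined")

  # harmonic mean is bounded by min/max and by the geometric mean
  set.seed(13)
  for (k in 1:50) {
    p <- runif(1, 0.01, 1); r <- runif(1, 0.01, 1)
    f <- f1_score(p, r)
    expect_gte(f, min(p, r) - 1e-12)
    expect_lte(f, max(p, r) + 1e-12)
    expect_lte(f, sqrt(p * r) + 1e-12)
  }
})

test_that("F1 reproduces the self-consistent published score cells", {
  # activation comparison table
  expect_equal(round(f1_score(0.859, 0.814), 3), 0.836)
  expect_equal(round(f1_score(0.828, 0.794), 3), 0.811)
  # detector comparison table
  expect_equal(round(f1_score(0.961, 0.753), 3), 0.844)
  expect_equal(round(f1_score(0.975, 0.794), 3), 0.875)
  # augmentation comparison table
  expect_equal(round(f1_score(0.917, 0.794), 3), 0.851)
})

test_that("class distribution reproduces the published percentage cells", {
  train <- class_distribution(c(153, 145, 183, 91, 39, 13))
  expect_equal(unname(train$percentages[1:5]),
               c(24.519, 23.237, 29.327, 14.583, 6.250))
  expect_equal(train$total, 624)

  test_d <- class_distribution(c(25, 20, 29, 8, 13, 2))
  expect_equal(unname(test_d$percentages[1:4]), c(25.773, 20.619, 29.897, 8.247))
  expect_equal(test_d$middle_share, 84.536)

  one <- class_distribution(c(1, 0, 0, 0, 0, 0))
  expect_equal(unname(one$percentages), c(100, 0, 0, 0, 0, 0))
  expect_error(class_distribution(rep(0, 6)), "all zero")
})

test_that("line profiles report correct statistics and transpose symmetry", {
  flat <- matrix(100, 32, 32)
  st <- line_profile(flat, c(2, 10), c(28, 10))
  expect_equal(c(st$maximum, st$minimum, st$mean, st$std), c(100, 100, 100, 0))

  two <- matrix(0, 1, 2); two[1, 2] <- 255
  st2 <- line_profile(two, c(0.5, 0.5), c(1.5, 0.5))
  expect_equal(st2$n, 2L)
  expect_equal(st2$mean, 127.5)
  expect_equal(st2$std, 127.5)       # population std of {0, 255}

  img <- desk_phantom(1)$image
  a <- line_profile(img, c(10, 40), c(100, 40))
  b <- line_profile(t(img), c(40, 10), c(40, 100))
  expect_equal(a$values, b$values)
  expect_error(line_profile(img, c(5, 5), c(5, 5)), "differ")
})

test_that("matching handles perfect, empty and mixed-modality predictions", {
  ph <- desk_phantom(5)
  gt <- ph$gt
  perfect <- list(boxes = panfrax:::boxes_to_detections(gt$boxes),
                  line_components = list())
  c1 <- match_detections(perfect, gt)
  expect_equal(c1$tp, length(gt$specs))
  expect_equal(c1$fp, 0L)
  expect_equal(c1$fn, 0L)

  none <- list(boxes = NULL, line_components = list())
  c2 <- match_detections(none, gt)
  expect_equal(c2$tp, 0L)
  expect_equal(c2$fn, length(gt$specs))

  # correct box plus an overlapping line component on one GT: one TP, no FP
  one_gt_idx <- which(vapply(gt$specs, function(s) s$shape != "displaced",
                             logical(1)))[1]
  skip_if(is.na(one_gt_idx))
  sp <- gt$specs[[one_gt_idx]]
  comp_mask <- matrix(0L, 128, 128)
  pts <- panfrax:::raster_polyline(sp$polyline, 128, 128)
  comp_mask[pts] <- 1L
  comps <- line_components(comp_mask)
  single_gt <- structure(list(specs = list(sp), line_mask = gt$line_mask,
                              tooth_mask = gt$tooth_mask,
                              boxes = gt$boxes[one_gt_idx, , drop = FALSE]),
                         class = "ground_truth")
  both <- list(boxes = panfrax:::boxes_to_detections(single_gt$boxes),
               line_components = comps)
  c3 <- match_detections(both, single_gt)
  expect_equal(c3$tp, 1L)
  expect_equal(c3$fp, 0L)
  expect_equal(c3$fn, 0L)
})

test_that("matching TP equals brute-force maximum over random box instances", {
  # oracle equivalence on instances with <= 6 GT and <= 6 predictions
  set.seed(31)
  canvas <- matrix(0L, 64, 64)
  for (k in 1:60) {
    n_gt <- sample(1:6, 1); n_pred <- sample(0:6, 1)
    specs <- lapply(seq_len(n_gt), function(i) {
      x0 <- runif(1, 0, 40); y0 <- runif(1, 0, 40)
      w <- runif(1, 8, 20); h <- runif(1, 8, 20)
      list(klass = "body", shape = "displaced",
           polyline = rbind(c(x0, y0), c(x0 + w, y0 + h)),
           box = c(x0 = x0, y0 = y0, x1 = min(64, x0 + w), y1 = min(64, y0 + h)))
    })
    gt <- structure(list(specs = specs, line_mask = canvas,
                         tooth_mask = canvas,
                         boxes = do.call(rbind, lapply(specs, function(s)
                           data.frame(klass = s$klass, x0 = s$box[1], y0 = s$box[2],
                                      x1 = s$box[3], y1 = s$box[4])))),
                    class = "ground_truth")
    boxes <- if (n_pred > 0) {
      data.frame(klass = "body",
                 x0 = runif(n_pred, 0, 40), y0 = runif(n_pred, 0, 40),
                 x1 = NA, y1 = NA, confidence = runif(n_pred))
    } else NULL
    if (!is.null(boxes)) {
      boxes$x1 <- pmin(64, boxes$x0 + runif(n_pred, 8, 20))
      boxes$y1 <- pmin(64, boxes$y0 + runif(n_pred, 8, 20))
    }
    got <- match_detections(list(boxes = boxes, line_components = list()), gt)

    elig <- matrix(FALSE, max(n_pred, 1), n_gt)
    if (n_pred > 0) {
      for (p in seq_len(n_pred)) for (g in seq_len(n_gt)) {
        elig[p, g] <- box_iou(as.numeric(boxes[p, c("x0", "y0", "x1", "y1")]),
                              as.numeric(specs[[g]]$box)) >= 0.5
      }
    }
    best <- brute_force_max_tp(if (n_pred > 0) elig else matrix(FALSE, 0, n_gt))
    expect_equal(got$tp, best)
    expect_equal(got$tp + got$fn, n_gt)       # count conservation
    expect_lte(got$tp + got$fp, max(n_pred, 0))
  }
})
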